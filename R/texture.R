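## patch descriptors: mean HU, SD, mean gradient magnitude (HU/mm) and RMS
## Laplacian over a patch or a box window around each voxel

shiftArray <- function(a, ax, by) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax]) # replicate edges
  switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

gradMagnitude <- function(a, spacing) {
  g2 <- 0
  for (ax in 1:3) {
    g <- (shiftArray(a, ax, 1L) - shiftArray(a, ax, -1L)) / (2 * spacing[ax])
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

laplacian3 <- function(a, spacing) {
  l <- 0
  for (ax in 1:3) {
    l <- l + (shiftArray(a, ax, 1L) - 2 * a + shiftArray(a, ax, -1L)) /
      spacing[ax]^2
  }
  l
}

patchDescriptor <- function(patch, spacing = c(1, 1, 1)) {
  d <- dim(patch)
  g <- gradMagnitude(patch, spacing)
  l <- laplacian3(patch, spacing)
  ## derivative stats over the patch interior only, so they match the
  ## full-volume finite differences used at deployment
  core <- function(a) a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  c(mean = mean(patch), sd = sd(as.numeric(patch)),
    grad = mean(core(g)), lap = sqrt(mean(core(l)^2)))
}

## per-voxel descriptor arrays over a physically sized box window
## (~5 mm edge: radius = round(2 mm / spacing) voxels per axis)
voxelDescriptors <- function(volume, radius = NULL) {
  v <- volume@values
  d <- dim(v)
  sp <- volume@spacing
  if (is.null(radius)) radius <- pmax(1L, as.integer(round(2 / sp)))
  bm <- function(x) .cpp_box_mean3(as.numeric(x), d, as.integer(radius))
  m <- bm(v)
  m2 <- bm(v^2)
  g <- gradMagnitude(v, sp)
  l <- laplacian3(v, sp)
  cbind(mean = m, sd = sqrt(pmax(m2 - m^2, 0)), grad = bm(g),
        lap = sqrt(bm(l^2)))
}

textureOrdination <- function() c("V", "R", "O", "I", "Y", "P", "B", "G", "C")

#' Fit the 9 texture exemplars
#'
#' k-means over patch descriptors (patch mean HU, SD, mean gradient magnitude,
#' Laplacian energy, standardized) of a training patch library. The fitted
#' centroids are ordinated by ascending mean HU and mapped onto the fixed
#' exemplar label order V-R-O-I-Y-P-B-G-C (most indolent to most aggressive).
#'
#' @param patches list of cubic HU arrays (any size >= 3 voxels per axis).
#' @param k number of exemplars (9).
#' @param seed integer seed for the k-means initialization.
#' @return an \linkS4class{ExemplarModel} of kind \code{"texture9"} with
#'   centroids stored in ordination order on the standardized descriptor
#'   scale.
#' @export
fitTextureExemplars <- function(patches, k = 9L, seed = 1L) {
  if (length(patches) < k)
    stop("need at least ", k, " training patches, got ", length(patches))
  D <- t(vapply(patches, patchDescriptor, numeric(4)))
  if (nrow(unique(D)) < k)
    stop("fewer than ", k, " distinct patches")
  ctr <- colMeans(D)
  scl <- apply(D, 2, sd)
  scl[scl == 0] <- 1
  Ds <- sweep(sweep(D, 2, ctr), 2, scl, "/")
  set.seed(deriveSeed(seed, "kmeans"))
  km <- kmeans(Ds, centers = k, nstart = 100, iter.max = 200)
  meanHu <- km$centers[, "mean"] * scl["mean"] + ctr["mean"]
  ord <- order(meanHu)
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- textureOrdination()
  new("ExemplarModel", kind = "texture9",
      exemplarLabels = c("V", "I", "B", "G", "Y", "O", "R", "C", "P"),
      ordination = textureOrdination(), centroids = centroids,
      descriptorCenter = ctr, descriptorScale = scl, thresholds = list())
}

.modelCache <- new.env(parent = emptyenv())

#' Default texture exemplar model
#'
#' The packaged stand-in exemplar dictionary, trained once per session with a
#' fixed seed on a synthetic patch library of nine separable HU/texture
#' families spanning air-density to soft-tissue-density patterns with
#' increasing heterogeneity. Reproducible by construction.
#'
#' @return an \linkS4class{ExemplarModel} of kind \code{"texture9"}.
#' @export
defaultTextureExemplars <- function() {
  if (!is.null(.modelCache$texture9)) return(.modelCache$texture9)
  set.seed(deriveSeed(1405L, "patch-library"))
  ## mean ladder spans air to soft tissue; the SD ladder is geometric so the
  ## noisy scatter of the texture descriptors stays well below the gap
  ## between neighboring families
  means <- c(-950, -800, -650, -500, -350, -200, -50, 100, 250)
  sds <- c(12, 17, 24, 34, 49, 69, 99, 140, 200)
  patches <- list()
  for (f in seq_along(means)) {
    for (r in seq_len(30)) {
      patches[[length(patches) + 1L]] <-
        array(rnorm(343, means[f], sds[f]), c(7, 7, 7))
    }
  }
  .modelCache$texture9 <- fitTextureExemplars(patches, k = 9L, seed = 1405L)
  .modelCache$texture9
}

#' Classify nodule voxels into texture exemplars
#'
#' Computes the four patch descriptors for every masked voxel over a ~5 mm
#' box window, standardizes them with the model's training scaling, assigns
#' each voxel to the nearest exemplar centroid, and returns the proportions
#' over the ordination.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param mask a \linkS4class{NoduleMask} on the same grid.
#' @param model an \linkS4class{ExemplarModel} of kind \code{"texture9"}.
#' @return an \linkS4class{ExemplarDistribution} over the 9 texture
#'   exemplars.
#' @export
classifyNoduleTexture <- function(volume, mask,
                                  model = defaultTextureExemplars()) {
  stopifnotSameGrid(volume, mask)
  if (!any(mask@values)) stop("validation error: empty mask")
  if (model@kind != "texture9") stop("model must be of kind 'texture9'")
  D <- voxelDescriptors(volume)[as.logical(mask@values), , drop = FALSE]
  Ds <- sweep(sweep(D, 2, model@descriptorCenter), 2,
              model@descriptorScale, "/")
  ## squared distances to each centroid
  cc <- model@centroids
  d2 <- outer(rowSums(Ds^2), rowSums(cc^2), "+") - 2 * Ds %*% t(cc)
  cls <- max.col(-d2, ties.method = "first")
  counts <- tabulate(cls, nbins = nrow(cc))
  exemplarDistribution(setNames(counts / sum(counts), model@ordination),
                       n = nrow(D), kind = "texture9")
}

#' Texture risk summary
#'
#' Mean ordinal exemplar position rescaled to [1, 3]:
#' 1 + 2 (E[rank] - 1) / (K - 1). 1 when all mass is on the most indolent
#' exemplar, 3 at the most aggressive, 2 for a uniform distribution.
#'
#' @param dist an \linkS4class{ExemplarDistribution}.
#' @return numeric scalar in [1, 3].
#' @export
textureRisk <- function(dist) {
  if (dist@n <= 0) stop("empty distribution")
  p <- dist@proportions
  K <- length(p)
  1 + 2 * sum(p * (seq_len(K) - 1)) / (K - 1)
}

parenchymaOrdination <- function() {
  c("normal", "groundglass", "mild_laa", "moderate_laa", "reticular",
    "severe_laa", "honeycombing")
}

#' Default parenchymal exemplar model
#'
#' Rule-based 7-class parenchymal dictionary using conventional
#' quantitative-CT HU cutoffs: low-attenuation areas at -950 / -910 / -856 HU
#' (severe / moderate / mild), ground glass (-700, -500], and
#' reticular/honeycombing surrogates as high local-SD voxels in the
#' (-700, -200] band (honeycombing additionally requiring adjacency to
#' air-density voxels). Vessels are soft-tissue-density shell voxels in
#' (-200, 100]; anything above 100 HU or at/below -1024 HU is non-lung
#' background.
#'
#' @return an \linkS4class{ExemplarModel} of kind \code{"parenchyma7"}.
#' @export
defaultParenchymaModel <- function() {
  new("ExemplarModel", kind = "parenchyma7",
      exemplarLabels = parenchymaOrdination(),
      ordination = parenchymaOrdination(),
      centroids = matrix(numeric(0), 0, 0),
      descriptorCenter = numeric(0), descriptorScale = numeric(0),
      thresholds = list(vessel = c(-200, 100), lungFloor = -1024,
                        severe = -950, moderate = -910, mild = -856,
                        groundglass = c(-700, -500),
                        fibrosisBand = c(-700, -200), sdThreshold = 40,
                        airHu = -910))
}

#' Classify the surrounding-lung shell into parenchymal exemplars
#'
#' Rule-based labeling of every shell voxel as vessel, background (non-lung),
#' or one of the 7 parenchymal exemplars; returns the parenchymal exemplar
#' distribution plus the vessel/background percentages and the two
#' sub-ordination SILA summaries: SILA_Fibrosis over Normal < Ground glass <
#' Reticular < Honeycombing and SILA_low_attenuation over Normal < mild <
#' moderate < severe low-attenuation (classes outside a sub-ordination count
#' as Normal for that score; both are reported x 100).
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param shellMask the nodule-free surrounding shell
#'   (\link{surroundShell}).
#' @param model an \linkS4class{ExemplarModel} of kind \code{"parenchyma7"}.
#' @return list with \code{distribution} (ExemplarDistribution over 7),
#'   \code{vesselsPct}, \code{backgroundPct}, \code{silaFibrosis},
#'   \code{silaLowAttenuation} and the raw \code{counts}; all NA (with a
#'   warning) for an empty shell.
#' @export
classifyParenchyma <- function(volume, shellMask,
                               model = defaultParenchymaModel()) {
  stopifnotSameGrid(volume, shellMask)
  if (model@kind != "parenchyma7") stop("model must be of kind 'parenchyma7'")
  if (!any(shellMask@values)) {
    warning("empty shell: parenchymal features flagged missing")
    return(list(distribution = NA, vesselsPct = NA_real_,
                backgroundPct = NA_real_, silaFibrosis = NA_real_,
                silaLowAttenuation = NA_real_, counts = NA))
  }
  th <- model@thresholds
  d <- dim(volume@values)
  sel <- as.logical(shellMask@values)
  hu <- volume@values[sel]
  ## local structure maps for the fibrosis surrogates
  radius <- pmax(1L, as.integer(round(1.5 / volume@spacing)))
  bm <- function(x) .cpp_box_mean3(as.numeric(x), d, radius)
  m <- bm(volume@values)
  localSd <- sqrt(pmax(bm(volume@values^2) - m^2, 0))[sel]
  nearAir <- (.cpp_box_mean3(as.numeric(volume@values <= th$airHu), d,
                             c(1L, 1L, 1L)) > 0)[sel]

  lab <- character(length(hu))
  vessel <- hu > th$vessel[1] & hu <= th$vessel[2]
  background <- hu > th$vessel[2] | hu <= th$lungFloor
  lab[vessel] <- "vessel"
  lab[background] <- "background"
  open <- !vessel & !background
  assign <- function(cond, name) {
    sel2 <- open & cond & lab == ""
    lab[sel2] <<- name
  }
  assign(hu <= th$severe, "severe_laa")
  assign(hu <= th$moderate, "moderate_laa")
  assign(hu <= th$mild, "mild_laa")
  inBand <- hu > th$fibrosisBand[1] & hu <= th$fibrosisBand[2]
  assign(inBand & localSd > th$sdThreshold & nearAir, "honeycombing")
  assign(inBand & localSd > th$sdThreshold, "reticular")
  assign(hu > th$groundglass[1] & hu <= th$groundglass[2], "groundglass")
  assign(rep(TRUE, length(hu)), "normal")

  ord <- model@ordination
  counts <- setNames(vapply(ord, function(o) sum(lab == o), numeric(1)), ord)
  nPar <- sum(counts)
  distribution <- if (nPar > 0)
    exemplarDistribution(counts / nPar, n = nPar, kind = "parenchyma7")
  else NA
  subSila <- function(subOrder) {
    if (nPar == 0) return(NA_real_)
    p <- counts / nPar
    ## fold classes outside the sub-ordination into "normal"
    folded <- p[subOrder]
    folded["normal"] <- folded["normal"] + sum(p[setdiff(ord, subOrder)])
    100 * silaFromProportions(unname(folded))
  }
  list(distribution = distribution,
       vesselsPct = 100 * sum(vessel) / length(hu),
       backgroundPct = 100 * sum(background) / length(hu),
       silaFibrosis = subSila(c("normal", "groundglass", "reticular",
                                "honeycombing")),
       silaLowAttenuation = subSila(c("normal", "mild_laa", "moderate_laa",
                                      "severe_laa")),
       counts = counts)
}
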