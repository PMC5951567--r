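#' Per-vertex principal curvatures
#'
#' Fits a quadric height patch over each vertex's ring neighborhood in the
#' frame of the outward vertex normal and returns the principal curvatures
#' kappa1 >= kappa2 (1/mm), mean and Gaussian curvature, Koenderink shape
#' index and curvedness. Convex regions have positive curvature under the
#' outward-normal convention (sphere of radius r: H = 1/r, K = 1/r^2).
#' Vertices with fewer than five 2-ring neighbors or an ill-conditioned fit
#' are flagged unreliable.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param rings neighborhood ring depth of the quadric fit (default 3; larger
#'   values average curvature noise over a wider patch at the cost of bias on
#'   fine features).
#' @return a \linkS4class{CurvatureField}.
#' @export
principalCurvatures <- function(mesh, rings = 3L) {
  if (nrow(mesh@vertices) < 10)
    stop("mesh too small for curvature estimation (< 10 vertices)")
  N <- .cpp_vertex_normals(mesh@vertices, mesh@faces)
  q <- .cpp_quadric_curvatures(mesh@vertices, mesh@faces, N,
                               as.integer(rings))
  k1 <- q$kappa1
  k2 <- q$kappa2
  H <- (k1 + k2) / 2
  K <- k1 * k2
  dk <- k1 - k2
  s <- ifelse(dk > 1e-9, (2 / pi) * atan((k1 + k2) / dk),
              ifelse(abs(H) < 1e-9, 0, sign(H)))
  C <- sqrt((k1^2 + k2^2) / 2)
  new("CurvatureField", kappa1 = k1, kappa2 = k2, H = H, K = K,
      shapeIndex = as.numeric(s), curvedness = C, reliable = q$reliable)
}

wMean <- function(x, w) if (sum(w) <= 0) 0 else sum(w * x) / sum(w)

#' Surface curvature summary features
#'
#' The nodule-surface block of the feature panel: vertex/face counts, the two
#' Willmore bending energies (integrands H^2 and H^2 - K; both scale-invariant
#' and equal to 4 pi and 0 on a sphere), extrema and area-weighted
#' positive-part means/skews of the mean and Gaussian curvatures, the bending
#' anisotropy Sharp = kappa1 - kappa2, curvedness statistics, shape-index
#' statistics, and the intrinsic ((1/4 pi) integral of max(K, 0)) and
#' extrinsic ((1/4 pi) integral of |H|) curvature indices. All integrals use
#' barycentric vertex area weights over reliable vertices.
#'
#' @param field a \linkS4class{CurvatureField}.
#' @param mesh the \linkS4class{SurfaceMesh} the field was computed on.
#' @return named list of the 26 surface features (catalogue ids 27-52).
#' @export
curvatureSummary <- function(field, mesh) {
  ok <- field@reliable
  if (!any(ok)) stop("no reliable vertices in curvature field")
  a <- mesh@vertexAreas[ok]
  H <- field@H[ok]
  K <- field@K[ok]
  sharp <- field@kappa1[ok] - field@kappa2[ok]
  C <- field@curvedness[ok]
  s <- field@shapeIndex[ok]
  posStats <- function(x) {
    sel <- x > 0
    list(avg = wMean(x[sel], a[sel]),
         skew = if (any(sel)) popSkew(x[sel], a[sel]) else 0)
  }
  pH <- posStats(H)
  pK <- posStats(K)
  list(
    n_vertices = nrow(mesh@vertices),
    n_faces = nrow(mesh@faces),
    willmore_energy_2 = sum((H^2 - K) * a),
    willmore_energy = sum(H^2 * a),
    min_mean_curv = min(H), max_mean_curv = max(H),
    avg_pos_mean_curv = pH$avg, skew_pos_mean_curv = pH$skew,
    min_gauss_curv = min(K), max_gauss_curv = max(K),
    avg_pos_gauss_curv = pK$avg, skew_pos_gauss_curv = pK$skew,
    min_sharp = min(sharp), max_sharp = max(sharp),
    avg_sharp = wMean(sharp, a), skew_sharp = popSkew(sharp, a),
    min_curved = min(C), max_curved = max(C),
    avg_curved = wMean(C, a), skew_curved = popSkew(C, a),
    min_shape_index = min(s), max_shape_index = max(s),
    avg_shape_index = wMean(s, a), skew_shape_index = popSkew(s, a),
    intrinsic_curv_index = sum(pmax(K, 0) * a) / (4 * pi),
    extrinsic_curv_index = sum(abs(H) * a) / (4 * pi))
}

surfaceOrdination <- function() {
  c("unknown", "minimal", "valley", "flat", "ridge", "pit",
    "saddle_valley", "saddle_ridge", "peak")
}

## HK-sign classification into the 9 surface exemplars (ordination indices)
surfaceVertexClasses <- function(field, eps = 0.02) {
  ord <- surfaceOrdination()
  cls <- integer(length(field@H))
  cls[] <- match("unknown", ord)
  ok <- field@reliable
  H <- field@H
  K <- field@K
  e2 <- eps^2
  assign <- function(name, cond) {
    sel <- ok & cond
    cls[sel] <<- match(name, ord)
  }
  assign("flat", abs(H) <= eps & abs(K) <= e2)
  assign("minimal", abs(H) <= eps & K < -e2)
  assign("ridge", H > eps & abs(K) <= e2)
  assign("peak", H > eps & K > e2)
  assign("saddle_ridge", H > eps & K < -e2)
  assign("valley", H < -eps & abs(K) <= e2)
  assign("pit", H < -eps & K > e2)
  assign("saddle_valley", H < -eps & K < -e2)
  cls
}

#' Surface exemplar distribution
#'
#' Classifies every vertex by the signs of its mean and Gaussian curvature
#' relative to a flatness tolerance eps (peak, ridge, saddle ridge, flat,
#' minimal surface, valley, pit, saddle valley; unreliable vertices are
#' "unknown") and returns the area-weighted proportions over the ordination
#' unknown < minimal < valley < flat < ridge < pit < saddle valley <
#' saddle ridge < peak (most indolent to most aggressive).
#'
#' @param field a \linkS4class{CurvatureField}.
#' @param mesh the corresponding \linkS4class{SurfaceMesh}.
#' @param eps curvature tolerance in 1/mm below which the surface is treated
#'   as flat (default 0.02, the curvature of a 50 mm sphere).
#' @return an \linkS4class{ExemplarDistribution} over the 9 surface classes.
#' @export
surfaceExemplarDistribution <- function(field, mesh, eps = 0.02) {
  ord <- surfaceOrdination()
  cls <- surfaceVertexClasses(field, eps)
  a <- mesh@vertexAreas
  mass <- vapply(seq_along(ord), function(k) sum(a[cls == k]), numeric(1))
  exemplarDistribution(setNames(mass / sum(mass), ord), n = sum(a),
                       kind = "surface9")
}

#' Surface SILA metrics
#'
#' The surface-exemplar SILA block: the global "morpheme" score (100 x SILA of
#' the whole-surface exemplar distribution), area-weighted mean and skew of
#' curvedness, and the local SILA statistics: each vertex's exemplar
#' distribution within a geodesic neighborhood of the given radius is scored
#' and the per-vertex scores are summarized by their mean (x 100) and
#' standardized skewness.
#'
#' @param field a \linkS4class{CurvatureField}.
#' @param mesh the corresponding \linkS4class{SurfaceMesh}.
#' @param neighborhoodRadiusMm geodesic neighborhood radius in mm (> 0).
#' @param eps curvature flatness tolerance (1/mm).
#' @return list with \code{silaMorpheme}, \code{morphemeAvgCurv},
#'   \code{morphemeSkewCurv}, \code{localSilaAvg}, \code{localSilaSkew} and
#'   the per-vertex \code{localScores} (0-1 scale).
#' @export
surfaceSilaMetrics <- function(field, mesh, neighborhoodRadiusMm = 3,
                               eps = 0.02) {
  if (neighborhoodRadiusMm <= 0)
    stop("validation error: neighborhood radius must be > 0")
  globalDist <- surfaceExemplarDistribution(field, mesh, eps)
  ok <- field@reliable
  a <- mesh@vertexAreas
  cls <- surfaceVertexClasses(field, eps)
  mass <- .cpp_geodesic_class_mass(mesh@vertices, mesh@faces,
                                   as.integer(cls), a, 9L,
                                   neighborhoodRadiusMm)
  tot <- colSums(mass)
  P <- sweep(mass, 2, pmax(tot, 1e-300), "/")
  Fc <- apply(P, 2, cumsum)[1:8, , drop = FALSE]
  scores <- colSums((1 - Fc)^2) / 8
  list(silaMorpheme = 100 * silaScore(globalDist),
       morphemeAvgCurv = wMean(field@curvedness[ok], a[ok]),
       morphemeSkewCurv = popSkew(field@curvedness[ok], a[ok]),
       localSilaAvg = 100 * mean(scores),
       localSilaSkew = popSkew(scores),
       localScores = scores)
}
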