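#' Configure the cohort feature-table simulator
#'
#' Builds a \linkS4class{CohortSimConfig} whose per-class feature marginals
#' default to the published cancer/control cohort means and SDs
#' (\code{\link{featureCatalog}}). Features are generated through a Gaussian
#' copula: correlated standard normals are transformed per feature to either a
#' Gaussian or a shifted-lognormal marginal moment-matched to the class
#' mean/SD (lognormal for skewed strictly-positive features such as volume,
#' where Gaussian draws would produce impossible negative values).
#'
#' @param nPerClass integer(2): rows per class, in the order (benign,
#'   malignant). Defaults to the published cohort sizes 318/408.
#' @param featureNames ordered feature identifiers (defaults to the catalogue
#'   panel).
#' @param classMeans,classSds p x 2 matrices (columns benign, malignant);
#'   defaults from the catalogue.
#' @param correlation a p x p correlation matrix, or a preset: "independent",
#'   or "block" (0.5 within a feature category, 0.1 across categories).
#' @param transform character(p): "gaussian" or "lognormal" per feature;
#'   defaults from the catalogue.
#' @param shift numeric(p): lower bound of the shifted-lognormal marginals.
#' @param clinical attach simulated clinical covariates (age, pack_years,
#'   sex, smoking) drawn from the published demographics.
#' @return a \linkS4class{CohortSimConfig}.
#' @export
cohortSimConfig <- function(nPerClass = c(benign = 318L, malignant = 408L),
                            featureNames = NULL, classMeans = NULL,
                            classSds = NULL, correlation = "block",
                            transform = NULL, shift = NULL,
                            clinical = TRUE) {
  cat57 <- featureCatalog()
  if (is.null(featureNames)) featureNames <- cat57$name
  p <- length(featureNames)
  known <- match(featureNames, cat57$name)
  if (is.null(classMeans)) {
    if (anyNA(known)) stop("classMeans required for non-catalogue features")
    classMeans <- cbind(benign = cat57$control_mean[known],
                        malignant = cat57$cancer_mean[known])
  }
  if (is.null(classSds)) {
    if (anyNA(known)) stop("classSds required for non-catalogue features")
    classSds <- cbind(benign = cat57$control_sd[known],
                      malignant = cat57$cancer_sd[known])
  }
  if (is.null(transform)) {
    transform <- if (anyNA(known)) rep("gaussian", p) else cat57$family[known]
  }
  if (is.null(shift)) {
    shift <- if (anyNA(known)) rep(0, p) else cat57$shift[known]
  }
  if (is.character(correlation) && length(correlation) == 1L) {
    correlation <- switch(correlation,
      independent = diag(p),
      block = {
        if (anyNA(known)) stop("'block' preset needs catalogue features")
        grp <- cat57$category[known]
        same <- outer(grp, grp, "==")
        m <- 0.1 + 0.4 * same
        diag(m) <- 1
        m
      },
      stop("unknown correlation preset: ", correlation))
  }
  dimnames(correlation) <- NULL
  nn <- as.integer(nPerClass)
  names(nn) <- c("benign", "malignant")
  new("CohortSimConfig", nPerClass = nn,
      featureNames = as.character(featureNames),
      classMeans = unname(as.matrix(classMeans)) |>
        `dimnames<-`(list(NULL, c("benign", "malignant"))),
      classSds = unname(as.matrix(classSds)) |>
        `dimnames<-`(list(NULL, c("benign", "malignant"))),
      correlation = correlation, transform = transform,
      shift = as.numeric(shift), clinical = isTRUE(clinical))
}

## published demographics used for the optional clinical covariates
clinicalMarginals <- list(
  age = list(benign = c(61.2, 5.0), malignant = c(63.7, 5.3)),
  pack_years = list(benign = c(55.3, 24), malignant = c(65.6, 28)),
  male_frac = c(benign = 0.594, malignant = 0.564),
  current_frac = c(benign = 0.506, malignant = 0.542))

#' Simulate a cohort feature table
#'
#' Draws \code{nPerClass} rows per class with the configured marginals and
#' copula correlation. The returned table has columns \code{id}, \code{label}
#' (factor benign/malignant), \code{size_mm} (nodule diameter, twice the
#' simulated \code{estimated_radius} when present), the features in
#' configured order, and, when \code{clinical} is set, \code{age},
#' \code{pack_years}, \code{sex} and \code{smoking}.
#'
#' @param config a \linkS4class{CohortSimConfig}.
#' @param seed integer seed; identical config + seed give identical tables.
#' @return a data.frame feature table.
#' @export
generateFeatureTable <- function(config, seed = 1L) {
  validObject(config)
  if (sum(config@nPerClass) == 0)
    stop("empty table: both class sizes are zero")
  set.seed(deriveSeed(seed, "cohort"))
  L <- chol(config@correlation + diag(1e-10, length(config@featureNames)))
  p <- length(config@featureNames)
  one <- function(cls) {
    n <- config@nPerClass[[cls]]
    if (n == 0) return(NULL)
    z <- matrix(rnorm(n * p), n, p) %*% L
    x <- matrix(NA_real_, n, p)
    for (f in seq_len(p)) {
      m <- config@classMeans[f, cls]
      s <- config@classSds[f, cls]
      if (config@transform[f] == "lognormal") {
        m0 <- m - config@shift[f]
        if (m0 <= 0 || s == 0) {
          x[, f] <- m + s * z[, f]
        } else {
          sig2 <- log(1 + s^2 / m0^2)
          mu <- log(m0) - sig2 / 2
          x[, f] <- config@shift[f] + exp(mu + sqrt(sig2) * z[, f])
        }
      } else {
        x[, f] <- m + s * z[, f]
      }
    }
    colnames(x) <- config@featureNames
    df <- data.frame(label = cls, x, check.names = FALSE)
    if (config@clinical) {
      ag <- clinicalMarginals$age[[cls]]
      py <- clinicalMarginals$pack_years[[cls]]
      df$age <- rnorm(n, ag[1], ag[2])
      df$pack_years <- pmax(30, rnorm(n, py[1], py[2]))
      df$sex <- ifelse(runif(n) < clinicalMarginals$male_frac[[cls]],
                       "male", "female")
      df$smoking <- ifelse(runif(n) < clinicalMarginals$current_frac[[cls]],
                           "current", "former")
    }
    df
  }
  out <- rbind(one("benign"), one("malignant"))
  out$label <- factor(out$label, levels = c("benign", "malignant"))
  out$id <- sprintf("S%05d", seq_len(nrow(out)))
  out$size_mm <- if ("estimated_radius" %in% names(out))
    2 * out$estimated_radius else NA_real_
  front <- c("id", "label", "size_mm")
  out[, c(front, setdiff(names(out), front))]
}
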