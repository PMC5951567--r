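labelsAsLogical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels == "malignant")
  labels > 0
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the Mann-Whitney rank formulation with midrank
#' tie correction, oriented so that higher scores in the malignant class give
#' AUC > 0.5.
#'
#' @param scores numeric scores.
#' @param labels class labels (factor/character benign/malignant, logical, or
#'   0/1 with 1 = malignant).
#' @return numeric AUC in [0, 1].
#' @export
aucRank <- function(scores, labels) {
  pos <- labelsAsLogical(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariate feature screening
#'
#' Per-feature discrimination: rank-based AUC, the Mann-Whitney test p-value
#' (normal approximation with tie correction), and the Bonferroni-adjusted
#' p-value min(1, m p) with m the number of features screened.
#'
#' @param table feature table with a \code{label} column.
#' @param features feature columns to screen (defaults to the catalogue panel
#'   columns present in the table).
#' @return data.frame with \code{feature}, \code{auc}, \code{p},
#'   \code{p_bonferroni}, sorted by catalogue order.
#' @export
univariateScreen <- function(table, features = NULL) {
  if (is.null(features))
    features <- intersect(featureNames57(), names(table))
  pos <- labelsAsLogical(table$label)
  if (!any(pos) || all(pos)) stop("both classes must be non-empty")
  m <- length(features)
  res <- lapply(features, function(f) {
    x <- table[[f]]
    p <- tryCatch(
      suppressWarnings(wilcox.test(x[pos], x[!pos], exact = FALSE)$p.value),
      error = function(e) NA_real_)
    data.frame(feature = f, auc = aucRank(x, pos), p = p,
               p_bonferroni = pmin(1, m * p))
  })
  do.call(rbind, res)
}

#' Spearman correlation matrix of the feature panel
#'
#' Pairwise Spearman rank correlations (midranks for ties). Correlations
#' involving a constant feature are undefined and reported as 0 with the
#' \code{"undefined"} attribute flagging them.
#'
#' @param table feature table (needs >= 3 rows).
#' @param features feature columns (defaults to the catalogue panel columns).
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   \code{undefined} is a logical matrix of masked entries.
#' @export
spearmanMatrix <- function(table, features = NULL) {
  if (is.null(features))
    features <- intersect(featureNames57(), names(table))
  x <- as.matrix(table[, features, drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 rows")
  constant <- apply(x, 2, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(cor(x, method = "spearman"))
  undef <- outer(constant, constant, "|")
  diag(undef) <- FALSE
  rho[undef] <- 0
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  attr(rho, "undefined") <- undef
  rho
}

#' Plot the Spearman heat map
#'
#' @param rho matrix from \code{\link{spearmanMatrix}}.
#' @param file optional PNG path; plots to the active device when NULL.
#' @return invisibly, the pheatmap object.
#' @export
plotSpearmanHeatmap <- function(rho, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap is required for plotting")
  attr(rho, "undefined") <- NULL
  ph <- pheatmap::pheatmap(rho, cluster_rows = FALSE, cluster_cols = FALSE,
                           breaks = seq(-1, 1, length.out = 101),
                           filename = file %||% NA)
  invisible(ph)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' LASSO stability selection
#'
#' Repeats L1-penalized logistic regression over stratified bootstrap
#' resamples of the rows: within each run the features are standardized (via
#' glmnet), the penalty is chosen by 10-fold cross-validated deviance, and a
#' feature counts as selected when its coefficient is non-zero at the chosen
#' penalty. Features selected in at least \code{freqThreshold} of the runs
#' form the stable set.
#'
#' @param table feature table with a \code{label} column (>= 20 rows per
#'   class).
#' @param features candidate feature columns (default: catalogue panel).
#' @param runs number of LASSO runs.
#' @param freqThreshold selection-frequency threshold (default 0.5).
#' @param seed integer seed (each run derives its own sub-seed).
#' @param nfolds cross-validation folds within each run.
#' @return a \linkS4class{StabilitySelectionResult}.
#' @export
lassoStabilitySelect <- function(table, features = NULL, runs = 1000L,
                                 freqThreshold = 0.5, seed = 1L,
                                 nfolds = 10L) {
  if (is.null(features))
    features <- intersect(featureNames57(), names(table))
  pos <- labelsAsLogical(table$label)
  if (sum(pos) < 20 || sum(!pos) < 20)
    stop("degenerate class balance: need at least 20 rows per class")
  x <- as.matrix(table[, features, drop = FALSE])
  constant <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    warning("excluding all-constant features: ",
            paste(features[constant], collapse = ", "))
    features <- features[!constant]
    x <- x[, features, drop = FALSE]
  }
  if (length(features) < 2) stop("need at least 2 non-constant features")
  y <- factor(ifelse(pos, "malignant", "benign"),
              levels = c("benign", "malignant"))
  iPos <- which(pos)
  iNeg <- which(!pos)
  counts <- setNames(numeric(length(features)), features)
  failures <- 0L
  for (r in seq_len(runs)) {
    set.seed(deriveSeed(seed, paste0("run", r)))
    idx <- c(sample(iNeg, length(iNeg), replace = TRUE),
             sample(iPos, length(iPos), replace = TRUE))
    sel <- tryCatch({
      cv <- glmnet::cv.glmnet(x[idx, , drop = FALSE], y[idx],
                              family = "binomial", nfolds = nfolds,
                              standardize = TRUE)
      ## 1-SE rule: the sparsest penalty whose CV deviance is within one
      ## standard error of the minimum (parsimonious selection)
      b <- as.numeric(coef(cv, s = "lambda.1se"))[-1]
      b != 0
    }, error = function(e) NULL)
    if (is.null(sel)) failures <- failures + 1L else counts <- counts + sel
  }
  good <- runs - failures
  if (good == 0) stop("all stability runs failed")
  freq <- counts / good
  new("StabilitySelectionResult", frequencies = freq,
      selected = names(freq)[freq >= freqThreshold],
      runs = as.integer(runs), threshold = freqThreshold,
      seed = as.integer(seed))
}

#' Fit the final multivariate logistic model
#'
#' Unpenalized maximum-likelihood logistic regression on the standardized
#' selected features (the selection stage already provided shrinkage;
#' per-feature Wald p-values require an unpenalized refit). Rows with missing
#' values in the selected features are dropped with a message. Perfect
#' separation is detected and raised as an error naming the separating
#' feature, since the refit would be invalid.
#'
#' @param table feature table with a \code{label} column.
#' @param selected non-empty character vector of feature columns.
#' @param onSeparation what to do when the classes are perfectly separated:
#'   \code{"error"} (default; the ML refit is invalid) or \code{"ridge"}, a
#'   lightly L2-penalized logistic fit that keeps coefficients finite (Wald
#'   p-values are then not reported). The fallback is intended for small
#'   simulated cohorts where separation is an artifact of sample size.
#' @return a \linkS4class{FittedClassifier}.
#' @export
fitFinalModel <- function(table, selected,
                          onSeparation = c("error", "ridge")) {
  onSeparation <- match.arg(onSeparation)
  if (length(selected) == 0) stop("selected feature set is empty")
  if (!all(selected %in% names(table)))
    stop("missing feature columns: ",
         paste(setdiff(selected, names(table)), collapse = ", "))
  keep <- stats::complete.cases(table[, selected, drop = FALSE])
  if (!all(keep))
    message("dropping ", sum(!keep), " rows with missing selected features")
  table <- table[keep, , drop = FALSE]
  pos <- labelsAsLogical(table$label)
  x <- as.matrix(table[, selected, drop = FALSE])
  sepFeature <- NULL
  for (f in selected) {
    xb <- x[!pos, f]
    xm <- x[pos, f]
    if (max(xb) < min(xm) || min(xb) > max(xm)) { sepFeature <- f; break }
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  if (!is.null(sepFeature)) {
    if (onSeparation == "error")
      stop("perfect separation detected: feature '", sepFeature,
           "' fully separates the classes")
    return(ridgeFallbackFit(xs, pos, selected, ctr, scl))
  }
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm(pos ~ xs, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  if (sepWarn && max(abs(b[-1])) > 15) {
    if (onSeparation == "error")
      stop("perfect separation detected: refit invalid (largest coefficient ",
           "on '", selected[which.max(abs(b[-1]))], "')")
    return(ridgeFallbackFit(xs, pos, selected, ctr, scl))
  }
  names(b) <- c("(Intercept)", selected)
  pv <- summary(fit)$coefficients[, 4]
  names(pv) <- c("(Intercept)", selected)
  new("FittedClassifier", features = selected, coefficients = b,
      center = setNames(ctr, selected), scale = setNames(scl, selected),
      pValues = pv)
}

#' Predict malignancy probabilities
#'
#' @param model a \linkS4class{FittedClassifier}.
#' @param table feature table containing the model features.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictClassifier <- function(model, table) {
  x <- as.matrix(table[, model@features, drop = FALSE])
  xs <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  eta <- model@coefficients[1] + drop(xs %*% model@coefficients[-1])
  stats::plogis(eta)
}

#' Modeling procedures for internal validation
#'
#' A procedure is a function \code{(table, seed) -> FittedClassifier}
#' encapsulating everything that must be repeated inside each bootstrap
#' resample. \code{fixedModelProcedure} refits a fixed feature set;
#' \code{stabilityProcedure} re-runs LASSO stability selection (with a reduced
#' number of runs for tractability) and refits, falling back to the single
#' feature with the most extreme univariate AUC if no feature reaches the
#' frequency threshold.
#'
#' @param features feature set (fixed procedure) or candidate set (stability
#'   procedure; NULL = catalogue panel).
#' @param runs,freqThreshold,nfolds stability-selection parameters.
#' @param onSeparation separation handling passed to
#'   \code{\link{fitFinalModel}}.
#' @return a procedure function.
#' @export
fixedModelProcedure <- function(features, onSeparation = "error") {
  force(features); force(onSeparation)
  function(table, seed) fitFinalModel(table, features,
                                      onSeparation = onSeparation)
}

#' @rdname fixedModelProcedure
#' @export
stabilityProcedure <- function(features = NULL, runs = 100L,
                               freqThreshold = 0.5, nfolds = 10L,
                               onSeparation = "error") {
  force(features); force(runs); force(freqThreshold); force(nfolds)
  force(onSeparation)
  function(table, seed) {
    ss <- lassoStabilitySelect(table, features = features, runs = runs,
                               freqThreshold = freqThreshold, seed = seed,
                               nfolds = nfolds)
    sel <- ss@selected
    if (length(sel) == 0) {
      scr <- univariateScreen(table, features = names(ss@frequencies))
      sel <- scr$feature[which.max(abs(scr$auc - 0.5))]
    }
    fitFinalModel(table, sel, onSeparation = onSeparation)
  }
}

## lightly penalized logistic fit used when maximum likelihood diverges
ridgeFallbackFit <- function(xs, pos, selected, ctr, scl) {
  if (length(selected) == 1L) xs <- cbind(xs, 0) # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(xs, factor(pos), family = "binomial", alpha = 0,
                        lambda = 0.01, standardize = FALSE)
  b <- as.numeric(coef(fit))[seq_len(length(selected) + 1L)]
  names(b) <- c("(Intercept)", selected)
  new("FittedClassifier", features = selected, coefficients = b,
      center = setNames(ctr, selected), scale = setNames(scl, selected),
      pValues = setNames(rep(NA_real_, length(selected) + 1L),
                         c("(Intercept)", selected)))
}
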