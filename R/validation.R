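#' Youden-index optimal cutoff
#'
#' Sweeps the midpoints between adjacent distinct scores and returns the
#' cutoff maximizing Youden's J = sensitivity + specificity - 1 under the rule
#' "score >= cutoff is called malignant". Ties are broken toward higher
#' specificity (and then the higher cutoff). With a single distinct score the
#' cutoff is that score (J = 0, sensitivity + specificity = 1).
#'
#' @param scores numeric classifier scores.
#' @param labels class labels (see \code{\link{aucRank}}).
#' @return list with \code{cutoff}, \code{sensitivity}, \code{specificity},
#'   \code{youdenJ}.
#' @export
youdenCutoff <- function(scores, labels) {
  pos <- labelsAsLogical(labels)
  if (!any(pos) || all(pos)) stop("both classes must be non-empty")
  u <- sort(unique(scores))
  if (length(u) == 1) {
    return(list(cutoff = u, sensitivity = 1, specificity = 0, youdenJ = 0))
  }
  cuts <- (u[-1] + u[-length(u)]) / 2
  sens <- vapply(cuts, function(ct) mean(scores[pos] >= ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(scores[!pos] < ct), numeric(1))
  J <- sens + spec - 1
  best <- which(J > max(J) - 1e-12)
  best <- best[order(-spec[best], -cuts[best])][1]
  list(cutoff = cuts[best], sensitivity = sens[best],
       specificity = spec[best], youdenJ = J[best])
}

#' Optimism-corrected bootstrap validation
#'
#' Harrell-style internal validation of a modeling procedure: the procedure is
#' fit on the full table (apparent AUC and Youden operating point), then
#' re-run on B stratified bootstrap resamples; each resample's optimism is
#' AUC(model_b on resample) - AUC(model_b on the original table), and the
#' corrected AUC is the apparent AUC minus the mean optimism. The procedure is
#' repeated in full inside every resample, so any selection step is part of
#' what is validated.
#'
#' @param table feature table with a \code{label} column.
#' @param procedure a procedure function (see
#'   \code{\link{fixedModelProcedure}}).
#' @param B number of bootstrap resamples (>= 1).
#' @param seed integer seed.
#' @param maxFailFrac error out when more than this fraction of resamples
#'   fails (default 0.1).
#' @return a \linkS4class{ValidationReport}.
#' @export
optimismCorrectedAuc <- function(table, procedure, B = 200L, seed = 1L,
                                 maxFailFrac = 0.1) {
  if (B < 1) stop("B must be >= 1")
  pos <- labelsAsLogical(table$label)
  if (!any(pos) || all(pos)) stop("both classes must be non-empty")
  model0 <- procedure(table, deriveSeed(seed, "apparent"))
  s0 <- predictClassifier(model0, table)
  apparent <- aucRank(s0, pos)
  yj <- youdenCutoff(s0, pos)
  iPos <- which(pos)
  iNeg <- which(!pos)
  optimisms <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    set.seed(deriveSeed(seed, paste0("boot", b)))
    idx <- c(sample(iNeg, length(iNeg), replace = TRUE),
             sample(iPos, length(iPos), replace = TRUE))
    boot <- table[idx, , drop = FALSE]
    optimisms[b] <- tryCatch({
      mb <- procedure(boot, deriveSeed(seed, paste0("bootproc", b)))
      aucRank(predictClassifier(mb, boot), pos[idx]) -
        aucRank(predictClassifier(mb, table), pos)
    }, error = function(e) NA_real_)
  }
  nFail <- sum(is.na(optimisms))
  if (nFail > maxFailFrac * B)
    stop("procedure failed on ", nFail, " of ", B, " resamples")
  opt <- mean(optimisms, na.rm = TRUE)
  new("ValidationReport", apparentAuc = apparent, optimism = opt,
      correctedAuc = apparent - opt, youdenCutoff = yj$cutoff,
      sensitivity = yj$sensitivity, specificity = yj$specificity,
      B = as.integer(B), n = nrow(table),
      ablation = data.frame(),
      details = list(optimisms = optimisms, failures = nFail,
                     seed = as.integer(seed), model = model0))
}

#' Leave-one-feature-out ablation
#'
#' Refits the model without each selected feature in turn and reports the
#' optimism-corrected and apparent AUC with the differences from the full
#' model; the final row is the full model. All rows use the same seed so the
#' bootstrap resamples are shared.
#'
#' @param table feature table.
#' @param selected selected features (>= 2).
#' @param B bootstrap resamples per row.
#' @param seed integer seed.
#' @return data.frame with one row per removed feature plus the full model.
#' @export
ablationAnalysis <- function(table, selected, B = 100L, seed = 1L) {
  if (length(selected) < 2) stop("need at least 2 selected features")
  full <- optimismCorrectedAuc(table, fixedModelProcedure(selected), B, seed)
  rows <- lapply(selected, function(f) {
    rep <- optimismCorrectedAuc(table,
                                fixedModelProcedure(setdiff(selected, f)),
                                B, seed)
    data.frame(removed = f,
               corrected_auc = rep@correctedAuc,
               corrected_diff = rep@correctedAuc - full@correctedAuc,
               apparent_auc = rep@apparentAuc,
               apparent_diff = rep@apparentAuc - full@apparentAuc)
  })
  rbind(do.call(rbind, rows),
        data.frame(removed = "(full model)",
                   corrected_auc = full@correctedAuc, corrected_diff = NA,
                   apparent_auc = full@apparentAuc, apparent_diff = NA))
}

#' Size-subset analysis
#'
#' Re-runs the full validation on the rows whose nodule diameter lies in the
#' closed interval \code{sizeRange} (mm).
#'
#' @param table feature table with a \code{size_mm} column.
#' @param sizeRange numeric(2) closed diameter interval in mm.
#' @param procedure modeling procedure.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return a \linkS4class{ValidationReport} for the subset.
#' @export
subsetAnalysis <- function(table, sizeRange = c(7, 15), procedure,
                           B = 100L, seed = 1L) {
  if (!"size_mm" %in% names(table)) stop("table needs a size_mm column")
  sub <- table[!is.na(table$size_mm) & table$size_mm >= sizeRange[1] &
                 table$size_mm <= sizeRange[2], , drop = FALSE]
  pos <- labelsAsLogical(sub$label)
  if (!any(pos) || all(pos))
    stop("size subset contains a single class; cannot validate")
  optimismCorrectedAuc(sub, procedure, B = B, seed = seed)
}
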