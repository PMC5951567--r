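#' Cohort inclusion filter
#'
#' Applies the nodule-selection rules: largest diameter within the closed
#' interval [7, 30] mm, a single nodule per case, and a known benign/malignant
#' outcome. Records failing a rule are excluded and tallied by the first
#' matching reason (missing diameter, size out of range, multiple nodules,
#' missing outcome).
#'
#' @param records data.frame with columns \code{diameter_mm}, and optionally
#'   \code{n_nodules} (default 1) and \code{outcome}.
#' @param sizeRange closed diameter interval in mm (default c(7, 30)).
#' @return list with \code{included} (the retained rows) and
#'   \code{exclusions} (named integer tally per reason).
#' @export
cohortFilter <- function(records, sizeRange = c(7, 30)) {
  reasons <- c("missing_diameter", "size_out_of_range", "multiple_nodules",
               "missing_outcome")
  tally <- setNames(integer(length(reasons)), reasons)
  if (nrow(records) == 0)
    return(list(included = records, exclusions = tally))
  d <- records$diameter_mm
  nNod <- if ("n_nodules" %in% names(records)) records$n_nodules else 1L
  outcome <- if ("outcome" %in% names(records)) records$outcome else "known"
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(d)] <- "missing_diameter"
  reason[is.na(reason) & (d < sizeRange[1] | d > sizeRange[2])] <-
    "size_out_of_range"
  reason[is.na(reason) & nNod != 1L] <- "multiple_nodules"
  reason[is.na(reason) & is.na(outcome)] <- "missing_outcome"
  tt <- table(factor(reason, levels = reasons))
  tally[] <- as.integer(tt)
  list(included = records[is.na(reason), , drop = FALSE], exclusions = tally)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact p-value (the sum of hypergeometric probabilities of all
#' tables, with the observed margins, that are no more probable than the
#' observed one).
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be 2 x 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("validation error: counts must be non-negative integers")
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(1)
  fisher.test(tab)$p.value
}

#' Two-sample t-test from summary statistics
#'
#' Student's t-test (pooled variance) computed from per-group mean, SD and n.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
tTestFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Group comparison tests
#'
#' Dispatches to Fisher's exact test for a 2 x 2 count matrix and to the
#' summary-statistics t-test for a list with elements \code{mean1, sd1, n1,
#' mean2, sd2, n2}.
#'
#' @param x a 2 x 2 matrix or a named list of summary statistics.
#' @return list with \code{test} ("fisher" or "t") and \code{p}.
#' @export
groupTests <- function(x) {
  if (is.matrix(x)) {
    list(test = "fisher", p = fisherExact2x2(x))
  } else if (is.list(x)) {
    r <- do.call(tTestFromSummary, x)
    list(test = "t", p = r$p)
  } else stop("x must be a 2 x 2 matrix or a summary-statistics list")
}
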