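silaFromProportions <- function(p) {
  K <- length(p)
  if (K < 2) stop("SILA needs at least 2 ordinated categories")
  if (any(p < -1e-12))
    stop("validation error: negative proportions")
  if (abs(sum(p) - 1) > 1e-9)
    stop("validation error: proportions must sum to 1")
  Fi <- cumsum(p)[seq_len(K - 1)]
  sum((1 - Fi)^2) / (K - 1)
}

#' @describeIn silaScore SILA of a raw proportion vector. With cumulative
#'   sums F_i over the ordination (most indolent first), the score is
#'   (1/(K-1)) * sum_{i=1}^{K-1} (1 - F_i)^2: the squared-CDF (Cramer-von
#'   Mises type) distance from the fully indolent degenerate distribution,
#'   normalized so the fully aggressive distribution scores exactly 1.
#' @export
setMethod("silaScore", "numeric", function(dist) silaFromProportions(dist))

#' @describeIn silaScore SILA of an \linkS4class{ExemplarDistribution}
#'   (proportions taken in ordination order).
#' @export
setMethod("silaScore", "ExemplarDistribution", function(dist) {
  if (dist@n <= 0) stop("empty distribution")
  silaFromProportions(dist@proportions)
})

#' Local SILA summary
#'
#' SILA score of each element's neighborhood exemplar distribution, summarized
#' as the mean and the standardized skewness across elements (zero-variance
#' input has skew 0).
#'
#' @param dists list of proportion vectors or
#'   \linkS4class{ExemplarDistribution} objects (one per element, e.g. mesh
#'   vertex).
#' @return list with \code{mean}, \code{skew} and the per-element
#'   \code{scores}.
#' @export
localSila <- function(dists) {
  if (length(dists) == 0) stop("validation error: no element distributions")
  scores <- vapply(dists, function(d) {
    if (is(d, "ExemplarDistribution")) silaScore(d) else silaFromProportions(d)
  }, numeric(1))
  list(mean = mean(scores), skew = popSkew(scores), scores = scores)
}
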