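#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname accessors
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname accessors
#' @export
setGeneric("vertexAreas", function(x) standardGeneric("vertexAreas"))

#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' @rdname accessors
#' @export
setGeneric("ordination", function(x) standardGeneric("ordination"))

#' @rdname accessors
#' @export
setGeneric("exemplarLabels", function(x) standardGeneric("exemplarLabels"))

#' @rdname accessors
#' @export
setGeneric("selectionFrequencies",
           function(x) standardGeneric("selectionFrequencies"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("apparentAuc", function(x) standardGeneric("apparentAuc"))

#' @rdname accessors
#' @export
setGeneric("correctedAuc", function(x) standardGeneric("correctedAuc"))

#' @rdname accessors
#' @export
setGeneric("optimism", function(x) standardGeneric("optimism"))

#' Compute the SILA aggression score
#'
#' Maps an ordinated exemplar distribution onto [0, 1] via a Cramer-von Mises
#' type squared-CDF distance from the fully indolent reference distribution;
#' see \code{\link{silaScore,numeric-method}} for the formula.
#'
#' @param dist an \linkS4class{ExemplarDistribution} or a numeric vector of
#'   proportions in ordination order (most indolent first).
#' @return numeric scalar in [0, 1].
#' @export
setGeneric("silaScore", function(dist) standardGeneric("silaScore"))
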