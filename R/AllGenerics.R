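#' @rdname Spectrum-class
#' @param object,x a \linkS4class{Spectrum} (or other object).
#' @export
setGeneric("peakMatrix", function(x) standardGeneric("peakMatrix"))

#' @rdname Spectrum-class
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname Spectrum-class
#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))

#' @rdname Spectrum-class
#' @export
setGeneric("peakCount", function(x) standardGeneric("peakCount"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname FingerprintMatrix-class
#' @export
setGeneric("fingerprintBits", function(x) standardGeneric("fingerprintBits"))

#' @rdname FingerprintMatrix-class
#' @export
setGeneric("bitNames", function(x) standardGeneric("bitNames"))

#' @rdname ActivityNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname ActivityNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname ExtendedConfusion-class
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
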