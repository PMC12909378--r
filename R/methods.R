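#' Construct a Spectrum
#'
#' @param mz numeric vector of fragment m/z values (Da).
#' @param intensity numeric vector of fragment intensities, same length.
#' @param compoundId compound identifier.
#' @param precursorMz precursor m/z (Da) or \code{NA}.
#' @param collisionEnergy collision energy or \code{NA}.
#' @param adduct adduct string or \code{NA}.
#' @param ionizationMode \code{"positive"} (default) or \code{"negative"}.
#'
#' @return a \linkS4class{Spectrum} with peaks sorted by ascending m/z.
#' @examples
#' sp <- Spectrum(c(150.1, 80.05), c(0.4, 1), compoundId = "CMP1",
#'                precursorMz = 180.1)
#' peakMatrix(sp)
#' @export
Spectrum <- function(mz, intensity, compoundId = NA_character_,
                     precursorMz = NA_real_, collisionEnergy = NA_real_,
                     adduct = NA_character_,
                     ionizationMode = c("positive", "negative")) {
    stopifnot(length(mz) == length(intensity))
    ionizationMode <- match.arg(ionizationMode)
    o <- order(mz)
    pk <- cbind(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
    new("Spectrum", compoundId = as.character(compoundId),
        precursorMz = as.numeric(precursorMz), peaks = pk,
        collisionEnergy = as.numeric(collisionEnergy),
        adduct = as.character(adduct), ionizationMode = ionizationMode)
}

#' @rdname Spectrum-class
#' @export
setMethod("peakMatrix", "Spectrum", function(x) x@peaks)

#' @rdname Spectrum-class
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)

#' @rdname Spectrum-class
#' @export
setMethod("compoundId", "Spectrum", function(x) x@compoundId)

#' @rdname Spectrum-class
#' @export
setMethod("peakCount", "Spectrum", function(x) nrow(x@peaks))

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum '%s': %d peaks, precursor m/z %s [%s mode]\n",
                object@compoundId, nrow(object@peaks),
                ifelse(is.na(object@precursorMz), "NA",
                       sprintf("%.4f", object@precursorMz)),
                object@ionizationMode))
    invisible(object)
})

#' Construct a SimilarityMatrix
#'
#' @param values square numeric matrix of scores in \code{[0, 1]}.
#' @param ids compound identifiers; defaults to the matrix row names.
#' @param metric name of the producing metric.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(values, ids = rownames(values),
                             metric = NA_character_) {
    if (is.null(ids))
        stop("ids must be given or present as row names")
    values <- as.matrix(values)
    dimnames(values) <- list(ids, ids)
    # symmetrize away floating-point asymmetry below validity tolerance
    values <- (values + t(values)) / 2
    new("SimilarityMatrix", ids = as.character(ids), values = values,
        metric = as.character(metric))
}

#' @rdname SimilarityMatrix-class
#' @param x a \linkS4class{SimilarityMatrix}.
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

#' @rdname SimilarityMatrix-class
#' @export
setMethod("compoundIds", "SimilarityMatrix", function(x) x@ids)

#' @rdname SimilarityMatrix-class
#' @param i,j,...,drop subsetting by compound id or index; always returns a
#'   \linkS4class{SimilarityMatrix} over the selected compounds.
#' @export
setMethod("[", "SimilarityMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- x@ids
    SimilarityMatrix(x@values[i, i, drop = FALSE], metric = x@metric)
})

setMethod("show", "SimilarityMatrix", function(object) {
    n <- length(object@ids)
    cat(sprintf("SimilarityMatrix: %d compounds, %s off-diagonal pairs (metric: %s)\n",
                n, format(pairCount(n), big.mark = ","), object@metric))
    invisible(object)
})

#' Number of distinct off-diagonal pairs among n items
#'
#' The number of distinct unordered compound pairs a pairwise similarity
#' computation over \code{n} items produces: \code{n * (n - 1) / 2}.
#'
#' @param n number of items.
#' @return pair count as a double (exact for any practical n).
#' @examples
#' pairCount(3413)
#' @export
pairCount <- function(n) {
    stopifnot(n >= 0)
    n * (n - 1) / 2
}

#' Construct a FingerprintMatrix
#'
#' @param bits 0/1 matrix (compounds x bits) with named columns.
#' @param ids compound identifiers; defaults to row names.
#' @param bitNames bit names; defaults to column names.
#' @return a \linkS4class{FingerprintMatrix}.
#' @export
FingerprintMatrix <- function(bits, ids = rownames(bits),
                              bitNames = colnames(bits)) {
    bits <- as.matrix(bits)
    storage.mode(bits) <- "integer"
    if (is.null(ids))
        ids <- sprintf("CMP%05d", seq_len(nrow(bits)))
    if (is.null(bitNames))
        bitNames <- sprintf("bit%04d", seq_len(ncol(bits)))
    dimnames(bits) <- list(ids, bitNames)
    new("FingerprintMatrix", ids = as.character(ids), bits = bits)
}

#' @rdname FingerprintMatrix-class
#' @param x a \linkS4class{FingerprintMatrix}.
#' @export
setMethod("fingerprintBits", "FingerprintMatrix", function(x) x@bits)

#' @rdname FingerprintMatrix-class
#' @export
setMethod("bitNames", "FingerprintMatrix", function(x) colnames(x@bits))

#' @rdname FingerprintMatrix-class
#' @export
setMethod("compoundIds", "FingerprintMatrix", function(x) x@ids)

setMethod("show", "FingerprintMatrix", function(object) {
    cat(sprintf("FingerprintMatrix: %d compounds x %d bits (density %.3f)\n",
                nrow(object@bits), ncol(object@bits),
                if (length(object@bits)) mean(object@bits) else NA_real_))
    invisible(object)
})

#' @rdname ActivityNetwork-class
#' @param x an \linkS4class{ActivityNetwork}.
#' @export
setMethod("networkNodes", "ActivityNetwork", function(x) x@nodes)

#' @rdname ActivityNetwork-class
#' @export
setMethod("networkEdges", "ActivityNetwork", function(x) x@edges)

setMethod("show", "ActivityNetwork", function(object) {
    deg <- table(factor(c(object@edges$from, object@edges$to),
                        levels = object@nodes$id))
    cat(sprintf(paste0("ActivityNetwork: %d nodes (%d active), %d edges, ",
                       "%d unconnected [threshold %.2f%s]\n"),
                nrow(object@nodes), sum(object@nodes$label),
                nrow(object@edges), sum(deg == 0L), object@threshold,
                if (is.na(object@topK)) "" else sprintf(", top-%d", object@topK)))
    invisible(object)
})

#' @rdname ExtendedConfusion-class
#' @param x an \linkS4class{ExtendedConfusion}.
#' @export
setMethod("confusionCounts", "ExtendedConfusion", function(x) x@counts)

setMethod("show", "ExtendedConfusion", function(object) {
    cat("ExtendedConfusion:\n")
    print(object@counts)
    invisible(object)
})

setMethod("show", "ConformalModel", function(object) {
    cat(sprintf(paste0("ConformalModel (Mondrian ICP): %d features, ",
                       "calibration n = %d active / %d inactive\n"),
                length(object@featureNames),
                length(object@calibrationScores$active),
                length(object@calibrationScores$inactive)))
    invisible(object)
})
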