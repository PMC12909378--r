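#' @import methods
NULL

#' Tandem (MS2) mass spectrum
#'
#' A fragment-ion peak list with its precursor m/z and acquisition
#' metadata. Peaks are stored as a two-column matrix (\code{mz},
#' \code{intensity}) kept sorted by ascending m/z; the precursor m/z is
#' required only by operations that use precursor-shifted peak matching
#' (the modified cosine).
#'
#' @slot compoundId character(1), compound identifier (by convention the
#'   14-character first block of an InChIKey).
#' @slot precursorMz numeric(1), precursor m/z in Da, or \code{NA} when
#'   unknown.
#' @slot peaks numeric matrix with columns \code{mz} and \code{intensity}.
#' @slot collisionEnergy numeric(1), collision energy or \code{NA}.
#' @slot adduct character(1), adduct annotation or \code{NA}.
#' @slot ionizationMode character(1), \code{"positive"} or
#'   \code{"negative"}.
#'
#' @seealso [Spectrum()] for the constructor, [normalizePeaks()],
#'   [greedyCosine()].
#' @exportClass Spectrum
setClass("Spectrum",
    representation(
        compoundId = "character",
        precursorMz = "numeric",
        peaks = "matrix",
        collisionEnergy = "numeric",
        adduct = "character",
        ionizationMode = "character"
    ),
    prototype(
        compoundId = NA_character_,
        precursorMz = NA_real_,
        peaks = matrix(numeric(0), ncol = 2L,
                       dimnames = list(NULL, c("mz", "intensity"))),
        collisionEnergy = NA_real_,
        adduct = NA_character_,
        ionizationMode = "positive"
    )
)

setValidity("Spectrum", function(object) {
    msgs <- character(0)
    pk <- object@peaks
    if (!is.numeric(pk) || ncol(pk) != 2L)
        msgs <- c(msgs, "peaks must be a numeric matrix with 2 columns")
    else {
        if (!identical(colnames(pk), c("mz", "intensity")))
            msgs <- c(msgs, "peak columns must be named 'mz', 'intensity'")
        if (nrow(pk) > 0L) {
            if (any(!is.finite(pk)))
                msgs <- c(msgs, "peaks must be finite")
            else {
                if (any(pk[, "mz"] <= 0))
                    msgs <- c(msgs, "all m/z values must be positive")
                if (any(pk[, "intensity"] < 0))
                    msgs <- c(msgs, "intensities must be non-negative")
                if (is.unsorted(pk[, "mz"]))
                    msgs <- c(msgs, "peaks must be sorted by ascending m/z")
            }
        }
    }
    if (length(object@precursorMz) != 1L)
        msgs <- c(msgs, "precursorMz must have length 1")
    else if (!is.na(object@precursorMz) && object@precursorMz <= 0)
        msgs <- c(msgs, "precursorMz must be positive")
    if (!object@ionizationMode %in% c("positive", "negative"))
        msgs <- c(msgs, "ionizationMode must be 'positive' or 'negative'")
    if (length(msgs)) msgs else TRUE
})

#' Symmetric pairwise similarity matrix
#'
#' Stores pairwise similarity scores in \code{[0, 1]} between identified
#' compounds, as produced by [pairwiseMatrix()] or imported with
#' [loadExternalMatrix()]. Feeds both network construction and the
#' similarity-feature vectors of the conformal classifier.
#'
#' @slot ids character vector of compound identifiers (row/column order).
#' @slot values numeric symmetric matrix of scores in \code{[0, 1]}.
#' @slot metric character(1), name of the metric that produced the scores.
#'
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
    representation(ids = "character", values = "matrix",
                   metric = "character"),
    prototype(ids = character(0),
              values = matrix(numeric(0), 0, 0),
              metric = NA_character_)
)

setValidity("SimilarityMatrix", function(object) {
    msgs <- character(0)
    v <- object@values
    n <- length(object@ids)
    if (nrow(v) != n || ncol(v) != n)
        msgs <- c(msgs, "values must be a square matrix matching ids")
    if (anyDuplicated(object@ids))
        msgs <- c(msgs, "ids must be unique")
    if (n > 0L) {
        if (any(!is.finite(v)))
            msgs <- c(msgs, "all similarity values must be finite")
        else {
            if (min(v) < 0 || max(v) > 1 + 1e-12)
                msgs <- c(msgs, "similarity values must lie in [0, 1]")
            if (max(abs(v - t(v))) > 1e-9)
                msgs <- c(msgs, "similarity matrix must be symmetric")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Binary molecular fingerprint matrix
#'
#' Compounds-by-bits binary matrix, the input representation of the
#' fingerprint-based activity classifier and of Tanimoto fingerprint
#' networking.
#'
#' @slot ids character vector of compound identifiers (rows).
#' @slot bits integer matrix of 0/1 values; column names are the bit names.
#'
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
    representation(ids = "character", bits = "matrix"),
    prototype(ids = character(0),
              bits = matrix(integer(0), 0, 0))
)

setValidity("FingerprintMatrix", function(object) {
    msgs <- character(0)
    b <- object@bits
    if (nrow(b) != length(object@ids))
        msgs <- c(msgs, "number of rows must match ids")
    if (anyDuplicated(object@ids))
        msgs <- c(msgs, "ids must be unique")
    if (is.null(colnames(b)) && ncol(b) > 0L)
        msgs <- c(msgs, "bit columns must be named")
    if (anyDuplicated(colnames(b)))
        msgs <- c(msgs, "bit names must be unique")
    if (length(b) && !all(b %in% c(0L, 1L)))
        msgs <- c(msgs, "bits must be 0/1")
    if (length(msgs)) msgs else TRUE
})

#' Thresholded activity network
#'
#' An undirected similarity network whose nodes are labeled compounds
#' (active = 1, inactive = 0) and whose edges carry similarity weights at
#' or above the construction threshold. Compounds with inconclusive labels
#' are excluded before construction.
#'
#' @slot nodes data.frame with columns \code{id} (character) and
#'   \code{label} (integer 0/1).
#' @slot edges data.frame with columns \code{from}, \code{to} (character,
#'   \code{from < to}) and \code{weight} (numeric).
#' @slot threshold numeric(1), similarity threshold used at construction.
#' @slot topK integer(1), per-node edge-filtering cap, or \code{NA} when
#'   all passing edges are kept.
#'
#' @exportClass ActivityNetwork
setClass("ActivityNetwork",
    representation(nodes = "data.frame", edges = "data.frame",
                   threshold = "numeric", topK = "integer"),
    prototype(nodes = data.frame(id = character(0), label = integer(0)),
              edges = data.frame(from = character(0), to = character(0),
                                 weight = numeric(0)),
              threshold = 0, topK = NA_integer_)
)

setValidity("ActivityNetwork", function(object) {
    msgs <- character(0)
    nd <- object@nodes; ed <- object@edges
    if (!all(c("id", "label") %in% names(nd)))
        msgs <- c(msgs, "nodes needs columns id, label")
    else {
        if (anyDuplicated(nd$id))
            msgs <- c(msgs, "node ids must be unique")
        if (!all(nd$label %in% c(0L, 1L)))
            msgs <- c(msgs, "node labels must be 0/1")
    }
    if (!all(c("from", "to", "weight") %in% names(ed)))
        msgs <- c(msgs, "edges needs columns from, to, weight")
    else if (nrow(ed)) {
        if (any(ed$from == ed$to))
            msgs <- c(msgs, "self-edges are not allowed")
        if (any(ed$from >= ed$to))
            msgs <- c(msgs, "edges must be stored once with from < to")
        if (!all(c(ed$from, ed$to) %in% nd$id))
            msgs <- c(msgs, "edge endpoints must be nodes")
        if (any(ed$weight < object@threshold - 1e-12))
            msgs <- c(msgs, "edge weights must be >= threshold")
    }
    if (length(msgs)) msgs else TRUE
})

#' Mondrian inductive conformal classifier
#'
#' Holds the fitted base classifier together with per-class calibration
#' nonconformity scores. Class-conditional (Mondrian) calibration gives a
#' per-class error guarantee at any chosen significance level under
#' exchangeability.
#'
#' @slot baseModel fitted base-classifier object (opaque; used through the
#'   learner's predict function).
#' @slot learner list with \code{fit} and \code{predictProb} functions (see
#'   [randomForestLearner()]).
#' @slot calibrationScores named list with elements \code{active} and
#'   \code{inactive}, each a numeric vector of nonconformity scores sorted
#'   decreasingly.
#' @slot featureNames character vector naming the feature columns the base
#'   model was trained on.
#' @slot seed integer(1) seed used for the internal calibration split.
#'
#' @exportClass ConformalModel
setClass("ConformalModel",
    representation(baseModel = "ANY", learner = "list",
                   calibrationScores = "list", featureNames = "character",
                   seed = "integer")
)

setValidity("ConformalModel", function(object) {
    cs <- object@calibrationScores
    msgs <- character(0)
    if (!all(c("active", "inactive") %in% names(cs)))
        msgs <- c(msgs, "calibrationScores needs 'active' and 'inactive'")
    else {
        for (cl in c("active", "inactive")) {
            s <- cs[[cl]]
            if (!length(s))
                msgs <- c(msgs, sprintf("no calibration scores for class '%s'", cl))
            else if (is.unsorted(rev(s)))
                msgs <- c(msgs, sprintf("calibration scores for '%s' must be sorted decreasingly", cl))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Extended confusion counts
#'
#' Classical TP/FP/TN/FN counts extended with the numbers of
#' network-unconnected positives (NCP) and negatives (NCN), the quantities
#' that drive the modified true/false positive rates.
#'
#' @slot counts named integer vector with elements TP, FP, TN, FN, NCP, NCN.
#'
#' @exportClass ExtendedConfusion
setClass("ExtendedConfusion", representation(counts = "integer"))

setValidity("ExtendedConfusion", function(object) {
    nm <- c("TP", "FP", "TN", "FN", "NCP", "NCN")
    if (!identical(names(object@counts), nm))
        return(sprintf("counts must be named %s", paste(nm, collapse = ", ")))
    if (any(object@counts < 0L))
        return("counts must be non-negative")
    TRUE
})
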