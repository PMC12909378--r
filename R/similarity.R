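# Spectral and fingerprint similarity metrics and pairwise matrices.
#
# The greedy peak-pairing scheme is shared by the plain and the
# precursor-shift-aware (modified) cosine: candidate peak pairs within the
# m/z tolerance are ranked by descending intensity product (ties by
# ascending m/z in a, then b) and accepted greedily with each peak used at
# most once. The score is the matched intensity-product sum divided by the
# product of the two spectra's Euclidean intensity norms, so it lies in
# [0, 1] and is scale-invariant.

.greedyMatchScore <- function(pkA, pkB, tol, shifts) {
    mzA <- pkA[, "mz"];  iA <- pkA[, "intensity"]
    mzB <- pkB[, "mz"];  iB <- pkB[, "intensity"]
    cand <- NULL
    for (d in shifts) {
        hit <- which(abs(outer(mzA, mzB + d, "-")) <= tol, arr.ind = TRUE)
        cand <- rbind(cand, hit)
    }
    if (is.null(cand) || nrow(cand) == 0L) return(0)
    cand <- unique(cand)
    i <- cand[, 1L]; j <- cand[, 2L]
    prod <- iA[i] * iB[j]
    o <- order(-prod, mzA[i], mzB[j])
    usedA <- logical(length(mzA)); usedB <- logical(length(mzB))
    tot <- 0
    for (k in o) {
        a <- i[k]; b <- j[k]
        if (!usedA[a] && !usedB[b]) {
            usedA[a] <- TRUE; usedB[b] <- TRUE
            tot <- tot + prod[k]
        }
    }
    min(1, tot / (sqrt(sum(iA^2)) * sqrt(sum(iB^2))))
}

#' Greedy cosine spectral similarity
#'
#' Cosine similarity over greedily matched fragment peaks: peaks of the two
#' spectra are paired when their m/z values differ by at most \code{tol},
#' each peak used at most once, pairs accepted in order of decreasing
#' intensity product.
#'
#' @param a,b \linkS4class{Spectrum} objects with at least one peak each.
#' @param tol peak-matching tolerance in Da (default 0.2).
#' @return score in \code{[0, 1]}.
#' @seealso [modifiedCosine()], [pairwiseMatrix()]
#' @export
greedyCosine <- function(a, b, tol = 0.2) {
    stopifnot(is(a, "Spectrum"), is(b, "Spectrum"), tol > 0)
    if (peakCount(a) == 0L || peakCount(b) == 0L)
        stop("cannot score an empty spectrum")
    .greedyMatchScore(a@peaks, b@peaks, tol, shifts = 0)
}

#' Modified cosine spectral similarity
#'
#' Like [greedyCosine()], but fragment peaks may additionally be paired at
#' an offset equal to the precursor-mass difference between the two
#' spectra, so that fragments shifted by a structural modification still
#' match. Both precursor m/z values are required.
#'
#' @inheritParams greedyCosine
#' @return score in \code{[0, 1]}.
#' @export
modifiedCosine <- function(a, b, tol = 0.2) {
    stopifnot(is(a, "Spectrum"), is(b, "Spectrum"), tol > 0)
    if (peakCount(a) == 0L || peakCount(b) == 0L)
        stop("cannot score an empty spectrum")
    if (is.na(precursorMz(a)) || is.na(precursorMz(b)))
        stop("modified cosine requires both precursor m/z values")
    delta <- precursorMz(a) - precursorMz(b)
    .greedyMatchScore(a@peaks, b@peaks, tol, shifts = unique(c(0, delta)))
}

#' Tanimoto similarity of binary fingerprints
#'
#' \code{|a AND b| / |a OR b|} over the set bits of two equal-length binary
#' fingerprint vectors.
#'
#' @param fa,fb 0/1 vectors of equal length, each with at least one set
#'   bit.
#' @return score in \code{[0, 1]}.
#' @export
tanimoto <- function(fa, fb) {
    if (length(fa) != length(fb))
        stop("fingerprint length mismatch: ", length(fa), " vs ", length(fb))
    fa <- as.logical(fa); fb <- as.logical(fb)
    u <- sum(fa | fb)
    if (u == 0L) stop("both fingerprints are empty")
    sum(fa & fb) / u
}

#' Pairwise similarity matrix
#'
#' Computes all n(n-1)/2 pairwise similarities over a set of compounds:
#' spectral metrics (\code{"greedy_cosine"}, \code{"modified_cosine"})
#' over a named list of \linkS4class{Spectrum} objects, or
#' \code{"tanimoto"} over a \linkS4class{FingerprintMatrix}. Externally
#' computed similarity matrices (e.g. from a learned spectral-similarity
#' model) are imported with [loadExternalMatrix()] instead.
#'
#' @param x named list of \linkS4class{Spectrum} objects, or a
#'   \linkS4class{FingerprintMatrix} for \code{metric = "tanimoto"}.
#' @param metric one of \code{"greedy_cosine"}, \code{"modified_cosine"},
#'   \code{"tanimoto"}.
#' @param mzTolerance peak-matching tolerance in Da for the spectral
#'   metrics (default 0.2).
#' @return a \linkS4class{SimilarityMatrix} with unit diagonal.
#' @export
pairwiseMatrix <- function(x, metric = c("greedy_cosine", "modified_cosine",
                                         "tanimoto", "external"),
                           mzTolerance = 0.2) {
    metric <- match.arg(metric)
    if (metric == "external")
        stop("external similarities are precomputed; use loadExternalMatrix()")
    if (metric == "tanimoto") {
        stopifnot(is(x, "FingerprintMatrix"))
        b <- x@bits
        rs <- rowSums(b)
        if (any(rs == 0))
            stop("fingerprints with no set bits: ",
                 paste(x@ids[rs == 0], collapse = ", "))
        inter <- tcrossprod(b)
        un <- outer(rs, rs, "+") - inter
        v <- inter / un
        diag(v) <- 1
        return(SimilarityMatrix(v, ids = x@ids, metric = metric))
    }
    stopifnot(is.list(x), all(vapply(x, is, logical(1), "Spectrum")))
    ids <- names(x)
    if (is.null(ids))
        ids <- vapply(x, compoundId, character(1))
    n <- length(x)
    fun <- if (metric == "greedy_cosine") greedyCosine else modifiedCosine
    v <- diag(nrow = n)
    if (n > 1L) {
        for (i in seq_len(n - 1L)) {
            for (j in (i + 1L):n) {
                s <- fun(x[[i]], x[[j]], tol = mzTolerance)
                v[i, j] <- s
                v[j, i] <- s
            }
        }
    }
    SimilarityMatrix(v, ids = ids, metric = metric)
}

#' Load a precomputed similarity matrix
#'
#' Reads a delimited square similarity matrix (first row and first column
#' carry compound ids), validates symmetry (within 1e-6) and the
#' \code{[0, 1]} range, and reorders rows/columns to the requested id
#' order.
#'
#' @param path path to a tab- or comma-delimited matrix file.
#' @param ids compound ids to select and order by; default keeps the file
#'   order.
#' @param metric metric name to record (default \code{"external"}).
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
loadExternalMatrix <- function(path, ids = NULL, metric = "external") {
    if (!file.exists(path)) stop("file not found: ", path)
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                             check.names = FALSE)
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m))
        stop("matrix is not square: ", nrow(m), " x ", ncol(m))
    if (!identical(rownames(m), colnames(m)))
        stop("row ids do not match column ids")
    if (any(!is.finite(m))) stop("non-finite similarity values present")
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("similarity out of [0, 1] at (%s, %s): %g",
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                     m[bad[1, , drop = FALSE]]))
    asym <- abs(m - t(m))
    if (max(asym) > 1e-6) {
        w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
        stop(sprintf("matrix asymmetric beyond 1e-6 at (%s, %s)",
                     rownames(m)[w[1]], colnames(m)[w[2]]))
    }
    if (is.null(ids)) ids <- rownames(m)
    missing <- setdiff(ids, rownames(m))
    if (length(missing))
        stop("ids missing from matrix file: ", paste(missing, collapse = ", "))
    SimilarityMatrix(m[ids, ids, drop = FALSE], ids = ids, metric = metric)
}

#' Write a similarity matrix to a delimited file
#'
#' @param x a \linkS4class{SimilarityMatrix}.
#' @param path output path (tab-delimited, values with 6 decimals).
#' @return \code{path}, invisibly.
#' @export
writeSimilarityMatrix <- function(x, path) {
    stopifnot(is(x, "SimilarityMatrix"))
    v <- format(round(x@values, 6), nsmall = 6, trim = TRUE,
                scientific = FALSE)
    lines <- c(paste(c("id", x@ids), collapse = "\t"),
               vapply(seq_along(x@ids), function(i)
                   paste(c(x@ids[i], v[i, ]), collapse = "\t"), character(1)))
    writeLines(lines, path)
    invisible(path)
}
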