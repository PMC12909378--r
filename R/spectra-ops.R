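#' Normalize a spectrum to its base peak
#'
#' Divides all intensities by the base-peak (maximum) intensity so the most
#' intense fragment has relative intensity 1. Peak order is preserved.
#'
#' @param s a \linkS4class{Spectrum} with at least one peak of positive
#'   intensity.
#' @return the normalized \linkS4class{Spectrum}.
#' @export
normalizePeaks <- function(s) {
    stopifnot(is(s, "Spectrum"))
    pk <- s@peaks
    if (nrow(pk) == 0L) stop("cannot normalize an empty spectrum")
    bp <- max(pk[, "intensity"])
    if (bp <= 0) stop("cannot normalize: all intensities are zero")
    s@peaks[, "intensity"] <- pk[, "intensity"] / bp
    s
}

#' Basic spectrum hygiene
#'
#' Drops zero-intensity peaks, removes peaks beyond the precursor window
#' (m/z greater than precursor + \code{precursorWindow}, when the precursor
#' is known), and normalizes to the base peak. The window default keeps
#' the precursor ion itself while discarding implausible super-precursor
#' fragments.
#'
#' @param s a \linkS4class{Spectrum}.
#' @param precursorWindow Da allowed above the precursor m/z (default 0.5).
#' @return the cleaned, normalized \linkS4class{Spectrum}.
#' @export
cleanSpectrum <- function(s, precursorWindow = 0.5) {
    stopifnot(is(s, "Spectrum"))
    pk <- s@peaks
    keep <- pk[, "intensity"] > 0
    if (!is.na(s@precursorMz))
        keep <- keep & pk[, "mz"] <= s@precursorMz + precursorWindow
    if (!any(keep))
        stop("no peaks survive cleaning for spectrum '", s@compoundId, "'")
    s@peaks <- pk[keep, , drop = FALSE]
    normalizePeaks(s)
}

#' Average replicate spectra of one compound
#'
#' Merges spectra of the same compound (for example acquisitions at
#' different collision energies) into one consensus spectrum. Each input is
#' normalized, all peaks are pooled and merged by single-linkage within the
#' m/z tolerance in ascending-m/z order; a merged peak's m/z is the
#' intensity-weighted mean and its intensity the arithmetic mean of the
#' normalized intensities across all input spectra (a spectrum lacking the
#' peak contributes 0). The result is normalized to its base peak.
#'
#' @param group list of \linkS4class{Spectrum} objects sharing a compound
#'   id.
#' @param mzTolerance peak-merging tolerance in Da (default 0.01).
#' @return one merged \linkS4class{Spectrum}; its precursor m/z is the mean
#'   of the available precursor values and its collision energy is dropped.
#' @export
averageSpectra <- function(group, mzTolerance = 0.01) {
    if (!length(group)) stop("cannot average an empty group of spectra")
    stopifnot(all(vapply(group, is, logical(1), "Spectrum")),
              mzTolerance > 0)
    ids <- vapply(group, compoundId, character(1))
    if (length(unique(ids)) != 1L)
        stop("mixed compound ids in averaging group: ",
             paste(unique(ids), collapse = ", "))
    group <- lapply(group, normalizePeaks)
    mz <- unlist(lapply(group, function(s) s@peaks[, "mz"]))
    int <- unlist(lapply(group, function(s) s@peaks[, "intensity"]))
    o <- order(mz)
    mz <- mz[o]; int <- int[o]
    # single-linkage clusters: break where the ascending-m/z gap > tol
    cl <- cumsum(c(1L, as.integer(diff(mz) > mzTolerance)))
    mzM <- vapply(split(seq_along(mz), cl), function(ix)
        sum(mz[ix] * int[ix]) / sum(int[ix]), numeric(1))
    intM <- vapply(split(int, cl), sum, numeric(1)) / length(group)
    prec <- vapply(group, precursorMz, numeric(1))
    prec <- if (all(is.na(prec))) NA_real_ else mean(prec, na.rm = TRUE)
    normalizePeaks(Spectrum(mzM, intM, compoundId = ids[1],
        precursorMz = prec, adduct = group[[1]]@adduct,
        ionizationMode = group[[1]]@ionizationMode))
}

#' Spectrum quality filter
#'
#' A spectrum passes when it carries at least \code{minPeaks} peaks whose
#' relative intensity exceeds \code{minRelIntensity} — the rule used to
#' decide which detected features have MS2 evidence worth interpreting
#' (default: five or more peaks above 5\% relative intensity).
#'
#' @param s a normalized \linkS4class{Spectrum}.
#' @param minPeaks minimum number of qualifying peaks (default 5).
#' @param minRelIntensity strict relative-intensity floor (default 0.05).
#' @return logical(1).
#' @export
qualityFilter <- function(s, minPeaks = 5L, minRelIntensity = 0.05) {
    stopifnot(is(s, "Spectrum"))
    sum(s@peaks[, "intensity"] > minRelIntensity) >= minPeaks
}

#' Aggregate raw activity reports into per-compound labels
#'
#' Groups raw assay reports by the 14-character compound-id block and
#' resolves conflicting reports precautionarily: a compound is
#' \code{"active"} in an assay if any report calls it active, otherwise
#' \code{"inactive"} if any report calls it inactive, otherwise
#' \code{"inconclusive"}. Assays with no report for a compound are simply
#' absent from the output.
#'
#' @param records data.frame with columns \code{compound_id}, \code{assay},
#'   \code{label} (values among active/inactive/inconclusive).
#' @return data.frame with columns \code{compound_id} (14-char block),
#'   \code{assay}, \code{label}; one row per (compound, assay) with at
#'   least one report.
#' @export
cleanLabels <- function(records) {
    stopifnot(is.data.frame(records),
              all(c("compound_id", "assay", "label") %in% names(records)))
    if (!nrow(records))
        return(data.frame(compound_id = character(0), assay = character(0),
                          label = character(0)))
    ok <- c("active", "inactive", "inconclusive")
    if (!all(records$label %in% ok))
        stop("labels must be among: ", paste(ok, collapse = ", "))
    id <- substr(as.character(records$compound_id), 1L, 14L)
    key <- paste(id, records$assay, sep = "\r")
    agg <- vapply(split(records$label, key), function(l) {
        if (any(l == "active")) "active"
        else if (any(l == "inactive")) "inactive"
        else "inconclusive"
    }, character(1))
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    out <- data.frame(
        compound_id = vapply(parts, `[`, character(1), 1L),
        assay = vapply(parts, `[`, character(1), 2L),
        label = unname(agg))
    out[order(out$compound_id, out$assay), , drop = FALSE]
}

#' Binary label vector for one assay
#'
#' Extracts a named 0/1 vector (active = 1) for one assay from cleaned
#' labels, dropping inconclusive compounds, as required before network
#' construction or model training.
#'
#' @param labels cleaned label data.frame (see [cleanLabels()]).
#' @param assay assay name.
#' @return named integer vector of 0/1 over the conclusive compounds.
#' @export
labelVector <- function(labels, assay) {
    sub <- labels[labels$assay == assay & labels$label != "inconclusive", ]
    if (!nrow(sub)) stop("no conclusive labels for assay '", assay, "'")
    stats::setNames(as.integer(sub$label == "active"), sub$compound_id)
}

#' Stratified train/test split
#'
#' Splits labeled compounds into train and test sets preserving the
#' active/inactive proportions for one assay within one compound per
#' class, never placing excluded ids in the test set, deterministically
#' under the seed.
#'
#' @param labels named 0/1 vector (see [labelVector()]).
#' @param testFraction fraction of compounds in the test set, in (0, 1).
#' @param seed integer seed.
#' @param excludeIds ids that must stay out of the test set.
#' @return list with character vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(labels, testFraction, seed, excludeIds = character(0)) {
    stopifnot(testFraction > 0, testFraction < 1)
    ids <- names(labels)
    if (is.null(ids) || anyDuplicated(ids))
        stop("labels must be a named vector with unique ids")
    test <- character(0)
    .withSeed(seed, {
        for (cls in sort(unique(labels))) {
            clsIds <- ids[labels == cls]
            if (length(clsIds) < 2L)
                stop("class ", cls, " has fewer than 2 members")
            nTest <- round(length(clsIds) * testFraction)
            pool <- sort(setdiff(clsIds, excludeIds))
            nTest <- min(nTest, length(pool))
            test <- c(test, sample(pool, nTest))
        }
    })
    list(train = setdiff(ids, test), test = sort(test))
}
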