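#' Read MS2 spectra from MSP or MGF files
#'
#' Parses the plain-text spectral library dialects in common use: NIST-style
#' MSP (\code{NAME:}/\code{PRECURSORMZ:}/\code{Num Peaks:} records separated
#' by blank lines) and MGF (\code{BEGIN IONS}/\code{PEPMASS=}/\code{END
#' IONS} blocks). Metadata fields are populated when present and left
#' \code{NA} otherwise; peaks are sorted by ascending m/z.
#'
#' @param path path to an MSP or MGF file.
#' @param format \code{"msp"} or \code{"mgf"}.
#' @return list of \linkS4class{Spectrum} objects, one per record. An empty
#'   file yields an empty list with a warning.
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, format = c("msp", "mgf")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\r$", "", lines)
    if (!any(nzchar(trimws(lines)))) {
        warning("empty spectrum file: ", path)
        return(list())
    }
    if (format == "msp") .readMsp(lines) else .readMgf(lines)
}

.parsePeakLines <- function(txt, rec) {
    if (!length(txt))
        return(matrix(numeric(0), ncol = 2L,
                      dimnames = list(NULL, c("mz", "intensity"))))
    parts <- strsplit(trimws(txt), "[\t ;]+")
    bad <- vapply(parts, function(p)
        length(p) < 2L || anyNA(suppressWarnings(as.numeric(p[1:2]))),
        logical(1))
    if (any(bad))
        stop(sprintf("malformed peak line in record %d: '%s'",
                     rec, txt[which(bad)[1]]))
    mz <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    int <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    cbind(mz = mz, intensity = int)
}

.numOrNA <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (length(v) != 1L) NA_real_ else v
}

.readMsp <- function(lines) {
    blank <- !nzchar(trimws(lines))
    grp <- cumsum(c(TRUE, blank[-length(blank)])) # record grouping
    recs <- split(lines[!blank], grp[!blank])
    out <- vector("list", length(recs))
    for (k in seq_along(recs)) {
        rl <- recs[[k]]
        isField <- grepl("^[A-Za-z][A-Za-z0-9_ ]*:", rl)
        fields <- rl[isField]
        keys <- toupper(trimws(sub(":.*$", "", fields)))
        vals <- trimws(sub("^[^:]*:", "", fields))
        getf <- function(key) {
            i <- match(key, keys)
            if (is.na(i)) NA_character_ else vals[i]
        }
        np <- .numOrNA(getf("NUM PEAKS"))
        if (is.na(np))
            stop(sprintf("malformed MSP record %d: missing 'Num Peaks'", k))
        peakTxt <- rl[!isField]
        if (length(peakTxt) != np)
            stop(sprintf("malformed MSP record %d: expected %d peaks, found %d",
                         k, np, length(peakTxt)))
        pk <- .parsePeakLines(peakTxt, k)
        mode <- tolower(getf("IONMODE"))
        if (is.na(mode) || !mode %in% c("positive", "negative"))
            mode <- "positive"
        out[[k]] <- Spectrum(pk[, "mz"], pk[, "intensity"],
            compoundId = getf("NAME"),
            precursorMz = .numOrNA(getf("PRECURSORMZ")),
            collisionEnergy = .numOrNA(getf("COLLISIONENERGY")),
            adduct = getf("PRECURSORTYPE"),
            ionizationMode = mode)
    }
    out
}

.readMgf <- function(lines) {
    begin <- grep("^BEGIN IONS\\s*$", lines)
    end <- grep("^END IONS\\s*$", lines)
    if (length(begin) != length(end) || any(end < begin))
        stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
    out <- vector("list", length(begin))
    for (k in seq_along(begin)) {
        rl <- lines[(begin[k] + 1L):(end[k] - 1L)]
        rl <- rl[nzchar(trimws(rl))]
        isField <- grepl("^[A-Za-z][A-Za-z0-9_]*=", rl)
        fields <- rl[isField]
        keys <- toupper(sub("=.*$", "", fields))
        vals <- trimws(sub("^[^=]*=", "", fields))
        getf <- function(key) {
            i <- match(key, keys)
            if (is.na(i)) NA_character_ else vals[i]
        }
        pk <- .parsePeakLines(rl[!isField], k)
        pep <- getf("PEPMASS")
        if (!is.na(pep)) # PEPMASS may carry "mz intensity"
            pep <- strsplit(pep, "\\s+")[[1]][1]
        charge <- getf("CHARGE")
        mode <- if (!is.na(charge) && grepl("-", charge, fixed = TRUE))
            "negative" else "positive"
        out[[k]] <- Spectrum(pk[, "mz"], pk[, "intensity"],
            compoundId = getf("TITLE"),
            precursorMz = .numOrNA(pep),
            collisionEnergy = .numOrNA(getf("COLLISIONENERGY")),
            adduct = getf("ADDUCT"),
            ionizationMode = mode)
    }
    out
}

#' Write spectra to an MSP or MGF file
#'
#' @param spectra list of \linkS4class{Spectrum} objects.
#' @param path output file path.
#' @param format \code{"msp"} or \code{"mgf"}.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(spectra, path, format = c("msp", "mgf")) {
    format <- match.arg(format)
    con <- file(path, "w")
    on.exit(close(con))
    for (sp in spectra) {
        stopifnot(is(sp, "Spectrum"))
        pk <- sp@peaks
        peakLines <- sprintf("%.6f %.6g", pk[, "mz"], pk[, "intensity"])
        if (format == "msp") {
            hdr <- c(sprintf("NAME: %s", sp@compoundId))
            if (!is.na(sp@precursorMz))
                hdr <- c(hdr, sprintf("PRECURSORMZ: %.6f", sp@precursorMz))
            if (!is.na(sp@adduct))
                hdr <- c(hdr, sprintf("PRECURSORTYPE: %s", sp@adduct))
            if (!is.na(sp@collisionEnergy))
                hdr <- c(hdr, sprintf("COLLISIONENERGY: %g", sp@collisionEnergy))
            hdr <- c(hdr, sprintf("IONMODE: %s", sp@ionizationMode),
                     sprintf("Num Peaks: %d", nrow(pk)))
            writeLines(c(hdr, peakLines, ""), con)
        } else {
            hdr <- c("BEGIN IONS", sprintf("TITLE=%s", sp@compoundId))
            if (!is.na(sp@precursorMz))
                hdr <- c(hdr, sprintf("PEPMASS=%.6f", sp@precursorMz))
            hdr <- c(hdr, sprintf("CHARGE=1%s",
                if (sp@ionizationMode == "negative") "-" else "+"))
            writeLines(c(hdr, peakLines, "END IONS", ""), con)
        }
    }
    invisible(path)
}
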