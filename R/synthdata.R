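# Seeded synthetic-data generator.
#
# Compounds carry binary fingerprints; a small set of hidden
# "toxicophore" bits determines activity (OR over the set, then label
# flips at labelNoise). Each set bit emits fixed characteristic fragment
# peaks, so spectral similarity correlates with fingerprint (structural)
# similarity — the assumption the networking approach relies on. All
# draws are governed by the config seed.

#' Synthetic-data configuration
#'
#' @param nCompounds number of compounds.
#' @param nBits fingerprint length; the first bits are background
#'   structure bits, plus the toxicophore bits.
#' @param toxicophoreBits indices of the activity-determining bits.
#' @param labelNoise probability of flipping a label, in \code{[0, 0.5)}.
#' @param bitPrevalence prevalence of each background bit.
#' @param peaksPerBit characteristic fragment peaks emitted per set bit.
#' @param mzJitterSd Gaussian m/z jitter of emitted peaks (Da).
#' @param noisePeaks uniform-random noise peaks added per spectrum.
#' @param activeFractionTarget target fraction of active compounds;
#'   toxicophore-bit prevalence is derived from it.
#' @param seed integer seed governing every draw.
#' @return a \code{synthConfig} list.
#' @export
synthConfig <- function(nCompounds = 200L, nBits = 64L,
                        toxicophoreBits = 1:3, labelNoise = 0.02,
                        bitPrevalence = 0.1, peaksPerBit = 2L,
                        mzJitterSd = 0.005, noisePeaks = 2L,
                        activeFractionTarget = 0.16, seed = 1L) {
    stopifnot(nCompounds >= 2, nBits >= 1,
              all(toxicophoreBits >= 1), all(toxicophoreBits <= nBits),
              labelNoise >= 0, labelNoise < 0.5,
              activeFractionTarget > 0, activeFractionTarget < 1)
    structure(list(nCompounds = as.integer(nCompounds),
                   nBits = as.integer(nBits),
                   toxicophoreBits = as.integer(toxicophoreBits),
                   labelNoise = labelNoise,
                   bitPrevalence = bitPrevalence,
                   peaksPerBit = as.integer(peaksPerBit),
                   mzJitterSd = mzJitterSd,
                   noisePeaks = as.integer(noisePeaks),
                   activeFractionTarget = activeFractionTarget,
                   seed = as.integer(seed)),
              class = "synthConfig")
}

#' Generate fingerprints and activity labels
#'
#' Draws per-bit Bernoulli fingerprints (toxicophore bits at the
#' prevalence implied by the target active fraction, background bits at
#' \code{bitPrevalence}), labels each compound active when any
#' toxicophore bit is set, then flips labels with probability
#' \code{labelNoise}. Redraws (fresh prevalence draw) until the realized
#' active fraction is within ±5 percentage points of the target.
#'
#' @param cfg a [synthConfig()].
#' @return list with \code{fingerprints} (a
#'   \linkS4class{FingerprintMatrix}), \code{labels} (named 0/1 vector)
#'   and \code{trueLabels} (before noise).
#' @export
generateCompounds <- function(cfg) {
    stopifnot(inherits(cfg, "synthConfig"))
    k <- length(cfg$toxicophoreBits)
    qTox <- 1 - (1 - cfg$activeFractionTarget)^(1 / k)
    n <- cfg$nCompounds
    ids <- sprintf("SYN%05d", seq_len(n))
    res <- .withSeed(cfg$seed, {
        out <- NULL
        for (attempt in 1:50) {
            prev <- rep(cfg$bitPrevalence, cfg$nBits)
            prev[cfg$toxicophoreBits] <- qTox
            bits <- vapply(prev, function(p) stats::rbinom(n, 1L, p),
                           integer(n))
            empty <- rowSums(bits) == 0L
            if (any(empty)) { # guarantee a non-empty fingerprint
                bg <- setdiff(seq_len(cfg$nBits), cfg$toxicophoreBits)
                if (!length(bg)) bg <- seq_len(cfg$nBits)
                bits[cbind(which(empty),
                           sample(bg, sum(empty), replace = TRUE))] <- 1L
            }
            trueLab <- as.integer(
                rowSums(bits[, cfg$toxicophoreBits, drop = FALSE]) > 0L)
            flip <- stats::rbinom(n, 1L, cfg$labelNoise) == 1L
            lab <- as.integer(ifelse(flip, 1L - trueLab, trueLab))
            if (abs(mean(lab) - cfg$activeFractionTarget) <= 0.05) {
                out <- list(
                    fingerprints = FingerprintMatrix(bits, ids = ids),
                    labels = stats::setNames(lab, ids),
                    trueLabels = stats::setNames(trueLab, ids))
                break
            }
        }
        out
    })
    if (is.null(res))
        stop(sprintf("active fraction %.2f unattainable under this configuration",
                     cfg$activeFractionTarget))
    res
}

# fixed characteristic peak table: bit b, replicate j -> (mz, intensity),
# a deterministic hash of the indices so no fixture files are needed
.bitPeak <- function(bit, j) {
    c(mz = 50 + 450 * .hash01(bit, j),
      intensity = 0.3 + 0.7 * .hash01(bit, j, 7))
}

#' Generate the MS2 spectrum of one fingerprint
#'
#' Each set bit emits its characteristic peaks (a fixed hash of the bit
#' index into 50-500 Da) with Gaussian m/z jitter, plus uniform-random
#' noise peaks; the precursor m/z is a deterministic function of the bit
#' pattern. Uses the current RNG stream — call within
#' [generateSpectra()] for seeded generation.
#'
#' @param fpRow 0/1 fingerprint vector with at least one set bit.
#' @param cfg a [synthConfig()].
#' @param compoundId id given to the spectrum.
#' @return a normalized \linkS4class{Spectrum}.
#' @export
generateSpectrum <- function(fpRow, cfg, compoundId = NA_character_) {
    set <- which(as.integer(fpRow) == 1L)
    if (!length(set)) stop("cannot generate a spectrum for an empty fingerprint")
    pk <- do.call(rbind, lapply(set, function(b)
        t(vapply(seq_len(cfg$peaksPerBit), function(j) .bitPeak(b, j),
                 numeric(2)))))
    mz <- pk[, 1L] + stats::rnorm(nrow(pk), 0, cfg$mzJitterSd)
    int <- pk[, 2L]
    if (cfg$noisePeaks > 0L) {
        mz <- c(mz, stats::runif(cfg$noisePeaks, 50, 500))
        int <- c(int, stats::runif(cfg$noisePeaks, 0.01, 0.2))
    }
    prec <- 500 + sum(vapply(set, function(b) 10 * .hash01(b, 9999),
                             numeric(1)))
    normalizePeaks(Spectrum(mz, int, compoundId = compoundId,
                            precursorMz = prec))
}

#' Generate spectra for a set of compounds
#'
#' @param fingerprints a \linkS4class{FingerprintMatrix}.
#' @param cfg a [synthConfig()]; the seed governs jitter and noise.
#' @return named list of \linkS4class{Spectrum} objects.
#' @export
generateSpectra <- function(fingerprints, cfg) {
    stopifnot(is(fingerprints, "FingerprintMatrix"))
    b <- fingerprintBits(fingerprints)
    ids <- compoundIds(fingerprints)
    .withSeed(cfg$seed + 1L, {
        stats::setNames(lapply(seq_len(nrow(b)), function(i)
            generateSpectrum(b[i, ], cfg, compoundId = ids[i])), ids)
    })
}

#' Generate a wastewater-style feature table
#'
#' Draws influent intensities log-normally and effluent intensities as
#' \code{influent * r} with \code{r} drawn inside the requested fate band
#' (persistent: ±20\%; transformation product: at least +50\%; other:
#' strictly between or below the bands), so [classifyFate()] recovers the
#' generated fates exactly.
#'
#' @param nFeatures number of features.
#' @param fractionPersistent,fractionTp fractions of persistent and
#'   transformation-product features (must sum to at most 1).
#' @param cfg a [synthConfig()] (seed source).
#' @return data.frame with columns \code{feature_id}, \code{mz},
#'   \code{rt}, \code{intensity_influent}, \code{intensity_effluent},
#'   \code{fate}.
#' @export
generateFeatureTable <- function(nFeatures, fractionPersistent, fractionTp,
                                 cfg) {
    stopifnot(fractionPersistent >= 0, fractionTp >= 0)
    if (fractionPersistent + fractionTp > 1)
        stop("fate fractions sum above 1")
    nP <- round(nFeatures * fractionPersistent)
    nT <- round(nFeatures * fractionTp)
    nO <- nFeatures - nP - nT
    fate <- c(rep("persistent", nP), rep("transformation_product", nT),
              rep("other", nO))
    .withSeed(cfg$seed + 2L, {
        fate <- sample(fate)
        inf <- exp(stats::rnorm(nFeatures, 12, 1))
        r <- numeric(nFeatures)
        r[fate == "persistent"] <- stats::runif(nP, 0.81, 1.19)
        r[fate == "transformation_product"] <- stats::runif(nT, 1.51, 3)
        isO <- fate == "other"
        lowBand <- stats::runif(nO) < 0.7
        r[isO] <- ifelse(lowBand, stats::runif(nO, 0.05, 0.79),
                         stats::runif(nO, 1.21, 1.49))
        data.frame(feature_id = sprintf("FT%05d", seq_len(nFeatures)),
                   mz = stats::runif(nFeatures, 100, 800),
                   rt = stats::runif(nFeatures, 0.5, 15),
                   intensity_influent = inf,
                   intensity_effluent = inf * r,
                   fate = fate)
    })
}

#' Ready-made synthetic study conditions
#'
#' Four bundles used throughout the package's evaluation:
#' \describe{
#'   \item{mn-demo}{250 compounds with 3 toxicophore bits among 203
#'     sparse structure bits (label noise 0.02, active fraction 0.16);
#'     spectra plus a greedy-cosine similarity matrix for network
#'     recovery.}
#'   \item{cp-validity}{3200 exchangeable compounds split into a
#'     1000-compound proper-training panel, 200 calibration and 2000 test
#'     rows; features are Tanimoto similarities to the panel (label noise
#'     0.1). The panel anchors the features and is disjoint from
#'     calibration and test rows, so those remain exchangeable.}
#'   \item{fp-recovery}{600 compounds, 64 bits, 3 toxicophore bits, label
#'     noise 0.05 — the fingerprint-classifier recovery setting.}
#'   \item{wastewater}{968 features with the persistent /
#'     transformation-product strata at 40/968 and 153/968.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a named list; contents depend on the preset (see details).
#' @export
synthPreset <- function(name = c("mn-demo", "cp-validity", "fp-recovery",
                                 "wastewater"), seed = 1L) {
    name <- match.arg(name)
    seed <- as.integer(seed)
    switch(name,
    "mn-demo" = {
        cfg <- synthConfig(nCompounds = 250L, nBits = 203L,
                           toxicophoreBits = 1:3, labelNoise = 0.02,
                           bitPrevalence = 0.025, peaksPerBit = 2L,
                           mzJitterSd = 0.005, noisePeaks = 2L,
                           activeFractionTarget = 0.16, seed = seed)
        cmp <- generateCompounds(cfg)
        spectra <- generateSpectra(cmp$fingerprints, cfg)
        sim <- pairwiseMatrix(spectra, "greedy_cosine", mzTolerance = 0.2)
        list(config = cfg, fingerprints = cmp$fingerprints,
             labels = cmp$labels, spectra = spectra, similarity = sim)
    },
    "cp-validity" = {
        cfg <- synthConfig(nCompounds = 3200L, nBits = 128L,
                           toxicophoreBits = 1:4, labelNoise = 0.1,
                           bitPrevalence = 0.08,
                           activeFractionTarget = 0.3, seed = seed)
        cmp <- generateCompounds(cfg)
        ids <- compoundIds(cmp$fingerprints)
        panel <- ids[1:1000]
        # Tanimoto of every compound to the panel, computed blockwise
        # (equivalent to similarityFeatures() on the full pairwise matrix)
        b <- fingerprintBits(cmp$fingerprints)
        pb <- b[panel, , drop = FALSE]
        inter <- tcrossprod(b, pb)
        feats <- inter / (outer(rowSums(b), rowSums(pb), "+") - inter)
        dimnames(feats) <- list(ids, panel)
        list(config = cfg, labels = cmp$labels, features = feats,
             panelIdx = 1:1000, calibrationIdx = 1001:1200,
             testIdx = 1201:3200)
    },
    "fp-recovery" = {
        cfg <- synthConfig(nCompounds = 600L, nBits = 64L,
                           toxicophoreBits = 1:3, labelNoise = 0.05,
                           bitPrevalence = 0.1,
                           activeFractionTarget = 0.16, seed = seed)
        cmp <- generateCompounds(cfg)
        list(config = cfg, fingerprints = cmp$fingerprints,
             labels = cmp$labels, trueLabels = cmp$trueLabels)
    },
    "wastewater" = {
        cfg <- synthConfig(nCompounds = 2L, seed = seed)
        list(config = cfg,
             features = generateFeatureTable(968L, 40 / 968, 153 / 968, cfg))
    })
}

#' Write a synthetic bundle to disk
#'
#' Writes whichever components a preset bundle contains in the package's
#' interchange formats: spectra as MSP, fingerprints and feature table as
#' tab-delimited text, labels as a compound/assay/label table, the
#' similarity matrix via [writeSimilarityMatrix()].
#'
#' @param bundle a list from [synthPreset()].
#' @param dir output directory (created if needed).
#' @param assay assay name used in the label table.
#' @return the directory, invisibly.
#' @export
writeSynthBundle <- function(bundle, dir, assay = "AhR") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(bundle$spectra))
        writeSpectra(bundle$spectra, file.path(dir, "spectra.msp"), "msp")
    if (!is.null(bundle$fingerprints)) {
        b <- fingerprintBits(bundle$fingerprints)
        utils::write.table(b, file.path(dir, "fingerprints.tsv"),
                           sep = "\t", quote = FALSE)
    }
    if (!is.null(bundle$labels)) {
        lab <- data.frame(compound_id = names(bundle$labels), assay = assay,
                          label = ifelse(bundle$labels == 1L, "active",
                                         "inactive"))
        utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    if (!is.null(bundle$similarity))
        writeSimilarityMatrix(bundle$similarity,
                              file.path(dir, "similarity.tsv"))
    if (!is.null(bundle$features))
        utils::write.table(bundle$features, file.path(dir, "features.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
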