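# Fingerprint-based activity classifier: feature cleaning + gradient
# boosting with stratified CV and randomized hyperparameter search.

#' Clean fingerprint features
#'
#' Three-stage cleaning before model training: (1) drop zero-variance
#' (constant) bits; (2) drop near-zero-variance bits, i.e. those whose
#' most-common/second-most-common value frequency ratio exceeds
#' \code{nzvFreqRatio} while the percentage of distinct values is below
#' \code{nzvUniquePct} (caret's convention); (3) iteratively resolve bit
#' pairs with absolute Pearson correlation at or above \code{corrCutoff},
#' dropping from each pair the bit with the larger mean absolute
#' correlation to the remaining bits (ties broken by dropping the
#' later-named bit). Highest-correlation pairs are resolved first.
#'
#' @param fp a \linkS4class{FingerprintMatrix} with at least 2 compounds.
#' @param nzvFreqRatio near-zero-variance frequency-ratio cutoff
#'   (default 19, i.e. 95/5).
#' @param nzvUniquePct near-zero-variance distinct-value percentage cutoff
#'   (default 10).
#' @param corrCutoff absolute-correlation cutoff (default 0.9).
#' @return list with \code{fingerprints} (the cleaned
#'   \linkS4class{FingerprintMatrix}) and \code{report} (lists
#'   \code{removedZeroVariance}, \code{removedNearZeroVariance} and a
#'   data.frame \code{removedCorrelated} with columns \code{kept},
#'   \code{dropped}, \code{correlation}).
#' @export
cleanFeatures <- function(fp, nzvFreqRatio = 19, nzvUniquePct = 10,
                          corrCutoff = 0.9) {
    stopifnot(is(fp, "FingerprintMatrix"))
    b <- fingerprintBits(fp)
    n <- nrow(b)
    if (n < 2L) stop("need at least 2 compounds to clean features")
    ones <- colSums(b)
    zv <- colnames(b)[ones == 0L | ones == n]
    keep <- setdiff(colnames(b), zv)
    # near-zero variance on the binary columns that remain
    cnt1 <- ones[keep]
    major <- pmax(cnt1, n - cnt1)
    freqRatio <- major / (n - major)
    uniquePct <- 100 * 2 / n
    nzv <- keep[freqRatio > nzvFreqRatio & uniquePct < nzvUniquePct]
    keep <- setdiff(keep, nzv)
    removedCorr <- data.frame(kept = character(0), dropped = character(0),
                              correlation = numeric(0))
    if (length(keep) >= 2L) {
        cm <- abs(stats::cor(b[, keep, drop = FALSE]))
        diag(cm) <- 0
        while (length(keep) >= 2L && max(cm) >= corrCutoff) {
            w <- which(cm == max(cm), arr.ind = TRUE)
            # deterministic pair choice: earliest (row, col) in bit order
            w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
            w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE][1L, ]
            i <- rownames(cm)[w[1L]]; j <- colnames(cm)[w[2L]]
            mi <- mean(cm[i, setdiff(keep, i)])
            mj <- mean(cm[j, setdiff(keep, j)])
            drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
            kept <- if (drop == i) j else i
            removedCorr <- rbind(removedCorr, data.frame(
                kept = kept, dropped = drop,
                correlation = stats::cor(b[, i], b[, j])))
            keep <- setdiff(keep, drop)
            cm <- cm[keep, keep, drop = FALSE]
        }
    }
    if (!length(keep)) stop("feature cleaning removed every bit")
    list(fingerprints = FingerprintMatrix(b[, keep, drop = FALSE],
                                          ids = compoundIds(fp)),
         report = list(removedZeroVariance = zv,
                       removedNearZeroVariance = nzv,
                       removedCorrelated = removedCorr))
}

# draw one hyperparameter configuration from the declared search grid
.sampleConfig <- function(grid) {
    data.frame(
        max_depth = sample(grid$max_depth, 1L),
        eta = 10^stats::runif(1L, log10(min(grid$eta)), log10(max(grid$eta))),
        nrounds = sample(grid$nrounds, 1L),
        subsample = stats::runif(1L, min(grid$subsample), max(grid$subsample)),
        colsample_bytree = stats::runif(1L, min(grid$colsample_bytree),
                                        max(grid$colsample_bytree)),
        scale_pos_weight = sample(grid$scale_pos_weight, 1L))
}

.defaultSearchGrid <- function(labels) list(
    max_depth = 2:8,
    eta = c(0.01, 0.3),
    nrounds = seq(50L, 300L, by = 25L),
    subsample = c(0.5, 1),
    colsample_bytree = c(0.5, 1),
    scale_pos_weight = c(1, max(1, sum(labels == 0L) / sum(labels == 1L))))

.fitBooster <- function(x, y, cfg, seed) {
    xgboost::xgboost(
        x, factor(y, levels = c(0L, 1L)), objective = "binary:logistic",
        nrounds = cfg$nrounds, max_depth = cfg$max_depth,
        learning_rate = cfg$eta, subsample = cfg$subsample,
        colsample_bytree = cfg$colsample_bytree,
        scale_pos_weight = cfg$scale_pos_weight,
        nthreads = 1L, seed = as.integer(seed))
}

#' Train the fingerprint activity classifier
#'
#' Randomized hyperparameter search for a gradient-boosted tree
#' classifier: \code{nTrials} configurations are drawn from a declared
#' grid (tree depth, learning rate, boosting rounds, row/column
#' subsampling, class weight) and scored by mean ROC-AUC over stratified
#' cross-validation folds; the best configuration is refit on all data.
#' Deterministic under \code{seed}.
#'
#' @param fp a cleaned \linkS4class{FingerprintMatrix}.
#' @param labels 0/1 vector (active = 1), one per compound.
#' @param nTrials number of random-search trials (default 20; large
#'   studies conventionally use 500).
#' @param cvFolds number of stratified folds (default 5).
#' @param seed integer seed.
#' @param searchGrid optional named list overriding the default search
#'   ranges (see \code{ToxScreenMS:::.defaultSearchGrid}).
#' @return object of class \code{fingerprintModel}: list with the fitted
#'   \code{booster}, \code{bestConfig}, per-trial \code{cvSummary}, the
#'   winning configuration's out-of-fold \code{cvPredictions} (a
#'   prediction data.frame usable as a training evaluation, e.g. with
#'   [fprAtTpr()]), \code{bitNames} and \code{seed}.
#' @export
trainClassifier <- function(fp, labels, nTrials = 20L, cvFolds = 5L,
                            seed = 1L, searchGrid = NULL) {
    stopifnot(is(fp, "FingerprintMatrix"), cvFolds >= 2L, nTrials >= 1L)
    x <- fingerprintBits(fp)
    storage.mode(x) <- "double"
    y <- as.integer(labels)
    stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
    if (!any(y == 1L) || !any(y == 0L)) stop("need both classes to train")
    grid <- searchGrid %||% .defaultSearchGrid(y)
    res <- .withSeed(seed, {
        folds <- caret::createFolds(factor(y), k = cvFolds)
        if (any(vapply(folds, function(f) length(unique(y[f])) < 2L,
                       logical(1))))
            stop("a fold is missing a class; need more data per class")
        configs <- do.call(rbind, replicate(nTrials, .sampleConfig(grid),
                                            simplify = FALSE))
        cvAuc <- vapply(seq_len(nTrials), function(tr) {
            mean(vapply(folds, function(holdOut) {
                fit <- .fitBooster(x[-holdOut, , drop = FALSE], y[-holdOut],
                                   configs[tr, ], seed)
                .rankAuc(stats::predict(fit, x[holdOut, , drop = FALSE]),
                         y[holdOut])
            }, numeric(1)))
        }, numeric(1))
        list(configs = configs, cvAuc = cvAuc, folds = folds)
    })
    best <- which.max(res$cvAuc)
    # out-of-fold probabilities of the winning configuration: an unbiased
    # training evaluation, e.g. for deriving decision thresholds at a
    # target recall
    oof <- rep(NA_real_, length(y))
    for (holdOut in res$folds) {
        fit <- .fitBooster(x[-holdOut, , drop = FALSE], y[-holdOut],
                           res$configs[best, ], seed)
        oof[holdOut] <- stats::predict(fit, x[holdOut, , drop = FALSE])
    }
    booster <- .fitBooster(x, y, res$configs[best, ], seed)
    structure(list(booster = booster,
                   bestConfig = res$configs[best, ],
                   cvSummary = cbind(trial = seq_len(nTrials), res$configs,
                                     cvAuc = res$cvAuc),
                   cvAuc = res$cvAuc[best],
                   cvPredictions = data.frame(
                       id = compoundIds(fp), probability = oof,
                       connected = TRUE),
                   bitNames = colnames(x), seed = as.integer(seed)),
              class = "fingerprintModel")
}

#' @export
print.fingerprintModel <- function(x, ...) {
    cat(sprintf("fingerprintModel: %d bits, best CV ROC-AUC %.3f (depth %d, eta %.3g, %d rounds)\n",
                length(x$bitNames), x$cvAuc, x$bestConfig$max_depth,
                x$bestConfig$eta, x$bestConfig$nrounds))
    invisible(x)
}

#' Predict activity probabilities from fingerprints
#'
#' @param model a \code{fingerprintModel} from [trainClassifier()].
#' @param fp a \linkS4class{FingerprintMatrix} whose bit names match the
#'   training schema (order-insensitive; missing or extra bits are an
#'   error).
#' @return named numeric vector of activity probabilities in
#'   \code{[0, 1]}.
#' @export
predictProba <- function(model, fp) {
    stopifnot(inherits(model, "fingerprintModel"),
              is(fp, "FingerprintMatrix"))
    have <- bitNames(fp)
    missing <- setdiff(model$bitNames, have)
    extra <- setdiff(have, model$bitNames)
    if (length(missing) || length(extra))
        stop("fingerprint schema mismatch; missing: [",
             paste(missing, collapse = ", "), "], extra: [",
             paste(extra, collapse = ", "), "]")
    x <- fingerprintBits(fp)[, model$bitNames, drop = FALSE]
    storage.mode(x) <- "double"
    stats::setNames(stats::predict(model$booster, x), compoundIds(fp))
}
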