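# Independent reference implementations used as oracles. These are kept
# deliberately naive (exhaustive enumeration, plain loops) and separate
# from the package's code paths.

# Exhaustive optimal-assignment cosine: maximizes the matched
# intensity-product sum over ALL one-to-one peak assignments drawn from
# the candidate pairs (within tol of any allowed shift). Feasible for
# spectra with <= 5 peaks.
oracleAssignmentScore <- function(a, b, tol, shifts = 0) {
    pkA <- peakMatrix(a); pkB <- peakMatrix(b)
    cand <- NULL
    for (d in shifts) {
        for (i in seq_len(nrow(pkA)))
            for (j in seq_len(nrow(pkB)))
                if (abs(pkA[i, "mz"] - (pkB[j, "mz"] + d)) <= tol)
                    cand <- rbind(cand, c(i, j))
    }
    if (is.null(cand)) return(0)
    cand <- unique(cand)
    prods <- pkA[cand[, 1], "intensity"] * pkB[cand[, 2], "intensity"]
    best <- 0
    recurse <- function(k, usedA, usedB, acc) {
        if (k > nrow(cand)) {
            best <<- max(best, acc)
            return(invisible(NULL))
        }
        recurse(k + 1, usedA, usedB, acc)  # skip pair k
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!(i %in% usedA) && !(j %in% usedB))
            recurse(k + 1, c(usedA, i), c(usedB, j), acc + prods[k])
    }
    recurse(1, integer(0), integer(0), 0)
    best / (sqrt(sum(pkA[, "intensity"]^2)) * sqrt(sum(pkB[, "intensity"]^2)))
}

# Naive leave-one-out voting: per-node recomputation straight from the
# similarity matrix, no network object, no top-k.
naiveLooVote <- function(sim, labels, threshold, scheme = "majority") {
    ids <- intersect(compoundIds(sim), names(labels))
    v <- similarityValues(sim)[ids, ids]
    do.call(rbind, lapply(ids, function(me) {
        nb <- setdiff(ids[v[me, ids] >= threshold], me)
        if (!length(nb))
            return(data.frame(id = me, probability = NA_real_,
                              connected = FALSE))
        w <- v[me, nb]
        y <- labels[nb]
        p <- if (scheme == "majority") mean(y) else sum(w[y == 1]) / sum(w)
        data.frame(id = me, probability = p, connected = TRUE)
    }))
}

# Independent modified-ROC area: plain threshold enumeration with loop
# counting, anchored at (0,0) and extended horizontally to mFPR = 1.
oracleMrocAuc <- function(preds, labels) {
    probs <- preds$probability[preds$connected]
    thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
    pts <- matrix(0, length(thr), 2)
    for (k in seq_along(thr)) {
        TP <- FP <- TN <- FN <- NCP <- NCN <- 0
        for (r in seq_len(nrow(preds))) {
            y <- labels[[preds$id[r]]]
            if (!preds$connected[r]) {
                if (y == 1) NCP <- NCP + 1 else NCN <- NCN + 1
            } else if (preds$probability[r] >= thr[k]) {
                if (y == 1) TP <- TP + 1 else FP <- FP + 1
            } else {
                if (y == 1) FN <- FN + 1 else TN <- TN + 1
            }
        }
        pts[k, ] <- c(FP / (FP + TN + NCN), TP / (TP + FN + NCP))
    }
    pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
    x <- c(0, pts[, 1], 1)
    y <- c(0, pts[, 2], pts[nrow(pts), 2])
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Naive pairwise-scan feature cleaning following the declared rule.
naiveCleanBits <- function(bits, freqRatio = 19, uniquePct = 10,
                           cutoff = 0.9) {
    n <- nrow(bits)
    keep <- colnames(bits)
    for (bn in colnames(bits)) {
        x <- bits[, bn]
        if (length(unique(x)) == 1) keep <- setdiff(keep, bn)
    }
    for (bn in keep) {
        x <- bits[, bn]
        tab <- sort(table(x), decreasing = TRUE)
        fr <- if (length(tab) < 2) Inf else tab[1] / tab[2]
        up <- 100 * length(tab) / n
        if (fr > freqRatio && up < uniquePct) keep <- setdiff(keep, bn)
    }
    repeat {
        if (length(keep) < 2) break
        cm <- abs(cor(bits[, keep, drop = FALSE]))
        diag(cm) <- 0
        if (max(cm) < cutoff) break
        w <- which(cm == max(cm), arr.ind = TRUE)
        w <- w[w[, 1] < w[, 2], , drop = FALSE]
        w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
        i <- keep[w[1]]; j <- keep[w[2]]
        mi <- mean(cm[i, setdiff(keep, i)])
        mj <- mean(cm[j, setdiff(keep, j)])
        drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
        keep <- setdiff(keep, drop)
    }
    keep
}

# random small spectrum fixtures
randomSpectrum <- function(nPeaks, id = "X", precursor = NA_real_) {
    normalizePeaks(Spectrum(runif(nPeaks, 50, 500), runif(nPeaks, 0.1, 1),
                            compoundId = id, precursorMz = precursor))
}

# random prediction/label fixtures for the metric tests
randomPredFixture <- function(n, pUnconnected = 0) {
    ids <- sprintf("N%03d", seq_len(n))
    conn <- runif(n) >= pUnconnected
    labels <- setNames(sample(0:1, n, replace = TRUE), ids)
    # guarantee both classes
    labels[1] <- 1L; labels[2] <- 0L
    list(preds = data.frame(id = ids,
                            probability = ifelse(conn, round(runif(n), 2),
                                                 NA_real_),
                            connected = conn),
         labels = labels)
}
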