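# Extended confusion counting and modified ROC metrics.
#
# The modified rates keep network-unconnected compounds in the
# denominators: mTPR = TP / (TP + FN + NCP) and mFPR = FP / (FP + TN +
# NCN), so raising a similarity threshold until most nodes are isolated
# is penalized instead of rewarded.

#' Extended confusion counts at a decision threshold
#'
#' Classifies connected predictions as positive when their probability is
#' at or above the decision threshold and tallies TP/FP/TN/FN, while
#' unconnected actives and inactives are counted separately as NCP and
#' NCN.
#'
#' @param preds data.frame with columns \code{id}, \code{probability},
#'   \code{connected} (see [looPredict()]).
#' @param labels named 0/1 vector covering every prediction id.
#' @param decisionThreshold probability cutoff (inclusive).
#' @return an \linkS4class{ExtendedConfusion}.
#' @export
extendedConfusion <- function(preds, labels, decisionThreshold) {
    stopifnot(is.data.frame(preds),
              all(c("id", "probability", "connected") %in% names(preds)))
    miss <- setdiff(preds$id, names(labels))
    if (length(miss))
        stop("no label for: ", paste(utils::head(miss, 5), collapse = ", "))
    y <- as.integer(labels[preds$id])
    conn <- preds$connected
    pos <- conn & preds$probability >= decisionThreshold
    counts <- c(
        TP = sum(pos & y == 1L),
        FP = sum(pos & y == 0L),
        TN = sum(conn & !pos & y == 0L),
        FN = sum(conn & !pos & y == 1L),
        NCP = sum(!conn & y == 1L),
        NCN = sum(!conn & y == 0L))
    new("ExtendedConfusion", counts = as.integer(counts) |>
            stats::setNames(names(counts)))
}

#' Modified true positive rate
#'
#' \code{TP / (TP + FN + NCP)}: recall whose denominator also counts
#' actives left unconnected by the network.
#'
#' @param x an \linkS4class{ExtendedConfusion}.
#' @return numeric(1).
#' @export
mTPR <- function(x) {
    stopifnot(is(x, "ExtendedConfusion"))
    cc <- x@counts
    den <- cc["TP"] + cc["FN"] + cc["NCP"]
    if (den == 0L) stop("mTPR undefined: no actives")
    unname(cc["TP"] / den)
}

#' Modified false positive rate
#'
#' \code{FP / (FP + TN + NCN)}: false positive rate whose denominator also
#' counts inactives left unconnected by the network.
#'
#' @param x an \linkS4class{ExtendedConfusion}.
#' @return numeric(1).
#' @export
mFPR <- function(x) {
    stopifnot(is(x, "ExtendedConfusion"))
    cc <- x@counts
    den <- cc["FP"] + cc["TN"] + cc["NCN"]
    if (den == 0L) stop("mFPR undefined: no inactives")
    unname(cc["FP"] / den)
}

# sweep decision thresholds over the connected probabilities (plus one
# above the maximum) and return one (threshold, mFPR, mTPR) row each
.mrocPoints <- function(preds, labels) {
    probs <- preds$probability[preds$connected]
    thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
    pts <- t(vapply(thr, function(t) {
        cc <- extendedConfusion(preds, labels, t)
        c(mFPR(cc), mTPR(cc))
    }, numeric(2)))
    data.frame(threshold = thr, mfpr = pts[, 1L], mtpr = pts[, 2L])
}

#' Area under the modified ROC curve
#'
#' Sweeps the decision threshold over all observed probabilities, plots
#' (mFPR, mTPR), anchors the curve at (0, 0) and extends it horizontally
#' from its terminal point to mFPR = 1, then integrates by the trapezoidal
#' rule. Because unconnected compounds stay in both denominators, the
#' terminal mTPR is below 1 whenever actives are unconnected, capping the
#' attainable area — the intended penalty. With no unconnected compounds
#' the result equals the classical ROC-AUC.
#'
#' @inheritParams extendedConfusion
#' @return area in \code{[0, 1]}.
#' @export
mrocAuc <- function(preds, labels) {
    y <- as.integer(labels[preds$id])
    if (anyNA(y)) stop("every prediction needs a label")
    if (!any(y == 1L) || !any(y == 0L))
        stop("mROC-AUC needs both an active and an inactive compound")
    pts <- .mrocPoints(preds, labels)
    x <- c(0, pts$mfpr[order(pts$mfpr, pts$mtpr)], 1)
    yy <- c(0, pts$mtpr[order(pts$mfpr, pts$mtpr)])
    yy <- c(yy, yy[length(yy)])
    sum(diff(x) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' False positive rate at a fixed recall
#'
#' Finds the largest decision threshold whose classical true positive rate
#' reaches the target recall and reports the false positive rate there —
#' the workload metric for prioritization (e.g. FPR at 90\% recall). For
#' this comparison unconnected compounds are treated as predicted
#' negative at every threshold, so the metric is a classical rate
#' comparable across approaches with and without a connectivity notion
#' (the attainable recall is capped by the connected actives). When the
#' target is unreachable (too many actives unconnected), the point of
#' maximal recall with the lowest FPR is returned and flagged.
#'
#' @inheritParams extendedConfusion
#' @param targetTpr target recall in \code{(0, 1]}.
#' @return list with \code{fpr}, \code{achievedTpr}, \code{threshold},
#'   \code{reachable}.
#' @export
fprAtTpr <- function(preds, labels, targetTpr) {
    stopifnot(targetTpr > 0, targetTpr <= 1)
    y <- as.integer(labels[preds$id])
    if (anyNA(y)) stop("every prediction needs a label")
    if (!any(y == 1L) || !any(y == 0L))
        stop("need both an active and an inactive compound")
    conn <- preds$connected
    p <- preds$probability
    thr <- c(Inf, sort(unique(p[conn]), decreasing = TRUE))
    tpr <- vapply(thr, function(t)
        sum(conn & p >= t & y == 1L) / sum(y == 1L), numeric(1))
    fpr <- vapply(thr, function(t)
        sum(conn & p >= t & y == 0L) / sum(y == 0L), numeric(1))
    ok <- tpr >= targetTpr - 1e-12
    if (any(ok)) {
        k <- which(ok)[1L]  # thresholds are decreasing: first hit = largest
        list(fpr = fpr[k], achievedTpr = tpr[k], threshold = thr[k],
             reachable = TRUE)
    } else {
        best <- which(tpr == max(tpr))
        k <- best[which.min(fpr[best])]
        list(fpr = fpr[k], achievedTpr = tpr[k], threshold = thr[k],
             reachable = FALSE)
    }
}
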