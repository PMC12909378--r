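# Wastewater feature-fate classification and multi-approach consensus.

#' Classify feature fate between influent and effluent
#'
#' With \code{r = effluent / influent}: a feature is \code{"persistent"}
#' when its intensity change stays within ±20\% (\code{0.8 <= r <= 1.2}),
#' a \code{"transformation_product"} when the effluent intensity is at
#' least 50\% higher (\code{r >= 1.5}), and \code{"other"} otherwise. A
#' feature absent from the influent but present in the effluent is a
#' transformation product; one absent from the effluent is \code{"other"}
#' (removed). Band boundaries are inclusive.
#'
#' @param intensityInfluent,intensityEffluent non-negative intensity
#'   vectors (means over replicate injections); at least one of each pair
#'   must be positive.
#' @return character vector of fates.
#' @export
classifyFate <- function(intensityInfluent, intensityEffluent) {
    stopifnot(length(intensityInfluent) == length(intensityEffluent))
    inf <- as.numeric(intensityInfluent); eff <- as.numeric(intensityEffluent)
    if (any(!is.finite(inf)) || any(!is.finite(eff)) ||
        any(inf < 0) || any(eff < 0))
        stop("intensities must be finite and non-negative")
    both0 <- inf == 0 & eff == 0
    if (any(both0))
        stop("feature with zero intensity in both influent and effluent: index ",
             which(both0)[1])
    r <- ifelse(inf > 0, eff / inf, Inf)
    ifelse(r >= 0.8 & r <= 1.2, "persistent",
           ifelse(r >= 1.5, "transformation_product", "other"))
}

#' Consensus table across prioritization approaches
#'
#' Counts, for every subset of approaches, the features labeled active by
#' exactly that subset — the membership counts behind an UpSet plot.
#' Features for which any approach is \code{"unavailable"} (for example
#' when fingerprints could not be predicted) are tabulated in a separate
#' stratum, never silently treated as inactive. The counts partition the
#' feature list.
#'
#' @param predictions data.frame with a \code{feature_id} column and one
#'   column per approach holding \code{"active"}, \code{"inactive"} or
#'   \code{"unavailable"}.
#' @param approaches approach (column) names to tabulate.
#' @return data.frame with columns \code{members} (approach names joined
#'   by \code{"+"}; \code{""} for none; \code{"<unavailable>"} for the
#'   incomplete stratum) and \code{count}.
#' @export
consensus <- function(predictions, approaches) {
    stopifnot(is.data.frame(predictions), length(approaches) > 0)
    bad <- setdiff(approaches, names(predictions))
    if (length(bad))
        stop("unknown approach: ", paste(bad, collapse = ", "))
    pr <- predictions[, approaches, drop = FALSE]
    vals <- unlist(pr)
    if (!all(vals %in% c("active", "inactive", "unavailable")))
        stop("predictions must be active/inactive/unavailable")
    anyUnavail <- apply(pr == "unavailable", 1L, any)
    members <- apply(pr == "active", 1L, function(row)
        paste(approaches[row], collapse = "+"))
    members[anyUnavail] <- "<unavailable>"
    tab <- table(members)
    out <- data.frame(members = names(tab), count = as.integer(tab))
    out[order(-out$count, out$members), , drop = FALSE]
}

#' Score and label features at a recall-calibrated threshold
#'
#' For each approach, derives the decision threshold that achieves the
#' target recall on that approach's training evaluation (via
#' [fprAtTpr()]), then labels every feature: \code{"active"} when its
#' score is at or above the derived threshold, \code{"inactive"} below
#' it, \code{"unavailable"} when the feature could not be scored
#' (\code{NA}).
#'
#' @param features data.frame with a \code{feature_id} column.
#' @param scores numeric matrix or data.frame of per-feature scores, one
#'   column per approach; \code{NA} marks unscorable features.
#' @param trainingEval named list, one element per approach, each a list
#'   with \code{preds} (a prediction data.frame, see [looPredict()]) and
#'   \code{labels} (named 0/1 vector).
#' @param recallTarget target recall in (0, 1], default 0.9.
#' @return list with \code{predictions} (features plus one label column
#'   per approach) and \code{thresholds} (named numeric vector).
#' @export
prioritizeFeatures <- function(features, scores, trainingEval,
                               recallTarget = 0.9) {
    stopifnot(is.data.frame(features), "feature_id" %in% names(features))
    scores <- as.matrix(scores)
    approaches <- colnames(scores)
    stopifnot(!is.null(approaches), nrow(scores) == nrow(features),
              all(approaches %in% names(trainingEval)))
    thresholds <- vapply(approaches, function(ap) {
        ev <- trainingEval[[ap]]
        res <- fprAtTpr(ev$preds, ev$labels, recallTarget)
        if (!res$reachable)
            stop(sprintf("recall target %.2f unreachable for approach '%s' (max %.3f)",
                         recallTarget, ap, res$achievedTpr))
        res$threshold
    }, numeric(1))
    out <- features
    for (ap in approaches) {
        s <- scores[, ap]
        out[[ap]] <- ifelse(is.na(s), "unavailable",
                            ifelse(s >= thresholds[ap], "active", "inactive"))
    }
    list(predictions = out, thresholds = thresholds)
}
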