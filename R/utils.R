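# Internal helpers shared across modules.

# Evaluate code under a fixed RNG seed without disturbing the caller's
# RNG stream.
.withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    force(code)
}

# Deterministic uniform-ish value in [0, 1) from non-negative integers,
# platform-stable (pure double arithmetic, no RNG).
.hash01 <- function(...) {
    k <- 0
    for (v in list(...)) k <- (k * 69069 + as.numeric(v)) %% 2147483647
    ((k * 16807) %% 2147483647) / 2147483647
}

# Fast tie-aware classical ROC-AUC used only where a full pROC object
# would be overkill (inner CV loops); pROC remains the reference in tests.
.rankAuc <- function(scores, labels) {
    pos <- labels == 1L
    if (!any(pos) || all(pos)) stop("need both classes for AUC")
    r <- rank(scores, ties.method = "average")
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
        (sum(pos) * sum(!pos))
}

.assertProb <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
        stop(sprintf("%s must lie in [0, 1]", what))
    invisible(x)
}
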