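test_that("extended confusion tallies connected and unconnected nodes", {
    preds <- data.frame(
        id = sprintf("n%d", 1:6),
        probability = c(0.9, 0.2, 0.6, 0.4, NA, NA),
        connected = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
    labels <- setNames(c(1L, 1L, 0L, 0L, 1L, 0L), preds$id)
    cc <- confusionCounts(extendedConfusion(preds, labels, 0.5))
    expect_equal(cc, c(TP = 1L, FP = 1L, TN = 1L, FN = 1L,
                       NCP = 1L, NCN = 1L))

    perfect <- data.frame(id = preds$id,
                          probability = c(1, 1, 0, 0, 1, 0),
                          connected = TRUE)
    cp <- confusionCounts(extendedConfusion(perfect, labels, 0.5))
    expect_equal(unname(cp[c("FP", "FN", "NCP", "NCN")]), rep(0L, 4))

    none <- data.frame(id = preds$id, probability = NA_real_,
                       connected = FALSE)
    cn <- confusionCounts(extendedConfusion(none, labels, 0.5))
    expect_equal(unname(cn[c("TP", "FP", "TN", "FN")]), rep(0L, 4))
    expect_equal(sum(cn[c("NCP", "NCN")]), 6L)
    expect_error(extendedConfusion(preds, labels[1:3], 0.5), "no label")
})

test_that("modified rates follow their defining ratios", {
    mk <- function(TP, FP, TN, FN, NCP, NCN)
        new("ExtendedConfusion",
            counts = setNames(as.integer(c(TP, FP, TN, FN, NCP, NCN)),
                              c("TP", "FP", "TN", "FN", "NCP", "NCN")))
    expect_equal(mTPR(mk(45, 0, 0, 45, 10, 0)), 0.45)
    expect_equal(mFPR(mk(0, 1, 8, 0, 0, 1)), 0.1)
    # with nothing unconnected the modified rates are the classical ones
    c0 <- mk(30, 5, 55, 10, 0, 0)
    expect_equal(mTPR(c0), 30 / 40)
    expect_equal(mFPR(c0), 5 / 60)
    expect_error(mTPR(mk(0, 1, 1, 0, 0, 0)), "no actives")
})

test_that("modified ROC area matches the brute-force threshold sweep", {
    set.seed(77)
    for (k in 1:10) {
        fx <- randomPredFixture(10, pUnconnected = 0.3)
        expect_equal(mrocAuc(fx$preds, fx$labels),
                     oracleMrocAuc(fx$preds, fx$labels), tolerance = 1e-12)
    }
    # perfect separation, all connected
    preds <- data.frame(id = c("a", "b", "c", "d"),
                        probability = c(0.9, 0.8, 0.2, 0.1),
                        connected = TRUE)
    labels <- setNames(c(1L, 1L, 0L, 0L), preds$id)
    expect_equal(mrocAuc(preds, labels), 1.0)
    # fully unconnected network never leaves the origin
    un <- data.frame(id = preds$id, probability = NA_real_,
                     connected = FALSE)
    expect_equal(mrocAuc(un, labels), 0.0)
    expect_error(mrocAuc(preds, setNames(c(1L, 1L, 1L, 1L), preds$id)),
                 "both")
})

test_that("modified ROC equals classical ROC without unconnected nodes", {
    set.seed(99)
    for (k in 1:50) {
        n <- sample(8:30, 1)
        fx <- randomPredFixture(n, pUnconnected = 0)
        ref <- as.numeric(pROC::auc(pROC::roc(
            response = fx$labels[fx$preds$id], predictor = fx$preds$probability,
            levels = c(0, 1), direction = "<", quiet = TRUE)))
        expect_equal(mrocAuc(fx$preds, fx$labels), ref, tolerance = 1e-9)
    }
})

test_that("modified ROC is invariant to monotone probability transforms", {
    set.seed(13)
    fx <- randomPredFixture(25, pUnconnected = 0.2)
    a1 <- mrocAuc(fx$preds, fx$labels)
    tr <- fx$preds
    tr$probability <- plogis(5 * tr$probability - 1)
    expect_equal(mrocAuc(tr, fx$labels), a1, tolerance = 1e-12)
})

test_that("FPR at fixed recall matches exhaustive enumeration", {
    # perfect classifier reaches any recall at zero FPR
    preds <- data.frame(id = c("a", "b", "c", "d"),
                        probability = c(0.9, 0.8, 0.2, 0.1),
                        connected = TRUE)
    labels <- setNames(c(1L, 1L, 0L, 0L), preds$id)
    r <- fprAtTpr(preds, labels, 0.9)
    expect_true(r$reachable)
    expect_equal(r$fpr, 0)

    # unconnected actives cap the attainable recall
    cap <- data.frame(id = sprintf("x%d", 1:10),
                      probability = c(runif(8), NA, NA),
                      connected = c(rep(TRUE, 8), FALSE, FALSE))
    capLab <- setNames(c(rep(1L, 2), rep(0L, 6), 1L, 1L), cap$id)
    rc <- fprAtTpr(cap, capLab, 0.9)  # 2 of 4 actives can ever be found
    expect_false(rc$reachable)
    expect_lte(rc$achievedTpr, 0.5)

    # exhaustive reference on a 20-node fixture (unconnected nodes are
    # predicted negative at every threshold)
    set.seed(17)
    fx <- randomPredFixture(20, pUnconnected = 0.15)
    conn <- fx$preds$connected
    p <- fx$preds$probability
    y <- fx$labels[fx$preds$id]
    for (target in c(0.3, 0.5, 0.9)) {
        got <- fprAtTpr(fx$preds, fx$labels, target)
        bestFpr <- Inf; bestThr <- NA
        for (t in c(Inf, sort(unique(p[conn]), decreasing = TRUE))) {
            tpr <- sum(conn & p >= t & y == 1) / sum(y == 1)
            fpr <- sum(conn & p >= t & y == 0) / sum(y == 0)
            if (tpr >= target && fpr < bestFpr) {
                bestFpr <- fpr; bestThr <- t
            }
        }
        if (is.finite(bestFpr)) {
            expect_true(got$reachable)
            expect_equal(got$fpr, bestFpr)
        } else expect_false(got$reachable)
    }
    # monotone in the target
    f1 <- fprAtTpr(fx$preds, fx$labels, 0.3)$fpr
    f2 <- fprAtTpr(fx$preds, fx$labels, 0.6)$fpr
    expect_gte(f2, f1)
})
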