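test_that("feature cleaning removes constant, rare and duplicated bits", {
    set.seed(8)
    n <- 40
    base <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
    bits <- cbind(base,
                  zero = 0L,                      # zero variance
                  one = 1L,                       # zero variance
                  rare = c(1L, rep(0L, n - 1)),   # near-zero variance
                  dup = base[, 2])                # perfectly correlated
    colnames(bits)[1:4] <- sprintf("b%d", 1:4)
    fp <- FingerprintMatrix(bits)
    out <- cleanFeatures(fp)
    expect_setequal(out$report$removedZeroVariance, c("zero", "one"))
    expect_true("rare" %in% out$report$removedNearZeroVariance)
    # exactly one of the duplicated pair goes
    expect_equal(nrow(out$report$removedCorrelated), 1L)
    expect_true(out$report$removedCorrelated$dropped %in% c("b2", "dup"))
    expect_equal(out$report$removedCorrelated$correlation, 1.0)
    # removal lists are disjoint and partition with the survivors
    rep <- out$report
    all3 <- c(rep$removedZeroVariance, rep$removedNearZeroVariance,
              rep$removedCorrelated$dropped)
    expect_equal(anyDuplicated(all3), 0L)
    expect_setequal(c(bitNames(out$fingerprints), all3), colnames(bits))
    expect_error(cleanFeatures(FingerprintMatrix(
        matrix(0L, 5, 2, dimnames = list(NULL, c("a", "b"))))), "every bit")
})

test_that("cleaning matches a naive pairwise scan and is idempotent", {
    set.seed(23)
    for (k in 1:5) {
        bits <- matrix(rbinom(20 * 10, 1, runif(1, 0.2, 0.6)), 20, 10)
        colnames(bits) <- sprintf("bit%02d", 1:10)
        fp <- FingerprintMatrix(bits)
        out <- cleanFeatures(fp)
        expect_setequal(bitNames(out$fingerprints), naiveCleanBits(bits))
        again <- cleanFeatures(out$fingerprints)
        expect_equal(bitNames(again$fingerprints),
                     bitNames(out$fingerprints))
        expect_length(again$report$removedZeroVariance, 0L)
        expect_equal(nrow(again$report$removedCorrelated), 0L)
    }
})

test_that("zero/near-zero variance agrees with the caret convention", {
    set.seed(4)
    bits <- cbind(matrix(rbinom(60 * 6, 1, 0.4), 60, 6),
                  allz = 0L, rare = c(1L, 1L, rep(0L, 58)))
    colnames(bits)[1:6] <- sprintf("v%d", 1:6)
    out <- cleanFeatures(FingerprintMatrix(bits))
    flagged <- colnames(bits)[caret::nearZeroVar(bits)]
    expect_setequal(c(out$report$removedZeroVariance,
                      out$report$removedNearZeroVariance), flagged)
})

test_that("classifier training is seeded and recovers toxicophore labels", {
    set.seed(31)
    cfg <- synthConfig(nCompounds = 300L, nBits = 48L, toxicophoreBits = 1:3,
                       labelNoise = 0.05, activeFractionTarget = 0.25,
                       seed = 31L)
    cmp <- generateCompounds(cfg)
    m1 <- trainClassifier(cmp$fingerprints, cmp$labels, nTrials = 3L,
                          seed = 7L)
    m2 <- trainClassifier(cmp$fingerprints, cmp$labels, nTrials = 3L,
                          seed = 7L)
    expect_identical(m1$cvSummary, m2$cvSummary)
    expect_gt(m1$cvAuc, 0.8)
    one <- trainClassifier(cmp$fingerprints, cmp$labels, nTrials = 1L,
                           seed = 7L)
    expect_equal(nrow(one$cvSummary), 1L)
    expect_equal(one$bestConfig, one$cvSummary[, names(one$bestConfig)])
})

test_that("CV AUC is near chance when labels are independent of bits", {
    # single-configuration fits so best-of-trials selection cannot bias
    # the CV estimate upward
    aucs <- numeric(10)
    for (s in 1:10) {
        set.seed(400 + s)
        bits <- matrix(rbinom(500 * 24, 1, 0.3), 500, 24)
        colnames(bits) <- sprintf("bit%02d", 1:24)
        labels <- sample(rep(c(0L, 1L), each = 250))
        m <- trainClassifier(FingerprintMatrix(bits), labels, nTrials = 1L,
                             seed = s)
        aucs[s] <- m$cvAuc
    }
    expect_true(all(aucs > 0.4 & aucs < 0.6))
})

test_that("probability prediction validates the bit schema", {
    set.seed(2)
    bits <- matrix(rbinom(120 * 12, 1, 0.4), 120, 12)
    colnames(bits) <- sprintf("bit%02d", 1:12)
    labels <- as.integer(bits[, 1] | bits[, 2])
    fp <- FingerprintMatrix(bits)
    m <- trainClassifier(fp, labels, nTrials = 2L, seed = 3L)
    p <- predictProba(m, fp)
    expect_length(p, 120L)
    expect_true(all(p >= 0 & p <= 1))
    # identical rows get identical probabilities
    twin <- FingerprintMatrix(bits[c(1, 1), , drop = FALSE],
                              ids = c("t1", "t2"))
    pt <- predictProba(m, twin)
    expect_equal(unname(pt[1]), unname(pt[2]))
    # unambiguous toxicophore rows land on the trained side of 0.5
    pos <- bits[, 1] == 1 & labels == 1
    neg <- bits[, 1] == 0 & bits[, 2] == 0
    expect_gt(mean(p[pos]), 0.5)
    expect_lt(mean(p[neg]), 0.5)
    expect_error(predictProba(m, FingerprintMatrix(bits[, 1:10])),
                 "missing.*bit11")
})
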