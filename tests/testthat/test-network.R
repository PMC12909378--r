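simFixture <- function(n, seed = 1) {
    set.seed(seed)
    ids <- sprintf("N%02d", seq_len(n))
    v <- matrix(runif(n * n), n, n); v <- (v + t(v)) / 2; diag(v) <- 1
    SimilarityMatrix(v, ids = ids, metric = "fixture")
}

test_that("thresholding builds the expected edge set", {
    ids <- c("a", "b", "c")
    v <- matrix(0.9, 3, 3); diag(v) <- 1
    m <- SimilarityMatrix(v, ids = ids)
    labels <- setNames(c(1L, 0L, 1L), ids)
    net <- buildNetwork(m, labels, threshold = 0.5)
    expect_equal(nrow(networkEdges(net)), 3L)  # triangle
    net2 <- buildNetwork(m, labels, threshold = 0.95)
    expect_equal(nrow(networkEdges(net2)), 0L)
    expect_error(buildNetwork(m, setNames(1L, "zz"), 0.5), "overlap")
})

test_that("top-k edge filtering keeps the union of per-node top lists", {
    m <- simFixture(8, seed = 21)
    labels <- setNames(rep(c(0L, 1L), 4), compoundIds(m))
    thr <- 0.3
    net <- buildNetwork(m, labels, thr, topK = 2L)
    # brute-force reference: per-node ranked neighbor lists
    v <- similarityValues(m)
    ids <- sort(compoundIds(m))
    topOf <- function(me) {
        nb <- setdiff(ids[v[me, ids] >= thr], me)
        nb[order(-v[me, nb], nb)][seq_len(min(2, length(nb)))]
    }
    expected <- c()
    for (i in ids) for (j in ids) if (i < j &&
        v[i, j] >= thr && (j %in% topOf(i) || i %in% topOf(j)))
        expected <- c(expected, paste(i, j))
    got <- with(networkEdges(net), paste(from, to))
    expect_setequal(got, expected)
    # every node with passing neighbors keeps at least min(2, #neighbors)
    for (me in ids) {
        nPass <- length(setdiff(ids[v[me, ids] >= thr], me))
        deg <- sum(networkEdges(net)$from == me | networkEdges(net)$to == me)
        expect_gte(deg, min(2L, nPass))
    }
})

test_that("voting reproduces the worked neighbor-fraction example", {
    # a node connected to 171 labeled spectra of which 39 are active
    nbIds <- sprintf("nb%03d", 1:171)
    ids <- c("query", nbIds)
    v <- diag(nrow = 172)
    v[1, 2:172] <- v[2:172, 1] <- 0.6
    m <- SimilarityMatrix(v, ids = ids)
    labels <- setNames(c(0L, rep(1L, 39), rep(0L, 132)), ids)
    net <- buildNetwork(m, labels, threshold = 0.5)
    p <- vote(net, "query", "majority")
    expect_equal(p$probability, 39 / 171)
    expect_equal(round(100 * p$probability, 1), 22.8)
})

test_that("voting handles pure, weighted and isolated cases", {
    ids <- c("q", "x", "y")
    v <- diag(3); v[1, 2] <- v[2, 1] <- 0.9; v[1, 3] <- v[3, 1] <- 0.1
    m <- SimilarityMatrix(v, ids = ids)
    net <- buildNetwork(m, setNames(c(0L, 1L, 0L), ids), threshold = 0.05)
    expect_equal(vote(net, "q", "weighted")$probability, 0.9)
    net2 <- buildNetwork(m, setNames(c(0L, 1L, 1L), ids), threshold = 0.05)
    expect_equal(vote(net2, "q", "majority")$probability, 1.0)
    expect_equal(vote(net2, "q", "weighted")$probability, 1.0)
    iso <- buildNetwork(m, setNames(c(0L, 1L, 0L), ids), threshold = 0.95)
    pIso <- vote(iso, "q")
    expect_false(pIso$connected)
    expect_true(is.na(pIso$probability))
    expect_error(vote(net, "nope"), "unknown node")
})

test_that("leave-one-out predictions match naive per-node recomputation", {
    two <- SimilarityMatrix(matrix(c(1, .8, .8, 1), 2),
                            ids = c("p", "q"))
    pr <- looPredict(two, setNames(c(1L, 0L), c("p", "q")), 0.5)
    expect_equal(pr$probability[pr$id == "p"], 0.0)
    expect_equal(pr$probability[pr$id == "q"], 1.0)

    m <- simFixture(20, seed = 33)
    labels <- setNames(sample(0:1, 20, replace = TRUE), compoundIds(m))
    for (scheme in c("majority", "weighted")) {
        got <- looPredict(m, labels, 0.55, voting = scheme)
        ref <- naiveLooVote(m, labels, 0.55, scheme)
        got <- got[order(got$id), ]; ref <- ref[order(ref$id), ]
        expect_equal(got$probability, ref$probability, tolerance = 1e-12)
        expect_equal(got$connected, ref$connected)
    }
})

test_that("voting probabilities are bounded and schemes agree on equal weights", {
    n <- 12; ids <- sprintf("E%02d", 1:n)
    v <- matrix(0.7, n, n); diag(v) <- 1
    m <- SimilarityMatrix(v, ids = ids)
    labels <- setNames(sample(rep(c(0L, 1L), 6)), ids)
    pm <- looPredict(m, labels, 0.5, voting = "majority")
    pw <- looPredict(m, labels, 0.5, voting = "weighted")
    expect_equal(pm$probability, pw$probability)
    expect_true(all(pm$probability >= 0 & pm$probability <= 1))
})

test_that("raising the threshold only removes edges and connections", {
    m <- simFixture(15, seed = 9)
    labels <- setNames(sample(0:1, 15, replace = TRUE), compoundIds(m))
    prevEdges <- Inf; prevUnconn <- -1
    for (thr in seq(0.2, 0.9, by = 0.1)) {
        net <- buildNetwork(m, labels, thr)
        ne <- nrow(networkEdges(net))
        unconn <- sum(!looPredict(m, labels, thr)$connected)
        expect_lte(ne, prevEdges)
        expect_gte(unconn, prevUnconn)
        prevEdges <- ne; prevUnconn <- unconn
    }
})

test_that("hyperparameter search ranks configurations reproducibly", {
    m <- simFixture(25, seed = 55)
    labels <- setNames(sample(0:1, 25, replace = TRUE), compoundIds(m))
    grid <- data.frame(metric = "sim", threshold = c(0.4, 0.4, 0.6),
                       topK = NA_integer_,
                       voting = c("majority", "majority", "weighted"))
    out <- optimizeHyperparams(list(sim = m), labels, grid)
    expect_equal(nrow(out), 3L)
    # duplicate configurations score identically
    dup <- out[out$threshold == 0.4 & out$voting == "majority", ]
    expect_equal(dup$mrocAuc[1], dup$mrocAuc[2])
    expect_true(!is.unsorted(rev(out$mrocAuc)))
    single <- optimizeHyperparams(list(sim = m), labels, grid[1, ])
    expect_equal(single$mrocAuc, out$mrocAuc[out$threshold == 0.4][1])
})
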