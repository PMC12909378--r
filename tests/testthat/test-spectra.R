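test_that("MSP and MGF files round-trip through read and write", {
    msp <- tempfile(fileext = ".msp")
    writeLines(c(
        "NAME: CMPA",
        "PRECURSORMZ: 200.1000",
        "IONMODE: positive",
        "Num Peaks: 3",
        "50.1 100", "80.2 40", "120.3 10",
        "",
        "NAME: CMPB",
        "Num Peaks: 3",
        "60.0 5", "61.0 50", "62.0 500",
        ""), msp)
    sp <- readSpectra(msp, "msp")
    expect_length(sp, 2L)
    expect_equal(vapply(sp, peakCount, integer(1)), c(3L, 3L))
    expect_equal(compoundId(sp[[1]]), "CMPA")
    expect_equal(precursorMz(sp[[1]]), 200.1)
    # record without precursor: stored absent, modified cosine refuses
    expect_true(is.na(precursorMz(sp[[2]])))
    expect_error(modifiedCosine(sp[[1]], sp[[2]]), "precursor")

    for (fmt in c("msp", "mgf")) {
        out <- tempfile(fileext = paste0(".", fmt))
        orig <- randomSpectrum(8, id = "RT1", precursor = 350.12)
        writeSpectra(list(orig), out, fmt)
        back <- readSpectra(out, fmt)[[1]]
        expect_equal(peakMatrix(back), peakMatrix(orig), tolerance = 1e-6)
        expect_equal(precursorMz(back), 350.12, tolerance = 1e-6)
    }
})

test_that("malformed and empty spectrum files are reported", {
    bad <- tempfile()
    writeLines(c("NAME: X", "Num Peaks: 2", "50.0 1"), bad)
    expect_error(readSpectra(bad, "msp"), "record 1")
    empty <- tempfile()
    writeLines(character(0), empty)
    expect_warning(out <- readSpectra(empty, "msp"), "empty")
    expect_length(out, 0L)
})

test_that("peak normalization scales to the base peak and is idempotent", {
    s <- Spectrum(c(100, 200, 300), c(10, 5, 1))
    n1 <- normalizePeaks(s)
    expect_equal(unname(peakMatrix(n1)[, "intensity"]), c(1, 0.5, 0.1))
    expect_equal(peakMatrix(normalizePeaks(n1)), peakMatrix(n1))
    expect_equal(unname(peakMatrix(normalizePeaks(
        Spectrum(77, 42)))[, "intensity"]), 1)
    expect_error(normalizePeaks(Spectrum(c(100, 200), c(0, 0))), "zero")
})

test_that("spectrum cleaning drops zero peaks and super-precursor peaks", {
    s <- Spectrum(c(50, 100, 220.9, 180), c(1, 0, 3, 2), precursorMz = 220.2)
    cl <- cleanSpectrum(s)
    expect_equal(unname(peakMatrix(cl)[, "mz"]), c(50, 180))
    expect_equal(max(peakMatrix(cl)[, "intensity"]), 1)
})

test_that("averaging merges peaks within tolerance and is order-invariant", {
    s1 <- Spectrum(c(100, 200), c(1, 1), compoundId = "C")
    s2 <- Spectrum(c(150, 250), c(1, 1), compoundId = "C")
    # disjoint peaks, each intensity 1 -> each averaged to 0.5, then the
    # renormalization brings the base peak back to 1
    av <- averageSpectra(list(s1, s2), mzTolerance = 0.01)
    expect_equal(unname(peakMatrix(av)[, "mz"]), c(100, 150, 200, 250))
    expect_equal(unname(peakMatrix(av)[, "intensity"]), rep(1, 4))
    av2 <- averageSpectra(list(s2, s1), mzTolerance = 0.01)
    expect_equal(peakMatrix(av), peakMatrix(av2))

    single <- averageSpectra(list(Spectrum(c(10, 20), c(2, 4),
                                           compoundId = "C")))
    expect_equal(unname(peakMatrix(single)[, "intensity"]), c(0.5, 1))
    ident <- averageSpectra(list(s1, s1))
    expect_equal(peakMatrix(ident), peakMatrix(normalizePeaks(s1)))

    # merged m/z is the intensity-weighted mean over normalized peaks
    m1 <- Spectrum(c(100.000, 300), c(1, 0.5), compoundId = "C")
    m2 <- Spectrum(c(100.010, 300), c(2, 0.5), compoundId = "C")
    avm <- averageSpectra(list(m1, m2), mzTolerance = 0.05)
    expect_equal(unname(peakMatrix(avm)[1, "mz"]),
                 (100 * 1 + 100.01 * 1) / 2, tolerance = 1e-9)

    expect_error(averageSpectra(list()), "empty")
    expect_error(averageSpectra(list(s1, Spectrum(1, 1, compoundId = "D"))),
                 "mixed")
})

test_that("quality filter requires enough peaks above the intensity floor", {
    pass <- Spectrum(1:5 * 50, c(1.0, 0.6, 0.3, 0.1, 0.06))
    expect_true(qualityFilter(pass))
    fail <- Spectrum(1:7 * 50, c(1.0, 0.6, 0.3, 0.1, 0.01, 0.01, 0.01))
    expect_false(qualityFilter(fail))
    expect_true(qualityFilter(normalizePeaks(Spectrum(99, 3)), minPeaks = 1))
    # monotone: raising either bar never turns FALSE into TRUE
    set.seed(42)
    for (k in 1:20) {
        s <- randomSpectrum(sample(3:10, 1))
        f1 <- qualityFilter(s, minPeaks = 4, minRelIntensity = 0.1)
        expect_true(!f1 || qualityFilter(s, 4, 0.05))
        expect_true(!f1 || qualityFilter(s, 3, 0.1))
    }
})

test_that("label cleaning applies the precautionary any-active rule", {
    raw <- data.frame(
        compound_id = c("AAAAAAAAAAAAAA-X", "AAAAAAAAAAAAAA-Y",
                        "BBBBBBBBBBBBBB", "BBBBBBBBBBBBBB",
                        "CCCCCCCCCCCCCC"),
        assay = c("AhR", "AhR", "AhR", "ER", "AhR"),
        label = c("active", "inactive", "inactive", "inactive",
                  "inconclusive"))
    out <- cleanLabels(raw)
    expect_equal(out$label[out$compound_id == "AAAAAAAAAAAAAA" &
                           out$assay == "AhR"], "active")
    expect_equal(out$label[out$compound_id == "BBBBBBBBBBBBBB" &
                           out$assay == "AhR"], "inactive")
    # no ER report for A -> absent
    expect_false(any(out$compound_id == "AAAAAAAAAAAAAA" & out$assay == "ER"))
    expect_equal(out$label[out$compound_id == "CCCCCCCCCCCCCC"],
                 "inconclusive")
    # one row per unique (id block, assay) with a report
    expect_equal(nrow(out), 4L)
    expect_equal(nrow(cleanLabels(raw[0, ])), 0L)
})

test_that("stratified split preserves class proportions and exclusions", {
    labels <- setNames(c(rep(1L, 10), rep(0L, 90)), sprintf("C%03d", 1:100))
    sp <- stratifiedSplit(labels, 0.2, seed = 5)
    expect_equal(sum(labels[sp$test]), 2L)
    expect_equal(length(sp$test), 20L)
    expect_setequal(c(sp$train, sp$test), names(labels))
    expect_identical(sp, stratifiedSplit(labels, 0.2, seed = 5))
    excl <- names(labels)[1:30]
    sp2 <- stratifiedSplit(labels, 0.2, seed = 5, excludeIds = excl)
    expect_length(intersect(sp2$test, excl), 0L)
    expect_error(stratifiedSplit(setNames(c(1L, 0L, 0L), c("a", "b", "c")),
                                 0.5, seed = 1), "fewer than 2")
})
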