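test_that("species profiles validate their parameters and shift correctly", {
    p <- speciesProfile("X", delta = 0.1)
    sh <- shiftedProfile(p)
    expect_equal(sum(sh), 1, tolerance = 1e-12)
    expect_true(all(sh >= 0))
    expect_equal(sum(sh[c("E", "D", "K", "R")]) -
                 sum(p$residueProbs[c("E", "D", "K", "R")]), 0.1)
    expect_equal(sum(p$residueProbs[c("S", "T", "N", "Q")]) -
                 sum(sh[c("S", "T", "N", "Q")]), 0.1)
    expect_error(speciesProfile("X", delta = 0.5), "delta")
    expect_error(speciesProfile("X", gc3Target = 2), "gc3Target")
})

test_that("generators are pure functions of their seed", {
    prof <- list(speciesProfile("A"), speciesProfile("B"))
    g1 <- genOrthologSets(prof, nSets = 4, lenRange = c(60, 90), seed = 5)
    g2 <- genOrthologSets(prof, nSets = 4, lenRange = c(60, 90), seed = 5)
    expect_identical(g1, g2)
    g3 <- genOrthologSets(prof, nSets = 4, lenRange = c(60, 90), seed = 6)
    expect_false(identical(g1$proteomes, g3$proteomes))

    expect_identical(genMeltCurve(45, noiseSd = 2, seed = 9),
                     genMeltCurve(45, noiseSd = 2, seed = 9))
    expect_identical(genPairDataset(5, 0.05, seed = 3),
                     genPairDataset(5, 0.05, seed = 3))
})

test_that("planted ortholog sets are recovered exactly without indels", {
    prof <- lapply(c("A", "B", "C"), speciesProfile)
    gs <- genOrthologSets(prof, nSets = 10, lenRange = c(80, 140),
                          indelRate = 0, seed = 31)
    sets <- buildOrthologSets(bestHits(gs$hits), c("A", "B", "C"))
    expect_length(sets, 10L)
    truthBysSeed <- setNames(gs$truth, vapply(gs$truth, `[[`, "", "A"))
    for (nm in names(sets))
        expect_equal(sets[[nm]], truthBysSeed[[nm]][c("A", "B", "C")])
})

test_that("true alignments reproduce the emitted proteomes", {
    prof <- lapply(c("A", "B"), speciesProfile)
    gs <- genOrthologSets(prof, nSets = 5, lenRange = c(60, 100),
                          indelRate = 0.05, seed = 8)
    for (k in seq_along(gs$alignments)) {
        rows <- gs$alignments[[k]]
        expect_length(unique(nchar(rows)), 1L)
        for (id in names(rows)) {
            sp <- gs$idToSpecies[[id]]
            expect_equal(gsub("-", "", rows[[id]], fixed = TRUE),
                         unname(gs$proteomes[[sp]][[id]]))
        }
    }
})

test_that("a zero shift gives symmetric CvP across species", {
    prof <- lapply(c("A", "B", "C"), speciesProfile)
    gs <- genOrthologSets(prof, nSets = 200, lenRange = c(150, 250),
                          nDecoys = 0, seed = 41)
    mns <- vapply(c("A", "B", "C"), function(s)
        mean(vapply(gs$proteomes[[s]], cvpBias, numeric(1))), numeric(1))
    expect_lt(max(mns) - min(mns), 1)
})

test_that("the planted shift raises mean CvP by about 200*delta", {
    delta <- 0.1
    prof <- list(speciesProfile("A", delta = delta), speciesProfile("B"),
                 speciesProfile("C"))
    gs <- genOrthologSets(prof, nSets = 200, lenRange = c(150, 250),
                          nDecoys = 0, seed = 42)
    mns <- vapply(c("A", "B", "C"), function(s)
        mean(vapply(gs$proteomes[[s]], cvpBias, numeric(1))), numeric(1))
    excess <- mns[["A"]] - mean(mns[c("B", "C")])
    expect_lt(abs(excess - 200 * delta), 2)
})

test_that("pair datasets give null AUC at delta 0 and monotone signal", {
    aucAt <- function(delta) {
        pd <- genPairDataset(nPairs = 300, deltaThermo = delta, len = 300,
                             seed = 17)
        scores <- vapply(pd$sequence, cvpBias, numeric(1))
        auc(rocAuc(scores, pd$label, positive = "thermophile"))
    }
    aucs <- vapply(c(0, 0.02, 0.04, 0.06, 0.08, 0.1), aucAt, numeric(1))
    expect_lt(abs(aucs[1] - 0.5), 0.05)
    expect_true(all(diff(aucs) >= -0.005))
    expect_gt(aucs[5], 0.95)
    expect_error(genPairDataset(0), "nPairs")
})

test_that("reverse translation is exact and honours the GC3 target", {
    set.seed(23)
    seqs <- setNames(vapply(1:3, function(i) randomProtein(200), ""),
                     paste0("p", 1:3))
    nt <- genCodingSequences(seqs, gc3Target = 0.5, seed = 2)
    expect_equal(unname(nchar(nt)), unname(3 * nchar(seqs)))
    for (id in names(seqs))
        expect_equal(sixFrameTranslate(nt[[id]])[["F1"]], seqs[[id]])

    # gc3Target = 1: every position with a G/C-ending codon available uses it
    nt1 <- genCodingSequences(c(x = "MKRDESTNQW"), gc3Target = 1, seed = 1)
    expect_equal(gcByCodonPosition(nt1[[1]])$gc3, 100)
    # long sequence lands near the achievable value for gc3Target = 0.5:
    # Met and Trp are invariantly G-ending, everything else is Bernoulli(0.5)
    s1 <- seqs[[1]]
    fr <- aaFrequencies(s1)
    achievable <- 50 + 0.5 * (fr[["M"]] + fr[["W"]])
    g <- gcByCodonPosition(genCodingSequences(seqs[1], 0.5, seed = 3)[[1]])$gc3
    expect_lt(abs(g - achievable), 5)
})

test_that("melt-curve generation validates the planted midpoint", {
    expect_error(genMeltCurve(10), "outside the temperature grid")
    cv <- genMeltCurve(45, 1.5, seed = 1)
    expect_length(curveTemperatures(cv), 301L)
    expect_lt(abs(meltingTemperature(fitTm(cv)) - 45), 0.01)
})
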