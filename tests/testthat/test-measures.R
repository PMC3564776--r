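AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("amino-acid composition sums to 100 and matches hand counts", {
    frA <- aaFrequencies("AAAA")
    expect_equal(frA[["A"]], 100)
    expect_true(all(frA[setdiff(AA20, "A")] == 0))
    expect_equal(unname(aaFrequencies("ACDEFGHIKLMNPQRSTVWY")), rep(5, 20))
    fr <- aaFrequencies("MKKR")
    expect_equal(fr[["M"]], 25)
    expect_equal(fr[["K"]], 50)
    expect_equal(fr[["R"]], 25)
    set.seed(3)
    for (i in 1:25) {
        s <- randomProtein(sample(5:200, 1))
        expect_equal(sum(aaFrequencies(s)), 100, tolerance = 1e-9)
    }
    expect_error(aaFrequencies("XXX"), "undefined composition")
})

test_that("CvP-bias equals 100*(C-P)/L and charged minus polar percent", {
    expect_equal(cvpBias("EDKR"), 100)
    expect_equal(cvpBias("STNQ"), -100)
    expect_equal(cvpBias("MKDESTAA"), 12.5)
    set.seed(4)
    for (i in 1:25) {
        s <- randomProtein(sample(5:200, 1))
        fr <- aaFrequencies(s)
        polar <- sum(fr[c("S", "T", "N", "Q")])
        expect_equal(cvpBias(s), chargedContent(s) - polar, tolerance = 1e-12)
    }
})

test_that("CvP-bias mixes length-weighted under concatenation", {
    set.seed(5)
    for (i in 1:15) {
        s1 <- randomProtein(sample(5:80, 1))
        s2 <- randomProtein(sample(5:80, 1))
        l1 <- nchar(s1); l2 <- nchar(s2)
        expect_equal(cvpBias(paste0(s1, s2)),
                     (l1 * cvpBias(s1) + l2 * cvpBias(s2)) / (l1 + l2),
                     tolerance = 1e-12)
    }
})

test_that("IVYWREL, serine, charged, GARP/FYMINK match hand counts", {
    expect_equal(ivywrel("IVYWREL"), 100)
    expect_equal(ivywrel("ACDGHKMNPQSTF"), 0)
    expect_equal(ivywrel("ACDEFGHIKLMNPQRSTVWY"), 35)
    expect_equal(serineContent("SSSS"), 100)
    expect_equal(chargedContent("DEKR"), 100)
    expect_equal(garpFymink("GARP"), c(garp = 100, fymink = 0))
    expect_equal(garpFymink("FYMINK"), c(garp = 0, fymink = 100))
    expect_equal(garpFymink("GAFY"), c(garp = 50, fymink = 50))
})

test_that("(E+K)/(Q+H) is a count ratio with an undefined zero-denominator", {
    expect_equal(ekQhRatio("EKQH"), 1)
    expect_true(is.na(ekQhRatio("EEKK")))
    expect_equal(ekQhRatio("EKKQ"), 3)
})

test_that("mean hydropathy uses the Kyte-Doolittle table by default", {
    expect_equal(meanHydrophobicity("II"), 4.5)
    expect_equal(meanHydrophobicity("IR"), 0)   # (4.5 - 4.5) / 2
    expect_error(meanHydrophobicity("II", scale = "nope"), "unknown")
})

test_that("percent measures are invariant under sequence shuffling", {
    set.seed(6)
    s <- randomProtein(120)
    sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(cvpBias(s), cvpBias(sh))
    expect_equal(ivywrel(s), ivywrel(sh))
    expect_equal(serineContent(s), serineContent(sh))
    expect_equal(aaFrequencies(s), aaFrequencies(sh))
})

test_that("ambiguity letters are excluded from numerators and denominators", {
    expect_equal(cvpBias("EDKRXXBZ"), 100)
    expect_equal(effectiveLength("EDKRXXBZ"), 4L)
    expect_equal(ivywrel("IVXX"), 100)   # X drops out of the denominator too
    expect_equal(ivywrel("IVXXAC"), 50)
})

test_that("codon-position GC matches hand counts and handles N codons", {
    expect_equal(gcByCodonPosition("ATGGCG")$gc3, 100)
    g <- gcByCodonPosition("ATTATA")
    expect_equal(c(g$gc1, g$gc2, g$gc3), c(0, 0, 0))
    g <- gcByCodonPosition("ATGAAA")   # codons ATG, AAA
    expect_equal(c(g$gc1, g$gc2, g$gc3), c(0, 0, 50))
    expect_equal(g$gc_total, 100 / 6, tolerance = 1e-9)
    expect_error(gcByCodonPosition("ATGAA"), "frame error")
    # codons containing N are excluded entirely
    g <- gcByCodonPosition("ATGANAGCG")
    expect_equal(g$n_codons, 2L)
    # a sequence of codons all ending in G/C has gc3 = 100
    expect_equal(gcByCodonPosition("GCGATCTGGCAC")$gc3, 100)
})

test_that("evaluateMeasures builds the registry table and merges externals", {
    seqs <- c(p1 = "MKDESTAAIVYW", p2 = "GARPFYMINKHQ")
    mt <- evaluateMeasures(seqs, species = c("A", "B"))
    expect_s4_class(mt, "MeasureTable")
    expect_equal(ncol(measureValues(mt)), 7L)
    expect_equal(sort(names(measureDirections(mt))),
                 sort(names(builtinMeasures())))

    ext <- scoreTable("disorder", c(p1 = 0.4), direction = -1)
    mt2 <- evaluateMeasures(seqs, species = c("A", "B"),
                            external = list(ext))
    v <- measureValues(mt2)
    expect_equal(v["p1", "disorder"], 0.4)
    expect_true(is.na(v["p2", "disorder"]))
    expect_equal(measureDirections(mt2)[["disorder"]], -1)

    clash <- scoreTable("cvp_bias", c(p1 = 1), direction = 1)
    expect_error(evaluateMeasures(seqs, external = list(clash)), "collides")
})

test_that("the CvP column of a MeasureTable equals charged minus polar", {
    set.seed(8)
    seqs <- setNames(vapply(1:10, function(i)
        randomProtein(sample(30:90, 1)), ""), paste0("p", 1:10))
    v <- measureValues(evaluateMeasures(seqs))
    for (id in rownames(v)) {
        fr <- aaFrequencies(seqs[[id]])
        polar <- sum(fr[c("S", "T", "N", "Q")])
        expect_equal(v[id, "cvp_bias"], v[id, "charged"] - polar,
                     tolerance = 1e-12)
    }
})
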