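test_that("Pearson correlation matches closed-form cases", {
    x <- 1:10
    expect_equal(corCoefficient(pearsonCor(x, 2 * x + 1)), 1)
    expect_equal(corCoefficient(pearsonCor(c(1, 2, 3), c(3, 2, 1))), -1)
    expect_error(pearsonCor(c(1, 2, 3), c(5, 5, 5)), "degenerate")
    expect_error(pearsonCor(1:2, 2:3), "at least 3")
})

test_that("Pearson agrees with a direct covariance evaluation", {
    set.seed(16)
    for (i in 1:20) {
        n <- sample(5:60, 1)
        x <- rnorm(n); y <- rnorm(n)
        res <- pearsonCor(x, y)
        direct <- sum((x - mean(x)) * (y - mean(y))) /
            sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
        expect_equal(corCoefficient(res), direct, tolerance = 1e-12)
        # p from the t transform with n - 2 df
        tt <- direct * sqrt((n - 2) / (1 - direct^2))
        expect_equal(corPValue(res), 2 * pt(-abs(tt), n - 2),
                     tolerance = 1e-10)
    }
})

test_that("Pearson is symmetric and affine-invariant", {
    set.seed(17)
    x <- rnorm(20); y <- rnorm(20)
    r <- corCoefficient(pearsonCor(x, y))
    expect_equal(corCoefficient(pearsonCor(y, x)), r, tolerance = 1e-12)
    expect_equal(corCoefficient(pearsonCor(3 * x + 7, y)), r,
                 tolerance = 1e-12)
    expect_equal(corCoefficient(pearsonCor(x, 0.2 * y - 5)), r,
                 tolerance = 1e-12)
})

test_that("proteome means correlate with a planted linear phenotype", {
    set.seed(18)
    species <- paste0("sp", 1:8)
    temps <- setNames(seq(35, 42, by = 1), species)
    means <- setNames(0.2 * temps + rnorm(8, sd = 0.01), species)
    res <- proteomeMeanVsPhenotype(means, temps)
    expect_gt(corCoefficient(res), 0.999)
    expect_error(proteomeMeanVsPhenotype(means[1:2], temps),
                 "insufficient overlap")
    expect_error(proteomeMeanVsPhenotype(means, setNames(rep(37, 8), species)),
                 "degenerate")
})

test_that("speciesMeans averages each species' proteins unweighted", {
    seqs <- c(p1 = "EDKR", p2 = "EDKRSTNQ", p3 = "STNQ")
    mt <- evaluateMeasures(seqs, species = c("A", "A", "B"))
    m <- speciesMeans(mt, "cvp_bias")
    expect_equal(m[["A"]], (100 + 0) / 2)
    expect_equal(m[["B"]], -100)
})

test_that("GARP vs FYMINK means anti-correlate in codon-biased proteomes", {
    set.seed(19)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    garp <- c("G", "A", "R", "P"); fym <- c("F", "Y", "M", "I", "N", "K")
    gMeans <- fMeans <- numeric(8)
    for (i in 1:8) {
        w <- setNames(rep(1, 20), aa)
        w[garp] <- 1 + i / 2          # increasing GC-rich codon usage
        w[fym] <- 1 + (8 - i) / 2
        probs <- w / sum(w)
        seqs <- vapply(1:15, function(j)
            paste(sample(aa, 150, replace = TRUE, prob = probs),
                  collapse = ""), "")
        gf <- vapply(seqs, garpFymink, numeric(2))
        gMeans[i] <- mean(gf["garp", ]); fMeans[i] <- mean(gf["fymink", ])
    }
    expect_lt(corCoefficient(pearsonCor(gMeans, fMeans)), -0.9)
})

test_that("uncorrelated species data give small r and large p on average", {
    set.seed(20)
    rs <- ps <- numeric(300)
    for (i in 1:300) {
        res <- pearsonCor(rnorm(10), rnorm(10))
        rs[i] <- corCoefficient(res); ps[i] <- corPValue(res)
    }
    expect_lt(mean(abs(rs)), 0.4)
    expect_gt(mean(ps), 0.35)
    gc3 <- setNames(rep(50, 5), paste0("s", 1:5))
    expect_error(measureVsGc3(setNames(rnorm(5), names(gc3)), gc3),
                 "degenerate")
})

test_that("stability-pair parsing recomputes differences and Tm midpoints", {
    path <- system.file("extdata", "ortholog_pair_stability.tsv",
                        package = "ThermoComp")
    pairs <- readStabilityPairs(path)
    expect_equal(nrow(pairs), 7L)
    expect_equal(pairs$difference, pairs$meso_value - pairs$thermo_value)
    collagen <- pairs[pairs$protein == "Collagen", ]
    expect_equal(collagen$thermo_tm, 45.5)   # midpoint of 45-46
    expect_equal(collagen$meso_tm, 40)       # midpoint of 38-42
    expect_equal(collagen$thermo_tm_printed, "45-46")
})

test_that("sign concordance flags zero differences and skips missing Tm", {
    pairs <- data.frame(protein = c("a", "b", "c"),
                        thermo_value = c(2, 1, 4), meso_value = c(1, 2, 4),
                        thermo_tm = c(50, NA, 45), meso_tm = c(45, 40, 45))
    expect_warning(res <- signConcordance(pairs), "skipping 1")
    expect_equal(res$nTotal, 2L)
    expect_equal(res$nConcordant, 1L)      # pair a: both negative
    expect_true(res$detail$zero_flag[2])   # pair c: zero differences
    one <- data.frame(thermo_value = 1, meso_value = 2,  # dCvP = +1
                      thermo_tm = 44, meso_tm = 43)      # dTm = -1
    expect_equal(signConcordance(one)$nConcordant, 0L)
})
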