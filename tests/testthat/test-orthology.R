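hitRow <- function(q, s, qs, ss, bit, ev = 1e-50) {
    data.frame(query_id = q, subject_id = s, query_species = qs,
               subject_species = ss, bitscore = bit, evalue = ev,
               stringsAsFactors = FALSE)
}

test_that("best hits pick maximal bitscore with deterministic tie-breaks", {
    hits <- rbind(hitRow("q1", "s1", "A", "B", 200),
                  hitRow("q1", "s2", "A", "B", 150))
    expect_equal(bestHits(hits)$subject_id, "s1")
    hits <- rbind(hitRow("q1", "s1", "A", "B", 200, 1e-50),
                  hitRow("q1", "s2", "A", "B", 200, 1e-40))
    expect_equal(bestHits(hits)$subject_id, "s1")
    hits <- rbind(hitRow("q1", "s2", "A", "B", 200, 1e-50),
                  hitRow("q1", "s1", "A", "B", 200, 1e-50))
    expect_equal(bestHits(hits)$subject_id, "s1")   # lexicographic
})

cliqueHits <- function(members, score = 200) {
    # members: named character vector species -> id; all directed best hits
    do.call(rbind, unlist(lapply(names(members), function(a)
        lapply(setdiff(names(members), a), function(b)
            hitRow(members[[a]], members[[b]], a, b, score))),
        recursive = FALSE))
}

test_that("ortholog sets require full best-hit consistency", {
    m <- c(A = "a1", B = "b1", C = "c1")
    sets <- buildOrthologSets(bestHits(cliqueHits(m)), c("A", "B", "C"))
    expect_length(sets, 1L)
    expect_equal(sets[["a1"]], m)

    # one direction pointing elsewhere breaks the set
    hits <- rbind(cliqueHits(m), hitRow("c1", "b9", "C", "B", 500))
    expect_length(buildOrthologSets(bestHits(hits), c("A", "B", "C")), 0L)

    # two reciprocal pairs over two species give two sets
    hits <- rbind(cliqueHits(c(A = "a1", B = "b1")),
                  cliqueHits(c(A = "a2", B = "b2")))
    sets <- buildOrthologSets(bestHits(hits), c("A", "B"))
    expect_length(sets, 2L)
    expect_error(buildOrthologSets(bestHits(hits), c("A", "A")), "duplicated")
})

test_that("emitted sets satisfy reciprocity for every ordered pair", {
    nChecked <- 0L
    species <- c("A", "B", "C")
    for (seed in 21:24) {
        gs <- genOrthologSets(lapply(species, speciesProfile),
                              nSets = 3, lenRange = c(60, 90),
                              indelRate = 0.05, seed = seed)
        best <- bestHits(gs$hits)
        inst <- list(species = species)
        bh <- setNames(best$subject_id,
                       paste(best$query_id, best$target_species, sep = "\r"))
        sets <- buildOrthologSets(best, inst$species)
        for (set in sets) {
            nChecked <- nChecked + 1L
            for (a in inst$species) for (b in setdiff(inst$species, a)) {
                expect_identical(unname(bh[paste(set[[a]], b, sep = "\r")]),
                                 set[[b]])
            }
        }
    }
    expect_gt(nChecked, 0L)
})

test_that("set construction agrees with brute-force clique enumeration", {
    for (seed in 1:20) {
        nSp <- sample(2:4, 1)
        nPer <- sample(2:6, 1)
        inst <- randomHitInstance(nSp, nPer, seed = seed * 13)
        best <- bestHits(inst$hits)
        got <- buildOrthologSets(best, inst$species)
        want <- bruteForceSets(best, inst$species)
        expect_equal(length(got), length(want),
                     info = sprintf("seed %d", seed))
        expect_equal(got, want)
    }
})

test_that("alignment trimming finds the shared gap-free core", {
    tr <- trimAlignment(c(a = "--KDE-R", b = "MAKDEFR"))
    expect_equal(unname(tr$span), c(3, 7))
    expect_equal(tr$fragments, c(a = "KDER", b = "KDEFR"))

    rows <- c(x = "MKRDE", y = "MARDE")
    tr <- trimAlignment(rows)
    expect_equal(unname(tr$span), c(1, 5))
    expect_equal(tr$fragments, rows)

    expect_error(trimAlignment(c(a = "-A-", b = "A-A")), "untrimmable")
})

test_that("trimming is idempotent and its anchor columns are gap-free", {
    set.seed(9)
    for (i in 1:20) {
        w <- sample(10:30, 1)
        rows <- vapply(1:3, function(j) {
            ch <- sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-"),
                         w, replace = TRUE, prob = c(rep(0.045, 20), 0.1))
            paste(ch, collapse = "")
        }, "")
        names(rows) <- paste0("r", 1:3)
        tr <- try(trimAlignment(rows), silent = TRUE)
        if (inherits(tr, "try-error")) next
        mat <- do.call(rbind, strsplit(rows, ""))
        expect_false(any(mat[, tr$span[1]] == "-"))
        expect_false(any(mat[, tr$span[2]] == "-"))
        # re-trimming the trimmed window changes nothing
        win <- vapply(seq_len(nrow(mat)), function(r)
            paste(mat[r, tr$span[1]:tr$span[2]], collapse = ""), "")
        names(win) <- names(rows)
        tr2 <- trimAlignment(win)
        expect_equal(tr2$fragments, tr$fragments)
        expect_equal(unname(tr2$span), c(1, tr$span[[2]] - tr$span[[1]] + 1))
    }
})
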