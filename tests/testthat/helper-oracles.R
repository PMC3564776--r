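# Independent oracles and small fixture builders used across the suite.

# Pair-counting AUC by explicit double loop (independent of the rank-based
# implementation in rocAuc).
bruteForceAuc <- function(scores, labels, positive) {
    pos <- scores[labels == positive]
    neg <- scores[labels != positive]
    total <- 0
    for (p in pos) for (n in neg)
        total <- total + (p > n) + 0.5 * (p == n)
    total / (length(pos) * length(neg))
}

# Exhaustive enumeration of fully consistent one-per-species tuples over a
# best-hit table (oracle for buildOrthologSets, instances <= 4 x 6).
bruteForceSets <- function(best, speciesOrder) {
    bh <- setNames(best$subject_id,
                   paste(best$query_id, best$target_species, sep = "\r"))
    look <- function(id, sp) {
        v <- bh[paste(id, sp, sep = "\r")]
        if (is.na(v)) NA_character_ else unname(v)
    }
    ids <- lapply(speciesOrder, function(s)
        sort(unique(c(best$query_id[best$query_species == s],
                      best$subject_id[best$target_species == s]))))
    names(ids) <- speciesOrder
    if (any(lengths(ids) == 0)) return(list())
    grid <- expand.grid(ids, stringsAsFactors = FALSE)
    out <- list()
    for (i in seq_len(nrow(grid))) {
        members <- setNames(as.character(grid[i, ]), speciesOrder)
        ok <- TRUE
        for (a in speciesOrder) {
            for (b in setdiff(speciesOrder, a)) {
                if (!identical(look(members[[a]], b), members[[b]])) {
                    ok <- FALSE
                    break
                }
            }
            if (!ok) break
        }
        if (ok) out[[members[[speciesOrder[1]]]]] <- members
    }
    if (length(out)) out[order(names(out))] else out
}

# Random hit instance over a few species and proteins per species.
randomHitInstance <- function(nSpecies, nPerSpecies, seed) {
    set.seed(seed)
    species <- LETTERS[seq_len(nSpecies)]
    ids <- lapply(species, function(s)
        paste0(tolower(s), seq_len(nPerSpecies)))
    names(ids) <- species
    rows <- list()
    for (a in species) for (b in setdiff(species, a)) {
        for (q in ids[[a]]) {
            nh <- sample.int(nPerSpecies, 1)
            subj <- sample(ids[[b]], nh)
            rows[[length(rows) + 1L]] <- data.frame(
                query_id = q, subject_id = subj,
                query_species = a, subject_species = b,
                bitscore = round(runif(nh, 50, 300)),
                evalue = 10^-round(runif(nh, 5, 50)),
                stringsAsFactors = FALSE)
        }
    }
    list(hits = do.call(rbind, rows), species = species)
}

# Random ambiguity-free protein sequence.
randomProtein <- function(len, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                 replace = TRUE), collapse = "")
}

# Write a hit data.frame in the 12-column tabular layout.
writeHitTsv <- function(hits, path) {
    tab <- data.frame(hits$query_id, hits$subject_id, 90, 100, 5, 0,
                      1, 100, 1, 100, hits$evalue, hits$bitscore)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    path
}
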