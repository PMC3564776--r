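# Seeded synthetic-data generators. Every generator sets the RNG from its
# `seed` argument and is therefore a pure function of its inputs.

.uniformProbs <- function() {
    stats::setNames(rep(1 / 20, 20), AA_STANDARD)
}

#' Construct a synthetic species profile
#'
#' Describes how one species' sequences are generated: a residue
#' frequency profile, a charged-versus-polar thermoadaptation shift
#' `delta`, and a target third-codon-position GC fraction. `delta` is the
#' fraction of residue probability mass moved from the polar set
#' (S, T, N, Q) to the charged set (E, D, K, R); it raises the expected
#' CvP-bias of generated sequences by exactly `200 * delta` percentage
#' points (the closed-form oracle used in testing).
#'
#' @param species species label.
#' @param delta thermoadaptation shift in `[0, 0.2]`.
#' @param gc3Target GC3 fraction in `[0, 1]` for reverse translation.
#' @param residueProbs base residue probabilities over the 20 standard
#'   amino acids (default uniform), summing to 1.
#' @return a `species_profile` list.
#' @export
speciesProfile <- function(species, delta = 0, gc3Target = 0.5,
                           residueProbs = NULL) {
    if (is.null(residueProbs)) residueProbs <- .uniformProbs()
    if (!identical(sort(names(residueProbs)), sort(AA_STANDARD)))
        stopf("residueProbs must be named by the 20 standard residues")
    residueProbs <- residueProbs[AA_STANDARD]
    if (abs(sum(residueProbs) - 1) > 1e-12)
        stopf("residueProbs must sum to 1")
    if (delta < 0 || delta > 0.2) stopf("delta must lie in [0, 0.2]")
    if (sum(residueProbs[AA_POLAR]) < delta)
        stopf("delta exceeds available polar probability mass")
    if (gc3Target < 0 || gc3Target > 1) stopf("gc3Target must lie in [0, 1]")
    structure(list(species = species, delta = delta,
                   gc3Target = gc3Target, residueProbs = residueProbs),
              class = "species_profile")
}

#' Residue profile after the charged-versus-polar shift
#'
#' Moves the profile's `delta` probability mass from the polar residues
#' (proportionally to their base mass) to the charged residues (split
#' equally). The result is a valid probability vector: the expected
#' composition of the species' generated sequences.
#'
#' @param profile a `species_profile` (see [speciesProfile()]).
#' @return named numeric 20-vector summing to 1.
#' @export
shiftedProfile <- function(profile) {
    p <- profile$residueProbs
    d <- profile$delta
    polarMass <- sum(p[AA_POLAR])
    if (d > 0) {
        p[AA_POLAR] <- p[AA_POLAR] * (1 - d / polarMass)
        p[AA_CHARGED] <- p[AA_CHARGED] + d / 4
    }
    p
}

# Convert polar residues to random charged residues with the per-residue
# probability that realises an expected converted length fraction of
# `delta`; the generative route to the profile shift that keeps homolog
# pairs sharing a backbone.
.applyThermoShift <- function(chars, delta, polarMass) {
    if (delta <= 0) return(chars)
    isPolar <- chars %in% AA_POLAR
    hit <- isPolar & stats::runif(length(chars)) < delta / polarMass
    if (any(hit))
        chars[hit] <- sample(AA_CHARGED, sum(hit), replace = TRUE)
    chars
}

#' Generate planted orthologous sets with proteomes and hit tables
#'
#' For every set, an ancestor sequence is drawn from the mean of the
#' species' base profiles; each species' member is derived from it by
#' positional resampling toward the species profile (rate
#' `resampleRate`), the species' charged-versus-polar shift (see
#' [speciesProfile()]), and indels at `indelRate` per position (deletions
#' and single-residue insertions, equally likely). The generator emits
#' per-species proteomes, the true gapped alignments, and an all-vs-all
#' hit table whose bitscores are pairwise identities (matches over
#' alignment columns) scaled by 100 — within-set identities dominate the
#' low-identity decoy hits, so reciprocal-best-hit construction recovers
#' the planted sets when `indelRate` is small.
#'
#' @param profiles list of `species_profile` objects (>= 2).
#' @param nSets number of orthologous sets to plant (>= 1).
#' @param lenRange integer range of ancestor lengths, e.g. `c(150, 400)`.
#' @param indelRate per-position indel probability.
#' @param resampleRate per-position probability of redrawing a residue
#'   from the species profile instead of inheriting the ancestor's.
#' @param nDecoys decoy (cross-set) hits emitted per query and target
#'   species.
#' @param seed integer RNG seed.
#' @return list with `proteomes` (named list species -> named character
#'   vector), `alignments` (per set, named gapped rows keyed by protein
#'   id), `hits` (data.frame in [readHitTable()] layout), `idToSpecies`,
#'   and `truth` (per set, species -> protein id).
#' @export
genOrthologSets <- function(profiles, nSets = 20, lenRange = c(150, 400),
                            indelRate = 0, resampleRate = 0.3,
                            nDecoys = 2, seed = 1) {
    if (length(profiles) < 2L) stopf("need at least two species profiles")
    if (nSets < 1L) stopf("nSets must be >= 1")
    for (p in profiles) if (!inherits(p, "species_profile"))
        stopf("profiles must be species_profile objects")
    set.seed(seed)
    species <- vapply(profiles, `[[`, character(1), "species")
    if (anyDuplicated(species)) stopf("duplicate species among profiles")
    names(profiles) <- species
    S <- length(species)
    baseMat <- vapply(profiles, `[[`, numeric(20), "residueProbs")
    meanProfile <- rowMeans(baseMat)

    proteomes <- stats::setNames(
        lapply(species, function(s) character(0)), species)
    alignments <- vector("list", nSets)
    truth <- vector("list", nSets)
    memberChars <- vector("list", nSets)   # aligned char matrices per set

    for (k in seq_len(nSets)) {
        L <- sample(lenRange[1]:lenRange[2], 1L)
        anc <- sample(AA_STANDARD, L, replace = TRUE, prob = meanProfile)
        ids <- stats::setNames(sprintf("%s_p%04d", species, k), species)
        # per-species derivation, tracked against ancestor positions
        perSp <- lapply(species, function(s) {
            pr <- profiles[[s]]
            ch <- anc
            redo <- stats::runif(L) < resampleRate
            if (any(redo))
                ch[redo] <- sample(AA_STANDARD, sum(redo), replace = TRUE,
                                   prob = pr$residueProbs)
            ch <- .applyThermoShift(ch, pr$delta,
                                    sum(pr$residueProbs[AA_POLAR]))
            del <- stats::runif(L) < indelRate / 2
            ins <- stats::runif(L) < indelRate / 2
            insRes <- ifelse(ins, sample(AA_STANDARD, L, replace = TRUE,
                                         prob = pr$residueProbs), "")
            list(ch = ch, del = del, ins = ins, insRes = insRes)
        })
        names(perSp) <- species
        # assemble the true alignment: one column per ancestor position,
        # plus one gap-elsewhere column per (species, position) insertion
        cols <- lapply(seq_len(L), function(j) {
            base <- vapply(species, function(s) {
                if (perSp[[s]]$del[j]) "-" else perSp[[s]]$ch[j]
            }, character(1))
            insCols <- lapply(species[vapply(species, function(s)
                perSp[[s]]$ins[j], logical(1))], function(s) {
                    v <- stats::setNames(rep("-", S), species)
                    v[s] <- perSp[[s]]$insRes[j]
                    v
                })
            c(list(base), insCols)
        })
        colMat <- do.call(cbind, lapply(unlist(cols, recursive = FALSE),
                                        identity))
        rownames(colMat) <- species
        rows <- apply(colMat, 1, paste, collapse = "")
        names(rows) <- unname(ids[species])
        ungapped <- gsub("-", "", rows, fixed = TRUE)
        for (s in species)
            proteomes[[s]][ids[[s]]] <- unname(ungapped[ids[[s]]])
        alignments[[k]] <- rows
        truth[[k]] <- ids
        memberChars[[k]] <- colMat
    }

    idToSpecies <- unlist(lapply(species, function(s)
        stats::setNames(rep(s, length(proteomes[[s]])),
                        names(proteomes[[s]]))))

    # hit table: true within-set identities plus low-identity decoys
    hitRows <- list()
    pairIdent <- function(colMat, a, b) {
        ra <- colMat[a, ]; rb <- colMat[b, ]
        keep <- !(ra == "-" & rb == "-")
        sum(ra[keep] == rb[keep] & ra[keep] != "-") / sum(keep)
    }
    for (k in seq_len(nSets)) {
        for (a in species) for (b in setdiff(species, a)) {
            idn <- pairIdent(memberChars[[k]], a, b)
            hitRows[[length(hitRows) + 1L]] <- data.frame(
                query_id = truth[[k]][[a]], subject_id = truth[[k]][[b]],
                query_species = a, subject_species = b,
                bitscore = 100 * idn, evalue = 10^(-100 * idn),
                stringsAsFactors = FALSE)
            if (nDecoys > 0L && nSets > 1L) {
                other <- sample(setdiff(seq_len(nSets), k),
                                min(nDecoys, nSets - 1L))
                for (m in other) {
                    bg <- stats::runif(1, 0.02, 0.10)
                    hitRows[[length(hitRows) + 1L]] <- data.frame(
                        query_id = truth[[k]][[a]],
                        subject_id = truth[[m]][[b]],
                        query_species = a, subject_species = b,
                        bitscore = 100 * bg, evalue = 10^(-100 * bg),
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    list(proteomes = proteomes, alignments = alignments,
         hits = do.call(rbind, hitRows), idToSpecies = idToSpecies,
         truth = truth)
}

#' Generate a labelled thermophile/mesophile homolog-pair dataset
#'
#' Each pair shares a backbone drawn from the base profile. The mesophile
#' member applies only background mutation; the thermophile member
#' additionally converts polar residues (S, T, N, Q) to random charged
#' residues (E, D, K, R) with the per-residue probability that moves an
#' expected fraction `deltaThermo` of its length — so its expected
#' CvP-bias exceeds the mesophile's by `200 * deltaThermo`.
#'
#' @param nPairs number of homolog pairs (>= 1).
#' @param deltaThermo composition shift of the thermophilic member.
#' @param len backbone length in residues.
#' @param mutationRate background per-position mutation probability
#'   applied independently to both members.
#' @param residueProbs base residue probabilities (default uniform).
#' @param seed integer RNG seed.
#' @return data.frame with one row per sequence (`2 * nPairs` rows):
#'   `pair`, `label` (`"thermophile"`/`"mesophile"`), `sequence`.
#' @export
genPairDataset <- function(nPairs = 500, deltaThermo = 0, len = 300,
                           mutationRate = 0.05, residueProbs = NULL,
                           seed = 1) {
    if (nPairs < 1L) stopf("nPairs must be >= 1")
    if (is.null(residueProbs)) residueProbs <- .uniformProbs()
    set.seed(seed)
    polarMass <- sum(residueProbs[AA_POLAR])
    mutate <- function(ch) {
        hit <- stats::runif(length(ch)) < mutationRate
        if (any(hit))
            ch[hit] <- sample(AA_STANDARD, sum(hit), replace = TRUE,
                              prob = residueProbs)
        ch
    }
    rows <- lapply(seq_len(nPairs), function(i) {
        backbone <- sample(AA_STANDARD, len, replace = TRUE,
                           prob = residueProbs)
        meso <- mutate(backbone)
        thermo <- .applyThermoShift(mutate(backbone), deltaThermo, polarMass)
        data.frame(pair = i,
                   label = c("thermophile", "mesophile"),
                   sequence = c(paste(thermo, collapse = ""),
                                paste(meso, collapse = "")),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Reverse-translate proteins with a controlled GC3 preference
#'
#' Chooses synonymous codons with a Bernoulli(`gc3Target`) preference for
#' G/C at the third position wherever the genetic code offers both
#' classes; residues with a single codon class (Met, Trp) use it
#' unconditionally. Output is in frame with length exactly `3 * L`.
#'
#' @param seqs named character vector (or `AAStringSet`) of protein
#'   sequences over the 20 standard residues.
#' @param gc3Target target GC3 fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return named character vector of coding sequences.
#' @export
genCodingSequences <- function(seqs, gc3Target = 0.5, seed = 1) {
    if (gc3Target < 0 || gc3Target > 1) stopf("gc3Target must lie in [0, 1]")
    if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
    set.seed(seed)
    code <- Biostrings::GENETIC_CODE
    codonsOf <- split(names(code), code)
    gcClass <- lapply(codonsOf, function(cs)
        split(cs, substr(cs, 3, 3) %in% c("G", "C")))
    vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1]]
        if (any(!ch %in% AA_STANDARD))
            stopf("unknown residue '%s'", ch[which(!ch %in% AA_STANDARD)[1]])
        codons <- vapply(ch, function(r) {
            cls <- gcClass[[r]]
            gcAvail <- "TRUE" %in% names(cls)
            atAvail <- "FALSE" %in% names(cls)
            useGC <- if (gcAvail && atAvail) stats::runif(1) < gc3Target
                     else gcAvail
            pool <- if (useGC) cls[["TRUE"]] else cls[["FALSE"]]
            if (length(pool) == 1L) pool else sample(pool, 1L)
        }, character(1))
        paste(codons, collapse = "")
    }, character(1))
}

#' Generate a synthetic Boltzmann melt curve
#'
#' Evaluates [boltzmannModel()] on a fixed temperature grid and adds
#' seeded Gaussian noise.
#'
#' @param tm planted melting temperature; must lie inside the grid.
#' @param slopeA transition slope parameter, degrees C.
#' @param fLow,fHigh baseline fluorescence values.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @param tempRange grid limits in degrees C (default 20-80).
#' @param step grid increment (default 0.2 degC).
#' @param wellIdLabel well identifier of the synthetic curve.
#' @return a [MeltCurve-class] object.
#' @export
genMeltCurve <- function(tm, slopeA = 1.5, fLow = 0, fHigh = 100,
                         noiseSd = 0, seed = 1, tempRange = c(20, 80),
                         step = 0.2, wellIdLabel = "synthetic") {
    if (tm < tempRange[1] || tm > tempRange[2])
        stopf("planted tm %.2f outside the temperature grid [%g, %g]",
              tm, tempRange[1], tempRange[2])
    set.seed(seed)
    temps <- seq(tempRange[1], tempRange[2], by = step)
    f <- boltzmannModel(temps, tm, slopeA, fLow, fHigh)
    if (noiseSd > 0) f <- f + stats::rnorm(length(f), sd = noiseSd)
    new("MeltCurve", temperatures = temps, fluorescence = f,
        wellId = wellIdLabel)
}
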