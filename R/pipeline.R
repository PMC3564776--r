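# End-to-end survey orchestration: preprocess -> orthologs -> measures ->
# ranking -> correlations, from a single configuration.

#' Run the full comparative thermostability survey
#'
#' Executes the pipeline stages in order on a configuration supplied as a
#' named list or a YAML file path:
#'
#' * `species`: character vector giving the species order (first species
#'   seeds ortholog construction).
#' * `proteomes`: named list, species -> named character vector of protein
#'   sequences, or FASTA file path.
#' * `hits`: hit data.frame (see [readHitTable()]) or hit-table path.
#' * `alignments` (optional): list of named gapped row vectors, keyed by
#'   protein id; each emitted ortholog set is matched to the alignment
#'   containing its members and trimmed with [trimAlignment()]. Without
#'   alignments, measures are computed on the full member sequences.
#' * `external` (optional): list of `score_table` objects.
#' * `phenotype` (optional): named numeric body temperatures or TSV path;
#'   adds a proteome-mean CvP-bias vs temperature correlation.
#' * `minLen` (default 60), `cluster` (default FALSE), `clusterId`
#'   (default 0.98): preprocessing controls.
#' * `outDir` (optional): directory for TSV/JSON outputs.
#'
#' Reruns on identical inputs produce byte-identical summaries.
#'
#' @param config named list or YAML file path.
#' @return run report: list with `nSets`, `sets`, `rankSummaries`
#'   (cumulative ranks per measure), `measureTable`, optional
#'   `phenotypeCorrelation`, and `log` (character vector of stage notes).
#' @export
runSurvey <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stopf("config must be a list or a YAML path")
    logLines <- character(0)
    note <- function(fmt, ...) {
        logLines <<- c(logLines, sprintf(fmt, ...))
    }
    need <- setdiff(c("species", "proteomes", "hits"), names(config))
    if (length(need))
        stopf("validation: config is missing field(s): %s",
              paste(need, collapse = ", "))
    species <- config$species
    minLen <- if (is.null(config$minLen)) 60L else config$minLen
    doCluster <- isTRUE(config$cluster)
    clusterId <- if (is.null(config$clusterId)) 0.98 else config$clusterId
    note("survey over %d species: %s", length(species),
         paste(species, collapse = ", "))

    proteomes <- config$proteomes
    for (s in species) {
        if (is.null(proteomes[[s]]))
            stopf("orthology stage: no proteome supplied for species '%s'", s)
        if (is.character(proteomes[[s]]) && length(proteomes[[s]]) == 1L &&
            file.exists(proteomes[[s]]))
            proteomes[[s]] <- as.character(readFasta(proteomes[[s]],
                                                     species = s))
        if (length(proteomes[[s]]) == 0L)
            stopf("orthology stage: species '%s' has an empty proteome", s)
        keep <- nchar(proteomes[[s]]) >= minLen
        if (any(!keep))
            note("preprocess: dropped %d sequence(s) of '%s' below %d aa",
                 sum(!keep), s, minLen)
        proteomes[[s]] <- proteomes[[s]][keep]
        if (length(proteomes[[s]]) == 0L)
            stopf("preprocess stage: species '%s' has no sequence >= %d aa",
                  s, minLen)
        if (doCluster) {
            n0 <- length(proteomes[[s]])
            proteomes[[s]] <- clusterByIdentity(proteomes[[s]], clusterId)
            note("preprocess: clustered '%s' %d -> %d at %.0f%% identity",
                 s, n0, length(proteomes[[s]]), 100 * clusterId)
        }
    }

    idToSpecies <- unlist(lapply(species, function(s)
        stats::setNames(rep(s, length(proteomes[[s]])),
                        names(proteomes[[s]]))))
    hits <- config$hits
    if (is.character(hits) && length(hits) == 1L)
        hits <- readHitTable(hits, idToSpecies)
    keepHit <- hits$query_id %in% names(idToSpecies) &
        hits$subject_id %in% names(idToSpecies)
    hits <- hits[keepHit, , drop = FALSE]
    best <- bestHits(hits)
    sets <- buildOrthologSets(best, species)
    note("orthology: %d consistent set(s) from %d best hits",
         length(sets), nrow(best))
    if (length(sets) == 0L)
        stopf("orthology stage: no consistent orthologous set found")

    external <- if (is.null(config$external)) list() else config$external
    setMatrices <- list()
    allMember <- list()
    for (setName in names(sets)) {
        members <- sets[[setName]]
        seqs <- vapply(species, function(s) proteomes[[s]][[members[[s]]]],
                       character(1))
        names(seqs) <- unname(members[species])
        if (!is.null(config$alignments)) {
            aln <- Filter(function(a) all(members %in% names(a)),
                          config$alignments)
            if (length(aln) == 0L) {
                note("alignment: set '%s' has no matching alignment, skipped",
                     setName)
                next
            }
            tr <- try(trimAlignment(aln[[1]][unname(members[species])]),
                      silent = TRUE)
            if (inherits(tr, "try-error")) {
                note("alignment: set '%s' untrimmable, excluded", setName)
                next
            }
            seqs <- tr$fragments
        }
        mt <- evaluateMeasures(seqs, species = species, external = external)
        setMatrices[[setName]] <- setMeasureMatrix(mt)
        allMember[[setName]] <- data.frame(
            set = setName, species = species,
            protein = unname(members[species]), stringsAsFactors = FALSE)
    }
    if (length(setMatrices) == 0L)
        stopf("measures stage: no usable orthologous set after trimming")
    rankSummaries <- cumulativeRanks(setMatrices)
    note("survey: cumulative ranks over %d usable set(s) and %d measure(s)",
         length(setMatrices), length(rankSummaries))

    pooledSeqs <- unlist(lapply(species, function(s) proteomes[[s]]))
    pooledSp <- unname(idToSpecies[names(pooledSeqs)])
    mtAll <- evaluateMeasures(pooledSeqs, species = pooledSp,
                              external = external)

    phenoCor <- NULL
    if (!is.null(config$phenotype)) {
        pheno <- config$phenotype
        if (is.character(pheno) && length(pheno) == 1L)
            pheno <- readPhenotypeTable(pheno)
        means <- speciesMeans(mtAll, "cvp_bias")
        phenoCor <- proteomeMeanVsPhenotype(means, pheno)
        note("correlate: mean CvP-bias vs body temperature r = %.3f (n = %d)",
             phenoCor@r, phenoCor@n)
    }

    report <- list(nSets = length(setMatrices), sets = sets,
                   rankSummaries = rankSummaries, measureTable = mtAll,
                   phenotypeCorrelation = phenoCor, log = logLines)

    if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        ranks <- do.call(rbind, lapply(rankSummaries, function(rs)
            data.frame(measure = rs@measure,
                       species = names(rs@cumulativeRank),
                       cumulative_rank = unname(rs@cumulativeRank),
                       n_sets_used = rs@nSetsUsed,
                       stringsAsFactors = FALSE)))
        utils::write.table(ranks, file.path(config$outDir, "ranks.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        mv <- measureValues(mtAll)
        utils::write.table(
            data.frame(protein = rownames(mv),
                       species = unname(proteinSpecies(mtAll)), mv,
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(config$outDir, "measures.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        summary <- list(
            n_sets = length(setMatrices),
            cumulative_ranks = lapply(rankSummaries, function(rs)
                as.list(rs@cumulativeRank)),
            correlation = if (is.null(phenoCor)) NULL else
                list(r = phenoCor@r, p = phenoCor@pValue, n = phenoCor@n),
            log = logLines)
        jsonlite::write_json(summary,
                             file.path(config$outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        note("wrote outputs to %s", config$outDir)
        report$log <- logLines
    }
    report
}
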