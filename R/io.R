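#' @importFrom Biostrings readBStringSet AAStringSet DNAStringSet
#'   writeXStringSet
#' @importFrom utils read.csv
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O")
AA_CHARGED <- c("E", "D", "K", "R")
AA_POLAR <- c("S", "T", "N", "Q")

#' Read a FASTA file of protein or nucleotide sequences
#'
#' Sequences are upper-cased and validated against the chosen alphabet:
#' the 20 standard amino acids plus the ambiguity letters B, Z, X, U, O
#' (protein) or A, C, G, T, N (nucleotide). A trailing/internal `*` stop
#' marker is only accepted for protein input when `allowStop = TRUE`.
#'
#' The species label of every record is taken from the `species` argument
#' (the usual case: one FASTA file per species) or, when `speciesPattern`
#' is given, from the first capture group of that regular expression
#' applied to each header.
#'
#' @param path FASTA file path.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param species single species label applied to all records, or `NULL`.
#' @param speciesPattern optional regex with one capture group extracting
#'   the species from each header line.
#' @param allowStop keep `*` characters in protein sequences.
#' @return For protein input an [Biostrings::AAStringSet] (nucleotide:
#'   [Biostrings::DNAStringSet]) named by record id, with a `species`
#'   column in `S4Vectors::mcols()` when a species source was given.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKR", ">p2", "STN"), tf)
#' readFasta(tf, species = "demo")
#' @export
readFasta <- function(path, alphabet = c("protein", "nucleotide"),
                      species = NULL, speciesPattern = NULL,
                      allowStop = FALSE) {
    alphabet <- match.arg(alphabet)
    if (!file.exists(path)) stopf("file not found: %s", path)
    if (file.size(path) == 0L) stopf("empty input: %s", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stopf("empty input: no FASTA records in %s", path)
    seqs <- toupper(as.character(raw))
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    allowed <- if (alphabet == "protein") {
        c(AA_STANDARD, AA_AMBIGUOUS, if (allowStop) "*")
    } else {
        c("A", "C", "G", "T", "N")
    }
    for (i in seq_along(seqs)) {
        ch <- strsplit(seqs[[i]], "")[[1]]
        bad <- which(!ch %in% allowed)
        if (length(bad))
            stopf("illegal %s character '%s' in record '%s' at position %d",
                  alphabet, ch[bad[1]], ids[i], bad[1])
        if (length(ch) == 0L)
            stopf("record '%s' has an empty sequence", ids[i])
    }
    out <- if (alphabet == "protein") Biostrings::AAStringSet(seqs)
           else Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    if (!is.null(speciesPattern)) {
        m <- regmatches(headers, regexec(speciesPattern, headers))
        sp <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
                     character(1))
        if (anyNA(sp))
            stopf("speciesPattern did not match header '%s'",
                  headers[which(is.na(sp))[1]])
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(species = sp)
    } else if (!is.null(species)) {
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(
            species = rep(species, length(out)))
    }
    out
}

#' Write sequences to FASTA
#'
#' @param x an `XStringSet` (or named character vector, coerced to protein).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
    if (is.character(x)) x <- Biostrings::AAStringSet(x)
    Biostrings::writeXStringSet(x, path, width = 60L)
    invisible(path)
}

#' Read a 12-column tabular similarity hit file
#'
#' Consumes the standard tab-separated all-vs-all hit format (columns:
#' query, subject, percent identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, evalue, bitscore). Only identifiers,
#' evalue (column 11) and bitscore (column 12) are used downstream; species
#' are resolved through `idToSpecies`. Lines starting with `#` are skipped.
#'
#' @param path hit-table path.
#' @param idToSpecies named character vector mapping every sequence id to
#'   its species label.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `query_species`, `subject_species`, `bitscore`, `evalue`.
#' @export
readHitTable <- function(path, idToSpecies) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineNo <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L))
        stopf("malformed hit row at line %d: %d columns (12 required)",
              lineNo[which(nf < 12L)[1]], nf[which(nf < 12L)[1]])
    q <- vapply(fields, `[`, character(1), 1L)
    s <- vapply(fields, `[`, character(1), 2L)
    ev <- as.numeric(vapply(fields, `[`, character(1), 11L))
    bs <- as.numeric(vapply(fields, `[`, character(1), 12L))
    if (anyNA(ev) || anyNA(bs))
        stopf("non-numeric evalue/bitscore at line %d",
              lineNo[which(is.na(ev) | is.na(bs))[1]])
    unknown <- setdiff(unique(c(q, s)), names(idToSpecies))
    if (length(unknown))
        stopf("hit table references unknown sequence id '%s'", unknown[1])
    data.frame(
        query_id = q, subject_id = s,
        query_species = unname(idToSpecies[q]),
        subject_species = unname(idToSpecies[s]),
        bitscore = bs, evalue = ev,
        stringsAsFactors = FALSE)
}

#' Read an aligned FASTA file
#'
#' @param path aligned-FASTA path; rows must all have the same width and
#'   use `-` as the gap symbol.
#' @return named character vector of gapped rows (ids as names).
#' @export
readAlignedFasta <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stopf("empty input: no records in %s", path)
    rows <- toupper(as.character(raw))
    names(rows) <- sub("\\s.*$", "", names(raw))
    w <- nchar(rows)
    if (length(unique(w)) > 1L) {
        off <- names(rows)[which(w != w[1])[1]]
        stopf("ragged alignment: row '%s' has width %d, expected %d",
              off, nchar(rows[[off]]), w[1])
    }
    rows
}

#' Construct an external score table
#'
#' Carrier for per-protein scores imported from external predictors
#' (e.g. melting-point index, thermostability rank or intrinsic-disorder
#' scores), together with the measure's thermophilic direction.
#'
#' @param measure measure name.
#' @param scores named numeric vector, protein id -> score.
#' @param direction +1 if larger scores indicate more thermostable, -1
#'   otherwise.
#' @return a `score_table` list with elements `measure`, `scores`,
#'   `direction`.
#' @export
scoreTable <- function(measure, scores, direction) {
    if (!direction %in% c(-1, 1)) stopf("direction must be +1 or -1")
    if (is.null(names(scores)) || anyDuplicated(names(scores)))
        stopf("scores must be uniquely named by protein id")
    structure(list(measure = measure, scores = scores,
                   direction = direction),
              class = "score_table")
}

#' Read an external per-protein score TSV
#'
#' Expects a header line and two columns: protein id and score.
#'
#' @param path TSV path.
#' @param direction thermophilic direction of the measure (+1/-1).
#' @param measure measure name; defaults to the second column's header.
#' @return a `score_table` (see [scoreTable()]).
#' @export
readScoreTable <- function(path, direction, measure = NULL) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stopf("score table needs id and score columns")
    if (is.null(measure)) measure <- colnames(tab)[2]
    sc <- as.numeric(tab[[2]])
    names(sc) <- as.character(tab[[1]])
    scoreTable(measure, sc, direction)
}

#' Read a species phenotype (body temperature) table
#'
#' Two tab-separated columns, species and body temperature in degrees C;
#' a header line is detected and skipped automatically.
#'
#' @param path TSV path.
#' @return named numeric vector, species -> body temperature.
#' @export
readPhenotypeTable <- function(path) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stopf("phenotype table needs species and temperature")
    if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, , drop = FALSE]
    sp <- as.character(tab[[1]])
    temp <- as.numeric(tab[[2]])
    if (anyDuplicated(sp))
        stopf("duplicate species '%s' in phenotype table",
              sp[which(duplicated(sp))[1]])
    if (anyNA(temp) || any(temp < 0 | temp > 50))
        stopf("body temperatures must be numeric and within 0-50 degC")
    names(temp) <- sp
    temp
}

#' Read a melt-curve plate CSV
#'
#' First column is the temperature ramp; every further column is one well's
#' fluorescence series.
#'
#' @param path CSV path.
#' @return list of [MeltCurve-class] objects, one per well column.
#' @export
readMeltPlate <- function(path) {
    tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    if (ncol(tab) < 2L) stopf("melt plate needs a temperature and a well column")
    temps <- as.numeric(tab[[1]])
    wells <- colnames(tab)[-1]
    lapply(seq_along(wells), function(i) {
        new("MeltCurve", temperatures = temps,
            fluorescence = as.numeric(tab[[i + 1L]]),
            wellId = wells[i])
    })
}

#' Species labels attached to a sequence set
#'
#' @param x an `XStringSet` read by [readFasta()].
#' @return character vector of species labels (NA-free) or an error if
#'   none were attached.
#' @export
sequenceSpecies <- function(x) {
    mc <- S4Vectors::mcols(x)
    if (is.null(mc) || !"species" %in% colnames(mc))
        stopf("no species labels attached; pass species= to readFasta()")
    as.character(mc$species)
}
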