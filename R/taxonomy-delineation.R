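# The rank decision engine: combine 16S identity, dDDH, ANI, POCP, clade
# topology flags and phenotype-distinctness flags into
# known-species / new-species / new-genus / new-family calls.
#
# Phenotype distinctness and clade topology arrive as boolean INPUTS (they
# come from BIOLOG/TEM profiling and phylogenetic trees, which this package
# does not compute); encoding them as flags keeps the rule engine total.

EVIDENCE_FIELDS <- c("id16s_best", "ddh", "ani", "pocp", "independent_clade",
                     "neighbor_families_count", "phenotype_distinct_species",
                     "phenotype_distinct_genus", "phenotype_distinct_family")

RANK_LEVELS <- c("known_species", "new_species", "new_genus", "new_family",
                 "ambiguous")

#' Default thresholds of the rank decision engine
#'
#' All boundaries are strict as conventionally printed: 16S identity > 0.987
#' means known species; novelty requires identity < 0.987 (exactly 0.987 is
#' surfaced as `ambiguous`), dDDH < 70, ANI < 95 (or ANI in the closed
#' window \[95, 96\] with distinct species-level phenotype), POCP < 50 and
#' 16S < 0.95 for a new genus, 16S < 0.90 and neighbour genera from at least
#' 2 families for a new family.
#'
#' @return named list of thresholds, suitable for the `thresholds` argument
#'   of [delineate()].
#' @export
delineationThresholds <- function() {
    list(id16sKnown = 0.987, id16sGenus = 0.95, id16sFamily = 0.90,
         ddhSpecies = 70, aniSpecies = 95, aniWindowHigh = 96,
         pocpGenus = 50, minNeighborFamilies = 2L)
}

#' Assemble a taxon evidence record
#'
#' @param id16s_best identity (fraction) to the nearest validly named
#'   species.
#' @param ddh digital DNA-DNA hybridization estimate, percent.
#' @param ani average nucleotide identity, percent.
#' @param pocp percentage of conserved proteins, percent.
#' @param independent_clade does the taxon sit on an independent clade of
#'   the phylogenetic tree?
#' @param neighbor_families_count number of distinct families among the
#'   closest neighbour genera.
#' @param phenotype_distinct_species,phenotype_distinct_genus,phenotype_distinct_family
#'   is the morphology/physiology distinct at the given rank?
#' @return one-row data.frame of evidence.
#' @examples
#' taxonEvidence(id16s_best = 0.93, ddh = 25, ani = 78, pocp = 42,
#'               independent_clade = TRUE, phenotype_distinct_genus = TRUE)
#' @export
taxonEvidence <- function(id16s_best, ddh, ani, pocp,
                          independent_clade = FALSE,
                          neighbor_families_count = 0L,
                          phenotype_distinct_species = FALSE,
                          phenotype_distinct_genus = FALSE,
                          phenotype_distinct_family = FALSE) {
    data.frame(id16s_best = id16s_best, ddh = ddh, ani = ani, pocp = pocp,
               independent_clade = independent_clade,
               neighbor_families_count = neighbor_families_count,
               phenotype_distinct_species = phenotype_distinct_species,
               phenotype_distinct_genus = phenotype_distinct_genus,
               phenotype_distinct_family = phenotype_distinct_family)
}

checkEvidence <- function(e) {
    if (is.list(e) && !is.data.frame(e)) e <- as.data.frame(e)
    missing <- setdiff(EVIDENCE_FIELDS, names(e))
    if (length(missing))
        stop("incomplete evidence: missing field(s) ",
             paste(missing, collapse = ", "))
    bad <- EVIDENCE_FIELDS[vapply(EVIDENCE_FIELDS,
                                  function(f) any(is.na(e[[f]])), logical(1))]
    if (length(bad))
        stop("incomplete evidence: NA in field(s) ",
             paste(bad, collapse = ", "))
    if (any(e$id16s_best < 0 | e$id16s_best > 1))
        stop("id16s_best must be a fraction in [0, 1]")
    if (any(e$ddh < 0 | e$ddh > 100) || any(e$ani < 0 | e$ani > 100) ||
        any(e$pocp < 0 | e$pocp > 100))
        stop("ddh, ani and pocp must be percents in [0, 100]")
    if (any(e$neighbor_families_count < 0))
        stop("neighbor_families_count must be >= 0")
    e
}

#' Delineate the taxonomic rank of a candidate isolate
#'
#' Applies the polyphasic novelty criteria to one evidence record and
#' reports the highest satisfied rank:
#' \itemize{
#'   \item known species iff 16S identity > 98.7%;
#'   \item new species iff 16S identity < 98.7% AND dDDH < 70% AND
#'     (ANI < 95%, or ANI within the closed 95-96% window with a distinct
#'     species-level phenotype);
#'   \item new genus additionally requires 16S < 95%, POCP < 50%, a distinct
#'     genus-level phenotype, and an independent clade;
#'   \item new family additionally requires 16S < 90%, closest neighbour
#'     genera from at least two different families, and a distinct
#'     family-level phenotype.
#' }
#' A 16S identity of exactly 98.7% that satisfies no novelty rank is
#' surfaced as `ambiguous` (the assignment rule treats <= 98.7% as a
#' novel-taxon candidate while the species clause requires < 98.7%), as is
#' any record satisfying neither the known-species rule nor all species
#' clauses.
#'
#' @param evidence a one-row data.frame or named list with the fields of
#'   [taxonEvidence()].
#' @param thresholds threshold configuration; see
#'   [delineationThresholds()].
#' @return list with `rank` (one of `known_species`, `new_species`,
#'   `new_genus`, `new_family`, `ambiguous`), `satisfiedClauses` and
#'   `failedClauses` (rule ids `S1`-`S3`, `G1`-`G4`, `F1`-`F3`).
#' @examples
#' delineate(taxonEvidence(0.96, ddh = 35, ani = 88, pocp = 60))$rank
#' @export
delineate <- function(evidence, thresholds = delineationThresholds()) {
    e <- checkEvidence(evidence)
    if (nrow(e) != 1L) stop("'evidence' must describe a single candidate")
    th <- thresholds
    clauses <- c(
        S1 = e$id16s_best < th$id16sKnown,
        S2 = e$ddh < th$ddhSpecies,
        S3 = e$ani < th$aniSpecies ||
            (e$ani >= th$aniSpecies && e$ani <= th$aniWindowHigh &&
             e$phenotype_distinct_species),
        G1 = e$id16s_best < th$id16sGenus,
        G2 = e$pocp < th$pocpGenus,
        G3 = isTRUE(e$phenotype_distinct_genus),
        G4 = isTRUE(e$independent_clade),
        F1 = e$id16s_best < th$id16sFamily,
        F2 = e$neighbor_families_count >= th$minNeighborFamilies,
        F3 = isTRUE(e$phenotype_distinct_family))
    rank <- if (e$id16s_best > th$id16sKnown) {
        "known_species"
    } else if (all(clauses[c("S1", "S2", "S3")])) {
        if (all(clauses[c("G1", "G2", "G3", "G4")])) {
            if (all(clauses[c("F1", "F2", "F3")])) "new_family"
            else "new_genus"
        } else "new_species"
    } else "ambiguous"
    list(rank = rank,
         satisfiedClauses = names(clauses)[clauses],
         failedClauses = names(clauses)[!clauses])
}

#' Delineate a table of candidates and summarize rank counts
#'
#' @param evidenceTable data.frame with one row per candidate and the fields
#'   of [taxonEvidence()]; row names (or an `id` column) identify
#'   candidates.
#' @inheritParams delineate
#' @return list with `decisions` (data.frame: id, rank, satisfied, failed)
#'   and `counts` (named integer vector over all ranks).
#' @examples
#' tab <- rbind(taxonEvidence(0.99, 80, 98, 70),
#'              taxonEvidence(0.96, 35, 88, 60))
#' delineateBatch(tab)$counts
#' @export
delineateBatch <- function(evidenceTable, thresholds = delineationThresholds()) {
    if (is.null(evidenceTable) || nrow(evidenceTable) == 0L) {
        counts <- setNames(integer(length(RANK_LEVELS)), RANK_LEVELS)
        return(list(decisions = data.frame(id = character(0),
                                           rank = character(0),
                                           satisfied = character(0),
                                           failed = character(0)),
                    counts = counts))
    }
    ids <- if (!is.null(evidenceTable[["id"]]))
               as.character(evidenceTable[["id"]])
           else if (!is.null(rownames(evidenceTable))) rownames(evidenceTable)
           else as.character(seq_len(nrow(evidenceTable)))
    rows <- lapply(seq_len(nrow(evidenceTable)), function(i) {
        d <- tryCatch(
            delineate(evidenceTable[i, EVIDENCE_FIELDS, drop = FALSE],
                      thresholds),
            error = function(err)
                stop("row '", ids[i], "': ", conditionMessage(err),
                     call. = FALSE))
        data.frame(id = ids[i], rank = d$rank,
                   satisfied = paste(d$satisfiedClauses, collapse = ","),
                   failed = paste(d$failedClauses, collapse = ","))
    })
    decisions <- do.call(rbind, rows)
    counts <- table(factor(decisions$rank, levels = RANK_LEVELS))
    list(decisions = decisions,
         counts = setNames(as.integer(counts), RANK_LEVELS))
}
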