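# Nonredundant protein catalog construction and catalog-vs-catalog coverage
# at structural (40%) / functional (60%) identity cutoffs, plus cumulative
# genome-sampling coverage curves.
#
# Protein identity dialect: matches / alignment length, where gapped columns
# count in the length (this differs subtly from BLAST-family identities and
# is used consistently for clustering and coverage).

proteinAlignStats <- function(q, s) {
    aln <- Biostrings::pairwiseAlignment(
        q, s, type = "overlap", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1)
    alnQ <- as.character(Biostrings::alignedPattern(aln))
    alnS <- as.character(Biostrings::alignedSubject(aln))
    a <- strsplit(alnQ, "", fixed = TRUE)[[1L]]
    b <- strsplit(alnS, "", fixed = TRUE)[[1L]]
    list(identity = sum(a == b & a != "-") / base::length(a),
         alnLength = base::length(a))
}

#' Build a nonredundant protein catalog by greedy incremental clustering
#'
#' Sequences are sorted by decreasing length (ties keep input order) and
#' processed in order: a sequence joins the FIRST existing representative it
#' aligns to with identity >= `id` AND an alignment covering at least
#' `covShort` of the SHORTER of the two sequences; otherwise it becomes a
#' new representative. These are the conventional nonredundant-catalog
#' settings (95% identity, 90% coverage of the shorter sequence). Building a
#' catalog from its own representatives returns them unchanged
#' (idempotence).
#'
#' @param proteins a named [Biostrings::AAStringSet] (or [ProteinCatalog],
#'   or named character vector).
#' @param id identity threshold (fraction, default 0.95).
#' @param covShort minimum alignment coverage of the shorter sequence
#'   (default 0.9).
#' @return a [ProteinCatalog] with a populated cluster map.
#' @examples
#' cat <- buildCatalog(Biostrings::AAStringSet(
#'     c(p1 = "MKVLAATTTRGSDE", p2 = "MKVLAATTTRGSDE")))
#' length(representatives(cat))
#' @export
buildCatalog <- function(proteins, id = 0.95, covShort = 0.90) {
    prots <- asAAStringSet(proteins)
    if (base::length(prots) == 0L) stop("catalog input must be non-empty")
    if (is.null(names(prots)))
        names(prots) <- paste0("prot", seq_along(prots))
    ord <- order(-Biostrings::width(prots))
    reps <- character(0)
    rows <- vector("list", base::length(prots))
    for (i in ord) {
        nm <- names(prots)[i]
        assigned <- FALSE
        for (r in reps) {
            st <- proteinAlignStats(prots[[i]], prots[[r]])
            shorter <- min(Biostrings::width(prots)[i],
                           nchar(as.character(prots[[r]])))
            cov <- st$alnLength / shorter
            if (st$identity >= id && cov >= covShort) {
                rows[[i]] <- data.frame(member = nm, representative = r,
                                        identity = st$identity,
                                        coverage = cov)
                assigned <- TRUE
                break
            }
        }
        if (!assigned) {
            reps <- c(reps, nm)
            rows[[i]] <- data.frame(member = nm, representative = nm,
                                    identity = 1, coverage = 1)
        }
    }
    new("ProteinCatalog", entries = prots,
        clusterMap = do.call(rbind, rows[ord]))
}

#' Coverage of a subject catalog by a query catalog
#'
#' A subject entry is hit if some query entry aligns to it with identity
#' >= `idCutoff` and an alignment spanning at least `qcov` of the QUERY
#' length. Coverage is the percentage of subject entries hit. The
#' conventional cutpoints are 60% identity (functional conservation) and
#' 40% (structural conservation), both with 70% query coverage.
#'
#' @param query,subject [ProteinCatalog] objects (their representative
#'   entries are compared; an unbuilt catalog compares all entries).
#' @param idCutoff identity cutoff (fraction).
#' @param qcov minimum alignment length as a fraction of the query length.
#' @return list with `subjectSize`, `nHit`, `coverage` (percent),
#'   `idCutoff`, `qcovCutoff`, and `hits` (logical per subject entry).
#' @export
coverageAgainst <- function(query, subject, idCutoff, qcov = 0.70) {
    q <- representatives(if (is(query, "ProteinCatalog")) query
                         else ProteinCatalog(query))
    s <- representatives(if (is(subject, "ProteinCatalog")) subject
                         else ProteinCatalog(subject))
    if (base::length(s) == 0L) stop("subject catalog must be non-empty")
    hits <- vapply(seq_along(s), function(j) {
        for (i in seq_along(q)) {
            st <- proteinAlignStats(q[[i]], s[[j]])
            if (st$identity >= idCutoff &&
                st$alnLength >= qcov * nchar(as.character(q[[i]])))
                return(TRUE)
        }
        FALSE
    }, logical(1))
    list(subjectSize = base::length(s), nHit = sum(hits),
         coverage = 100 * sum(hits) / base::length(s),
         idCutoff = idCutoff, qcovCutoff = qcov,
         hits = setNames(hits, names(s)))
}

#' Cumulative catalog coverage over randomly ordered genomes
#'
#' Per-genome hit sets against the subject are computed once; the curve
#' value at k is the mean, over `nPerm` random genome orderings, of the
#' union of the first k hit sets divided by the subject size (percent).
#' Monotone non-decreasing; the endpoint equals the all-genome coverage
#' exactly for any seed.
#'
#' @param genomeProteomes named list of per-genome proteomes
#'   ([Biostrings::AAStringSet]).
#' @param subject a [ProteinCatalog].
#' @param idCutoff,qcov hit criteria passed to [coverageAgainst()].
#' @param nPerm number of random orderings.
#' @param seed integer seed.
#' @return data.frame with columns `k`, `mean`, `sd` (coverage percent).
#' @export
cumulativeCoverage <- function(genomeProteomes, subject, idCutoff = 0.40,
                               qcov = 0.70, nPerm = 50L, seed) {
    stopifnot(length(genomeProteomes) >= 1L, nPerm >= 1L)
    subjectSize <- base::length(representatives(subject))
    hitSets <- lapply(genomeProteomes, function(p)
        which(coverageAgainst(ProteinCatalog(p), subject, idCutoff,
                              qcov)$hits))
    n <- length(hitSets)
    cov <- matrix(0, nPerm, n)
    withSeed(seed, {
        for (p in seq_len(nPerm)) {
            ord <- sample.int(n)
            seen <- integer(0)
            for (k in seq_len(n)) {
                seen <- union(seen, hitSets[[ord[k]]])
                cov[p, k] <- 100 * base::length(seen) / subjectSize
            }
        }
    })
    data.frame(k = seq_len(n), mean = colMeans(cov),
               sd = apply(cov, 2, stats::sd))
}

#' Partition a catalog by annotation status
#'
#' Splits the subject entries into annotated and unannotated sub-catalogs
#' (disjoint, order-preserving). Annotation labels are inputs (e.g. from an
#' ortholog-annotation run); every entry must be labeled.
#'
#' @param subject a [ProteinCatalog].
#' @param labels named character vector mapping every entry id to
#'   `"annotated"` or `"unannotated"`.
#' @return list with [ProteinCatalog] elements `annotated` and
#'   `unannotated`.
#' @export
partitionByAnnotation <- function(subject, labels) {
    stopifnot(is(subject, "ProteinCatalog"))
    ids <- names(entries(subject))
    missing <- setdiff(ids, names(labels))
    if (base::length(missing))
        stop("missing annotation label(s) for: ",
             paste(head(missing, 5L), collapse = ", "))
    bad <- setdiff(unique(labels[ids]), c("annotated", "unannotated"))
    if (base::length(bad))
        stop("labels must be 'annotated' or 'unannotated'")
    ann <- ids[labels[ids] == "annotated"]
    list(annotated = ProteinCatalog(entries(subject)[ann]),
         unannotated = ProteinCatalog(entries(subject)[setdiff(ids, ann)]))
}
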