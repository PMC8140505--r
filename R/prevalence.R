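# Equally weighted multi-study prevalence statistics: QC filtering, per-study
# RA/FO summaries, equally weighted averages, dominant/common classification,
# and permutation accumulation curves.

#' Remove low-depth samples from a study table
#'
#' Samples with fewer than `minReads` reads are removed (strict `<`: a
#' sample at exactly the boundary is retained).
#'
#' @param x a [StudyTable] with read counts attached.
#' @param minReads read-count threshold (default 10000).
#' @return the filtered [StudyTable].
#' @examples
#' t <- StudyTable("s", matrix(1, 2, 1, dimnames = list(NULL, "t1")),
#'                 readCounts = c(9999, 10000))
#' dim(qcFilter(t))
#' @export
qcFilter <- function(x, minReads = 10000) {
    stopifnot(is(x, "StudyTable"))
    if (base::length(readCounts(x)) == 0L)
        stop("read counts are required for QC filtering but are absent")
    keep <- readCounts(x) >= minReads
    new("StudyTable", studyId = studyId(x),
        abund = abundances(x)[keep, , drop = FALSE],
        readCounts = readCounts(x)[keep])
}

#' Per-study mean relative abundance and frequency of occurrence
#'
#' FO of a taxon is `100 * (#samples with ra > 0) / n_samples` (by default a
#' taxon is "present" at any positive abundance; `minRa` raises that floor).
#' The mean RA includes samples where the taxon is absent.
#'
#' @param x a [StudyTable] (already QC-filtered as appropriate).
#' @param minRa presence floor for FO (default 0: present iff ra > 0).
#' @return data.frame with columns `taxon`, `mean_ra` (fraction), `fo`
#'   (percent).
#' @examples
#' t <- StudyTable("s", matrix(c(0.2, 0, 0, 0), 4, 1,
#'                             dimnames = list(NULL, "t1")))
#' studySummary(t)
#' @export
studySummary <- function(x, minRa = 0) {
    stopifnot(is(x, "StudyTable"))
    a <- abundances(x)
    if (nrow(a) == 0L) stop("study table has no samples")
    data.frame(taxon = colnames(a),
               mean_ra = unname(colMeans(a)),
               fo = unname(100 * colMeans(a > minRa)),
               row.names = NULL)
}

#' Equally weighted average prevalence across studies
#'
#' The equally weighted RA (FO) of a taxon is the unweighted mean of its
#' per-study mean RAs (FOs), giving every study the same weight regardless
#' of its sample count. A taxon absent from a study contributes
#' `mean_ra = 0`, `fo = 0` for that study.
#'
#' @param summaries list of per-study summaries from [studySummary()] (or
#'   list of [StudyTable] objects, which are summarized first).
#' @return data.frame with columns `taxon`, `ew_ra` (fraction), `ew_fo`
#'   (percent), plus `n_studies`.
#' @examples
#' s1 <- data.frame(taxon = "t", mean_ra = 0.002, fo = 40)
#' s2 <- data.frame(taxon = "t", mean_ra = 0.0005, fo = 20)
#' equallyWeighted(list(s1, s2))
#' @export
equallyWeighted <- function(summaries) {
    if (length(summaries) == 0L) stop("at least one study is required")
    summaries <- lapply(summaries, function(s)
        if (is(s, "StudyTable")) studySummary(s) else s)
    taxa <- unique(unlist(lapply(summaries, `[[`, "taxon")))
    ra <- fo <- matrix(0, length(summaries), length(taxa),
                       dimnames = list(NULL, taxa))
    for (i in seq_along(summaries)) {
        s <- summaries[[i]]
        ra[i, s$taxon] <- s$mean_ra
        fo[i, s$taxon] <- s$fo
    }
    data.frame(taxon = taxa,
               ew_ra = unname(colMeans(ra)),
               ew_fo = unname(colMeans(fo)),
               n_studies = length(summaries),
               row.names = NULL)
}

#' Classify taxa as dominant, common, and core
#'
#' Dominant iff equally weighted RA strictly exceeds `raThresh` (default
#' 0.001, i.e. RA > 0.1%); common iff equally weighted FO strictly exceeds
#' `foThresh` (default 30%); core = dominant AND common.
#'
#' @param prev data.frame from [equallyWeighted()].
#' @param raThresh dominance boundary on `ew_ra` (fraction, strict >).
#' @param foThresh commonness boundary on `ew_fo` (percent, strict >).
#' @return `prev` with added logical columns `dominant`, `common`, `core`.
#' @examples
#' classifyTaxa(data.frame(taxon = "t", ew_ra = 0.00125, ew_fo = 30))
#' @export
classifyTaxa <- function(prev, raThresh = 0.001, foThresh = 30) {
    prev$dominant <- prev$ew_ra > raThresh
    prev$common <- prev$ew_fo > foThresh
    prev$core <- prev$dominant & prev$common
    prev
}

#' Taxon accumulation curve over studies
#'
#' The value at k is the mean, over `nPerm` random study orderings, of the
#' number of distinct detected taxa in the first k studies (a taxon is
#' detected in a study if its per-study FO is positive). The curve is
#' monotone non-decreasing and its endpoint equals the union richness
#' exactly, for any seed.
#'
#' @inheritParams equallyWeighted
#' @param nPerm number of random orderings (>= 1).
#' @param seed integer seed for the permutations.
#' @return data.frame with columns `k`, `mean`, `sd`.
#' @examples
#' s1 <- data.frame(taxon = c("a", "b"), mean_ra = 0.1, fo = 50)
#' s2 <- data.frame(taxon = c("b", "c"), mean_ra = 0.1, fo = 50)
#' accumulationCurve(list(s1, s2), nPerm = 10, seed = 1)
#' @export
accumulationCurve <- function(summaries, nPerm = 100L, seed) {
    stopifnot(nPerm >= 1L)
    summaries <- lapply(summaries, function(s)
        if (is(s, "StudyTable")) studySummary(s) else s)
    sets <- lapply(summaries, function(s) unique(s$taxon[s$fo > 0]))
    n <- length(sets)
    if (n == 0L) stop("at least one study is required")
    richness <- matrix(0L, nPerm, n)
    withSeed(seed, {
        for (p in seq_len(nPerm)) {
            ord <- sample.int(n)
            seen <- character(0)
            for (k in seq_len(n)) {
                seen <- union(seen, sets[[ord[k]]])
                richness[p, k] <- base::length(seen)
            }
        }
    })
    data.frame(k = seq_len(n),
               mean = colMeans(richness),
               sd = apply(richness, 2, stats::sd))
}

#' Read a manifest of per-study abundance TSVs
#'
#' The manifest is a TSV with columns `study_id` and `path`; each path
#' points to a samples-by-taxa abundance table (header row of taxon names,
#' first column sample ids, fractions not percents), optionally with a
#' `reads` column giving per-sample read counts.
#'
#' @param manifest path to the manifest TSV.
#' @return list of [StudyTable] objects.
#' @export
readStudyManifest <- function(manifest) {
    man <- read.delim(manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("study_id", "path") %in% names(man)))
    base <- dirname(manifest)
    lapply(seq_len(nrow(man)), function(i) {
        p <- man$path[i]
        if (!file.exists(p)) p <- file.path(base, p)
        tab <- read.delim(p, row.names = 1L, check.names = FALSE)
        reads <- numeric(0)
        if ("reads" %in% names(tab)) {
            reads <- tab$reads
            tab <- tab[, setdiff(names(tab), "reads"), drop = FALSE]
        }
        StudyTable(man$study_id[i], as.matrix(tab), readCounts = reads)
    })
}
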