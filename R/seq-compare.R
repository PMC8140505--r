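# Pairwise 16S comparison: global alignment identity, Kimura 2-parameter
# distance, greedy centroid clustering, and known-species assignment at the
# 98.7% boundary.
#
# Identity dialect used everywhere in this package: matches over ungapped,
# unambiguous alignment columns of an ends-free global alignment (terminal
# gaps unpenalized and excluded). Ambiguous bases (N, R, Y, ...) are excluded
# from the compared sites for both identity and the K2P counts.

checkNucleotides <- function(x, what = "sequence") {
    s <- asDNAString(x, what)  # DNAString constructor enforces IUPAC alphabet
    if (length(s) == 0L) stop(what, " must be non-empty")
    s
}

#' Align two nucleotide sequences and tabulate column statistics
#'
#' Performs a global (Needleman-Wunsch) alignment with unit match/mismatch
#' scores and returns the aligned strings together with the counts that
#' identity and the K2P distance are computed from. Gap columns - including
#' terminal ones - and columns with ambiguity codes are excluded from the
#' compared sites, so terminal overhangs never count against identity.
#'
#' @param a,b nucleotide sequences (character or
#'   [Biostrings::DNAString]); IUPAC ambiguity codes are tolerated but
#'   excluded from compared sites.
#' @return object of class `NucAlignment`: a list with `alignedA`,
#'   `alignedB`, `matches`, `mismatches`, `transitions`, `transversions`,
#'   `comparedSites`.
#' @examples
#' aln <- nucAlignment("ACGTACGT", "ACGTGCGT")
#' aln$mismatches
#' @export
nucAlignment <- function(a, b) {
    a <- checkNucleotides(a, "'a'")
    b <- checkNucleotides(b, "'b'")
    aln <- Biostrings::pairwiseAlignment(
        a, b, type = "global", substitutionMatrix = iupacSubMatrix(),
        gapOpening = 2, gapExtension = 1)
    alnA <- as.character(Biostrings::alignedPattern(aln))
    alnB <- as.character(Biostrings::alignedSubject(aln))
    stats <- nucAlignStats(alnA, alnB)
    structure(c(list(alignedA = alnA, alignedB = alnB), stats),
              class = "NucAlignment")
}

#' @export
print.NucAlignment <- function(x, ...) {
    cat(sprintf(
        "NucAlignment: %d compared sites, %d matches, %d ts + %d tv mismatches\n",
        x$comparedSites, x$matches, x$transitions, x$transversions))
    invisible(x)
}

#' Global alignment identity of two nucleotide sequences
#'
#' Identity is `matches / comparedSites` from a global alignment; gap
#' columns (terminal ones included) and ambiguous bases do not count as
#' compared sites, so overhangs are never penalized. Symmetric in its
#' arguments. Orientation is the caller's responsibility (a sequence and its
#' reverse complement simply score low).
#'
#' @inheritParams nucAlignment
#' @return identity fraction in \[0, 1\].
#' @examples
#' alignIdentity("ACGTACGTACGT", "ACGTACGTACGT")
#' @export
alignIdentity <- function(a, b) {
    aln <- nucAlignment(a, b)
    if (aln$comparedSites == 0L)
        stop("no comparable (ungapped, unambiguous) alignment columns")
    aln$matches / aln$comparedSites
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` where `P` and `Q` are the
#' transition and transversion proportions over the compared (ungapped,
#' unambiguous) sites of a pairwise alignment, i.e. pairwise deletion of
#' gapped/ambiguous columns. Saturated pairs (log argument not positive)
#' raise a condition of class `k2pSaturationError`.
#'
#' @param x a `NucAlignment` (from [nucAlignment()]), or the first of two
#'   nucleotide sequences.
#' @param y optional second sequence when `x` is a sequence.
#' @return distance in substitutions per site (>= 0; 0 iff P = Q = 0).
#' @examples
#' k2pDistance(nucAlignment("ACGTACGTACGTACGT", "ACGTACGTACGTACGT"))
#' @export
k2pDistance <- function(x, y = NULL) {
    if (!inherits(x, "NucAlignment")) x <- nucAlignment(x, y)
    if (x$comparedSites <= 0L) stop("comparedSites must be > 0")
    P <- x$transitions / x$comparedSites
    Q <- x$transversions / x$comparedSites
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0)
        stop(structure(class = c("k2pSaturationError", "error", "condition"),
                       list(message = sprintf(
                           "K2P distance saturated (P=%.3f, Q=%.3f)", P, Q),
                           call = sys.call(-1))))
    -0.5 * log(w1 * sqrt(w2))
}

#' Greedy centroid clustering of nucleotide sequences
#'
#' Reimplements the centroid-based greedy strategy of species-level 16S
#' clustering: sequences are processed in decreasing length order (ties keep
#' input order); each sequence joins the FIRST existing centroid it matches
#' with [alignIdentity()] at or above `threshold`, otherwise it founds a new
#' cluster. Deterministic by construction.
#'
#' @param seqs a named [Biostrings::DNAStringSet] (or named character
#'   vector).
#' @param threshold identity threshold in (0, 1); default 0.987, the
#'   species boundary.
#' @return a [ClusterSet].
#' @examples
#' cs <- greedyCluster(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"))
#' length(cs)
#' @export
greedyCluster <- function(seqs, threshold = 0.987) {
    stopifnot(threshold > 0, threshold < 1)
    seqs <- asDNAStringSet(seqs)
    if (length(seqs) == 0L)
        return(new("ClusterSet", threshold = threshold,
                   membership = data.frame(member = character(0),
                                           centroid = character(0),
                                           identity = numeric(0))))
    if (is.null(names(seqs)))
        names(seqs) <- paste0("seq", seq_along(seqs))
    ord <- order(-Biostrings::width(seqs))  # stable: ties keep input order
    centroidIds <- character(0)
    rows <- vector("list", length(seqs))
    for (i in ord) {
        id <- names(seqs)[i]
        assigned <- FALSE
        for (cid in centroidIds) {
            ident <- alignIdentity(seqs[[i]], seqs[[cid]])
            if (ident >= threshold) {
                rows[[i]] <- data.frame(member = id, centroid = cid,
                                        identity = ident)
                assigned <- TRUE
                break
            }
        }
        if (!assigned) {
            centroidIds <- c(centroidIds, id)
            rows[[i]] <- data.frame(member = id, centroid = id, identity = 1)
        }
    }
    new("ClusterSet", threshold = threshold,
        membership = do.call(rbind, rows[ord]))
}

#' Assign a query 16S sequence to a known species or flag it as novel
#'
#' A query is a known species iff its best identity to any reference exceeds
#' 98.7% (strict). A best identity of exactly 0.987 is a novel-taxon
#' candidate ("identities <= 98.7% are candidates of novel taxa").
#'
#' @param query nucleotide sequence.
#' @param refs named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference species sequences.
#' @param threshold identity boundary (default 0.987).
#' @return list with `bestName`, `identity`, and `status`
#'   (`"known"` or `"novel_candidate"`).
#' @examples
#' assignKnownSpecies("ACGTACGTACGTACGT",
#'                    c(sp1 = "ACGTACGTACGTACGT"))
#' @export
assignKnownSpecies <- function(query, refs, threshold = 0.987) {
    refs <- asDNAStringSet(refs)
    if (length(refs) == 0L) stop("reference set must be non-empty")
    if (is.null(names(refs)))
        names(refs) <- paste0("ref", seq_along(refs))
    ids <- vapply(seq_along(refs),
                  function(i) alignIdentity(query, refs[[i]]), numeric(1))
    best <- which.max(ids)
    list(bestName = names(refs)[best],
         identity = ids[best],
         status = if (ids[best] > threshold) "known" else "novel_candidate")
}

#' Write cluster membership and centroid sequences to files
#'
#' @param x a [ClusterSet].
#' @param seqs the sequences that were clustered.
#' @param tsv path for the membership TSV (member, centroid, identity).
#' @param fasta optional path for the centroid FASTA.
#' @return invisibly, the TSV path.
#' @export
writeClusterSet <- function(x, seqs, tsv, fasta = NULL) {
    stopifnot(is(x, "ClusterSet"))
    writeTSV(clusterMembership(x), tsv)
    if (!is.null(fasta))
        Biostrings::writeXStringSet(asDNAStringSet(seqs)[centroids(x)], fasta)
    invisible(tsv)
}
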