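# Synthetic-data generators: genome pairs, 16S pairs, proteome pairs and
# multi-study abundance tables with known ground truth. Everything is
# deterministic given `seed`, and divergence is introduced by sampling sites
# WITHOUT replacement so that realized identity equals the target exactly.

randomBases <- function(n) sample(DNA_BASES, n, replace = TRUE)

# Substitute `nSub` distinct positions of character vector `x`, always to a
# different base.
substituteSites <- function(x, nSub) {
    if (nSub == 0L) return(x)
    pos <- sample.int(length(x), nSub)
    x[pos] <- vapply(x[pos],
                     function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    x
}

splitContigs <- function(chars, nContigs, prefix) {
    n <- length(chars)
    bounds <- floor(seq(0, n, length.out = nContigs + 1L))
    seqs <- vapply(seq_len(nContigs), function(i)
        paste(chars[(bounds[i] + 1L):bounds[i + 1L]], collapse = ""), "")
    DNAStringSet(setNames(seqs, paste0(prefix, "_c", seq_len(nContigs))))
}

#' Generate a genome pair diverged to a target ANI
#'
#' Draws a random ancestor of `ancestorLength` bp and derives two genomes from
#' it: the first is the ancestor itself, the second carries exactly
#' `round(ancestorLength * (1 - targetAni))` point substitutions placed
#' uniformly at random without replacement, so the site-wise identity of the
#' (known) ancestral alignment is exact. Optionally, short indels (1-3 bp)
#' are added afterwards at rate `indelRate` per site; indels are not counted
#' in `truthAni`, and fragment-based ANI recovery on indel-bearing pairs is
#' only expected within about two percentage points.
#'
#' @param ancestorLength ancestor length in bp (>= 10000).
#' @param targetAni target fraction identity in (0.5, 1].
#' @param indelRate per-site indel rate (default 0).
#' @param nContigs number of contigs each genome is split into.
#' @param seed integer seed; same seed gives bit-identical output.
#' @return list with elements `genomeA`, `genomeB` (both
#'   [GenomeAssembly]) and `truthAni` (exact ancestral site identity).
#' @examples
#' gp <- makeGenomePair(20000, 0.95, seed = 1)
#' gp$truthAni
#' @export
makeGenomePair <- function(ancestorLength, targetAni, indelRate = 0,
                           nContigs = 1L, seed) {
    stopifnot(ancestorLength >= 10000, nContigs >= 1L, indelRate >= 0)
    if (targetAni <= 0.5 || targetAni > 1)
        stop("'targetAni' must be in (0.5, 1]; values <= 0.5 are below the ",
             "validity range of fragment-based ANI")
    withSeed(seed, {
        anc <- randomBases(ancestorLength)
        nSub <- round(ancestorLength * (1 - targetAni))
        der <- substituteSites(anc, nSub)
        if (indelRate > 0) {
            nIndel <- round(ancestorLength * indelRate)
            for (i in seq_len(nIndel)) {
                at <- sample.int(length(der) - 4L, 1L)
                len <- sample.int(3L, 1L)
                if (runif(1) < 0.5)
                    der <- append(der, randomBases(len), after = at)
                else
                    der <- der[-(at:(at + len - 1L))]
            }
        }
        list(genomeA = GenomeAssembly("genomeA",
                                      splitContigs(anc, nContigs, "A")),
             genomeB = GenomeAssembly("genomeB",
                                      splitContigs(der, nContigs, "B")),
             truthAni = 1 - nSub / ancestorLength)
    })
}

#' Generate a 16S rRNA gene pair at a target identity
#'
#' The second sequence differs from the first at exactly
#' `round(length * (1 - targetIdentity))` sites, so the ungapped site
#' identity of the pair equals the target within 1/length.
#'
#' @param length sequence length in bp (>= 1200, full-length 16S scale).
#' @param targetIdentity fraction in (0, 1].
#' @param seed integer seed.
#' @return named [Biostrings::DNAStringSet] of length 2 (`ssuA`, `ssuB`).
#' @examples
#' pr <- makeSSUPair(1500, 0.987, seed = 3)
#' @export
makeSSUPair <- function(length, targetIdentity, seed) {
    if (length < 1200)
        stop("'length' must be >= 1200 bp (full-length 16S scale)")
    if (targetIdentity <= 0 || targetIdentity > 1)
        stop("'targetIdentity' must be in (0, 1]")
    withSeed(seed, {
        a <- randomBases(length)
        b <- substituteSites(a, round(length * (1 - targetIdentity)))
        DNAStringSet(c(ssuA = paste(a, collapse = ""),
                       ssuB = paste(b, collapse = "")))
    })
}

#' Generate a proteome pair with a designed conserved fraction
#'
#' Builds two proteomes of `n1` and `n2` proteins sharing exactly
#' `conservedPairs` homolog pairs; each conserved pair is an ancestor protein
#' plus a copy with `round(proteinLength * (1 - conservedIdentity))`
#' residue substitutions (without replacement), which by construction passes
#' the POCP hit criteria (identity > 40%, full-length alignment, tiny
#' E-value). All remaining proteins are independent random sequences.
#'
#' @param n1,n2 protein counts of the two proteomes.
#' @param conservedPairs number of designed homolog pairs
#'   (`<= min(n1, n2)`).
#' @param conservedIdentity fraction identity of each conserved pair; must
#'   exceed the 0.4 POCP hit criterion.
#' @param proteinLength protein length in residues.
#' @param seed integer seed.
#' @return list with `proteomeA`, `proteomeB` (named
#'   [Biostrings::AAStringSet]) and `truthPocp` =
#'   `100 * 2 * conservedPairs / (n1 + n2)`.
#' @examples
#' pp <- makeProteomePair(4, 4, conservedPairs = 2, seed = 5)
#' pp$truthPocp
#' @export
makeProteomePair <- function(n1, n2, conservedPairs,
                             conservedIdentity = 0.9,
                             proteinLength = 250L, seed) {
    stopifnot(n1 >= 1, n2 >= 1, conservedPairs >= 0,
              conservedPairs <= min(n1, n2), proteinLength >= 30)
    if (conservedIdentity <= 0.4)
        stop("'conservedIdentity' must exceed the 40% POCP hit criterion; ",
             "below it the designed truth is undefined")
    withSeed(seed, {
        randProt <- function()
            paste(sample(AA_RESIDUES, proteinLength, replace = TRUE),
                  collapse = "")
        mutProt <- function(p) {
            x <- strsplit(p, "", fixed = TRUE)[[1L]]
            nSub <- round(proteinLength * (1 - conservedIdentity))
            pos <- if (nSub) sample.int(proteinLength, nSub) else integer(0)
            x[pos] <- vapply(x[pos],
                             function(r) sample(setdiff(AA_RESIDUES, r), 1L),
                             "")
            paste(x, collapse = "")
        }
        cons <- vapply(seq_len(conservedPairs), function(i) randProt(), "")
        a <- c(cons, vapply(seq_len(n1 - conservedPairs),
                            function(i) randProt(), character(1)))
        b <- c(vapply(cons, mutProt, "", USE.NAMES = FALSE),
               vapply(seq_len(n2 - conservedPairs),
                      function(i) randProt(), character(1)))
        list(proteomeA = AAStringSet(setNames(a, paste0("pA_", seq_len(n1)))),
             proteomeB = AAStringSet(setNames(b, paste0("pB_", seq_len(n2)))),
             truthPocp = 100 * 2 * conservedPairs / (n1 + n2))
    })
}

#' Generate multi-study OTU tables with known presence structure
#'
#' Emulates a multi-study 16S amplicon compilation: for each study, each
#' taxon is present in a sample with the study-specific probability
#' `presenceProb[study, taxon]`, and present taxa receive heavy-tailed
#' lognormal abundance draws that are renormalized so every sample's relative
#' abundances sum to one. A sample that draws no taxa at all is re-drawn (the
#' empty sample would have no classified reads). Per-sample read counts are
#' drawn lognormally around `meanReads` to support QC filtering.
#'
#' @param nStudies number of studies.
#' @param samplesPerStudy integer vector of per-study sample counts
#'   (length `nStudies`).
#' @param taxa character vector of taxon ids.
#' @param presenceProb `nStudies` x `length(taxa)` matrix of presence
#'   probabilities.
#' @param abundanceLaw list with `meanlog` and `sdlog` of the lognormal
#'   abundance law.
#' @param meanReads geometric-mean per-sample read count.
#' @param seed integer seed.
#' @return list of [StudyTable] objects, one per study.
#' @examples
#' tabs <- makeOtuTables(2, c(5, 5), c("t1", "t2"),
#'                       matrix(0.8, 2, 2), seed = 9)
#' @export
makeOtuTables <- function(nStudies, samplesPerStudy, taxa, presenceProb,
                          abundanceLaw = list(meanlog = 0, sdlog = 2),
                          meanReads = 30000, seed) {
    if (length(samplesPerStudy) != nStudies)
        stop("'samplesPerStudy' must have one entry per study")
    presenceProb <- matrix(presenceProb, nrow = nStudies,
                           ncol = length(taxa))
    withSeed(seed, {
        lapply(seq_len(nStudies), function(s) {
            n <- samplesPerStudy[s]
            m <- matrix(0, n, length(taxa),
                        dimnames = list(paste0("s", s, "_", seq_len(n)),
                                        taxa))
            for (i in seq_len(n)) {
                repeat {
                    pres <- runif(length(taxa)) < presenceProb[s, ]
                    if (any(pres)) break
                    if (all(presenceProb[s, ] == 0)) break
                }
                if (any(pres)) {
                    ab <- rlnorm(sum(pres), abundanceLaw$meanlog,
                                 abundanceLaw$sdlog)
                    m[i, pres] <- ab / sum(ab)
                }
            }
            StudyTable(paste0("study", s), m,
                       readCounts = round(rlnorm(n, log(meanReads), 0.4)))
        })
    })
}
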