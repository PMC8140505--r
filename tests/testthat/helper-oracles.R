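# Independent oracles used across the suite. These are deliberately naive
# (direct counting, closed forms, exhaustive enumeration) and never share
# code with the implementation paths they check.

# Site-wise identity of two equal-length, gap-free sequences by direct
# character comparison (no aligner involved).
siteIdentityOracle <- function(a, b) {
    x <- strsplit(as.character(a), "")[[1]]
    y <- strsplit(as.character(b), "")[[1]]
    stopifnot(length(x) == length(y))
    sum(x == y) / length(x)
}

# Transition/transversion counts of two equal-length gap-free sequences.
tsTvOracle <- function(a, b) {
    x <- strsplit(as.character(a), "")[[1]]
    y <- strsplit(as.character(b), "")[[1]]
    mm <- which(x != y)
    pur <- c("A", "G")
    ts <- sum((x[mm] %in% pur) == (y[mm] %in% pur))
    c(transitions = ts, transversions = length(mm) - ts,
      sites = length(x))
}

# Closed-form K2P distance.
k2pOracle <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

# Closed-form Mash distance from a Jaccard index.
mashOracle <- function(j, k) if (j == 0) 1.0 else -(1 / k) * log(2 * j / (1 + j))

# Brute-force N50: the largest contig length L such that contigs >= L sum to
# at least half of the total, found by scanning every candidate length.
n50Oracle <- function(widths) {
    tot <- sum(widths)
    cand <- sort(unique(widths), decreasing = TRUE)
    for (L in cand) if (sum(widths[widths >= L]) >= tot / 2) return(L)
    min(widths)
}

# Exhaustive rank oracle: literal transcription of the novelty criteria,
# evaluated clause by clause with no shared code with delineate().
rankOracle <- function(id16s, ddh, ani, pocp, clade, nfam,
                       phS, phG, phF) {
    if (id16s > 0.987) return("known_species")
    sp <- (id16s < 0.987) && (ddh < 70) &&
        (ani < 95 || (ani >= 95 && ani <= 96 && phS))
    if (!sp) return("ambiguous")
    ge <- (id16s < 0.95) && (pocp < 50) && phG && clade
    if (!ge) return("new_species")
    fa <- (id16s < 0.90) && (nfam >= 2) && phF
    if (fa) "new_family" else "new_genus"
}

# All-pairs identity matrix through the package's own alignIdentity (used
# only to confirm synthetic group structure, not as the clustering oracle).
identityMatrix <- function(seqs) {
    n <- length(seqs)
    m <- matrix(1, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        m[i, j] <- m[j, i] <- alignIdentity(seqs[[i]], seqs[[j]])
    m
}

# Random 16S-scale sequence groups: `n` members per group at within-group
# divergence `div`, groups mutually unrelated.
makeSequenceGroups <- function(nGroups, n, len = 1300, div = 0.004,
                               seed = 1) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    out <- character(0)
    for (g in seq_len(nGroups)) {
        anc <- sample(bases, len, replace = TRUE)
        for (i in seq_len(n)) {
            x <- anc
            pos <- sample(len, round(len * div))
            x[pos] <- vapply(x[pos],
                             function(b) sample(setdiff(bases, b), 1), "")
            out[sprintf("g%d_%d", g, i)] <- paste(x, collapse = "")
        }
    }
    Biostrings::DNAStringSet(out)
}
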