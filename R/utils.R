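# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generators never perturb user code.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

asDNAString <- function(x, what = "sequence") {
    if (is(x, "DNAString")) return(x)
    if (is(x, "DNAStringSet")) {
        if (length(x) != 1L) stop("expected a single ", what)
        return(x[[1L]])
    }
    if (is.character(x) && length(x) == 1L) {
        if (nchar(x) == 0L) stop(what, " must be non-empty")
        return(Biostrings::DNAString(x))
    }
    stop(what, " must be a DNAString or single character string")
}

asDNAStringSet <- function(x) {
    if (is(x, "DNAStringSet")) return(x)
    if (is(x, "SSUCollection")) return(collectionSequences(x))
    DNAStringSet(x)
}

asAAStringSet <- function(x) {
    if (is(x, "AAStringSet")) return(x)
    if (is(x, "ProteinCatalog")) return(entries(x))
    AAStringSet(x)
}

# Substitution matrix over the full IUPAC nucleotide alphabet; unit scores so
# alignment optimizes the edit-like criterion the identity definition uses.
iupacSubMatrix <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- Biostrings::nucleotideSubstitutionMatrix(
                match = 1, mismatch = -1, baseOnly = FALSE, type = "DNA")
        cache
    }
})

# Column-wise statistics of a global (ends-free) nucleotide alignment.
# Compared sites are ungapped columns where both bases are unambiguous
# (A/C/G/T); ambiguity codes are excluded from all counts. Transitions are
# A<->G and C<->T; all other mismatches are transversions.
nucAlignStats <- function(alnA, alnB) {
    a <- strsplit(alnA, "", fixed = TRUE)[[1L]]
    b <- strsplit(alnB, "", fixed = TRUE)[[1L]]
    keep <- a %in% DNA_BASES & b %in% DNA_BASES
    a <- a[keep]; b <- b[keep]
    match <- a == b
    mm <- !match
    purA <- a %in% c("A", "G")
    purB <- b %in% c("A", "G")
    transitions <- sum(mm & (purA == purB))
    list(matches = sum(match),
         mismatches = sum(mm),
         transitions = transitions,
         transversions = sum(mm) - transitions,
         comparedSites = length(a))
}

# Minimal union-find for single-linkage component construction.
unionFind <- function(n) {
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    list(union = function(i, j) {
             ri <- find(i); rj <- find(j)
             if (ri != rj) parent[ri] <<- rj
         },
         components = function() {
             roots <- vapply(seq_len(n), find, integer(1))
             match(roots, unique(roots))
         })
}

writeTSV <- function(df, file) {
    write.table(df, file = file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(file)
}
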