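#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet pairwiseAlignment
#'   nucleotideSubstitutionMatrix letterFrequency width readDNAStringSet
#'   readAAStringSet writeXStringSet alignedPattern alignedSubject
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importFrom stats rlnorm runif setNames plogis
#' @importFrom utils head read.delim write.table
#' @useDynLib PolyphasicTaxa, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' GenomeAssembly: a named set of nucleotide contigs
#'
#' Container for one genome assembly, the unit on which ANI, MinHash distance,
#' G+C content and assembly QC are computed.
#'
#' @slot assemblyName single character identifier.
#' @slot contigs a [Biostrings::DNAStringSet] of contig sequences.
#'
#' @examples
#' ga <- GenomeAssembly("toy", Biostrings::DNAStringSet(c(c1 = "ACGTACGT")))
#' gcContent(ga)
#' @export
setClass("GenomeAssembly",
    representation(assemblyName = "character", contigs = "DNAStringSet"))

setValidity("GenomeAssembly", function(object) {
    msg <- NULL
    if (length(object@assemblyName) != 1L || is.na(object@assemblyName))
        msg <- c(msg, "'assemblyName' must be a single non-NA string")
    if (length(object@contigs) == 0L)
        msg <- c(msg, "assembly must contain at least one contig")
    else if (sum(Biostrings::width(object@contigs)) == 0L)
        msg <- c(msg, "total assembly length must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' @param assemblyName single character identifier.
#' @param contigs a [Biostrings::DNAStringSet], plain character vector of
#'   contig sequences, or path to a (multi-)FASTA file.
#' @rdname GenomeAssembly-class
#' @export
GenomeAssembly <- function(assemblyName, contigs) {
    if (is.character(contigs)) {
        contigs <- if (length(contigs) == 1L && file.exists(contigs))
            readDNAStringSet(contigs) else DNAStringSet(contigs)
    }
    new("GenomeAssembly", assemblyName = assemblyName, contigs = contigs)
}

#' MashSketch: a MinHash bottom sketch of a genome
#'
#' Holds the smallest `sketchSize` 53-bit hashes of the canonical k-mers of a
#' genome (a k-mer and its reverse complement hash identically). Two sketches
#' built with the same `k` can be compared with [mashDistance()].
#'
#' @slot k k-mer size.
#' @slot sketchSize maximum number of retained minimum hashes.
#' @slot hashes sorted numeric vector of distinct minimum hash values.
#' @export
setClass("MashSketch",
    representation(k = "integer", sketchSize = "integer", hashes = "numeric"))

setValidity("MashSketch", function(object) {
    msg <- NULL
    if (length(object@hashes) > object@sketchSize)
        msg <- c(msg, "more hashes than sketchSize")
    if (is.unsorted(object@hashes, strictly = TRUE))
        msg <- c(msg, "'hashes' must be strictly increasing")
    if (is.null(msg)) TRUE else msg
})

#' ClusterSet: greedy centroid clustering result
#'
#' @slot membership data.frame with columns `member`, `centroid`, `identity`.
#' @slot threshold identity threshold used for clustering (fraction).
#' @export
setClass("ClusterSet",
    representation(membership = "data.frame", threshold = "numeric"))

setValidity("ClusterSet", function(object) {
    m <- object@membership
    need <- c("member", "centroid", "identity")
    if (!all(need %in% names(m)))
        return("membership must have columns member, centroid, identity")
    if (anyDuplicated(m$member))
        return("every sequence must appear in exactly one cluster")
    if (nrow(m) && !all(m$centroid %in% m$member))
        return("centroids must be members of their own clusters")
    TRUE
})

#' StudyTable: one study's samples-by-taxa relative-abundance matrix
#'
#' Rows are samples, columns are taxa, entries are fractions of each sample's
#' classified reads. Optional per-sample read counts support QC filtering.
#'
#' @slot studyId single character study identifier.
#' @slot abund numeric matrix, samples x taxa, fractions.
#' @slot readCounts integer vector parallel to rows (or length 0 when absent).
#' @export
setClass("StudyTable",
    representation(studyId = "character", abund = "matrix",
                   readCounts = "numeric"))

setValidity("StudyTable", function(object) {
    msg <- NULL
    a <- object@abund
    if (is.null(colnames(a)))
        msg <- c(msg, "abundance matrix must have taxon column names")
    if (any(a < 0)) msg <- c(msg, "abundances must be >= 0")
    if (nrow(a) && any(rowSums(a) > 1 + 1e-9))
        msg <- c(msg, "sample abundances must sum to <= 1 + 1e-9")
    if (length(object@readCounts) && length(object@readCounts) != nrow(a))
        msg <- c(msg, "readCounts length must match the number of samples")
    if (is.null(msg)) TRUE else msg
})

#' @param studyId single character study identifier.
#' @param abund samples x taxa numeric matrix of fractions, or path to a TSV
#'   with samples as rows and taxa as columns.
#' @param readCounts optional per-sample read counts (for [qcFilter()]).
#' @rdname StudyTable-class
#' @export
StudyTable <- function(studyId, abund, readCounts = numeric(0)) {
    if (is.character(abund))
        abund <- as.matrix(read.delim(abund, row.names = 1L,
                                      check.names = FALSE))
    new("StudyTable", studyId = studyId, abund = abund,
        readCounts = as.numeric(readCounts))
}

#' ProteinCatalog: amino-acid sequences with cluster-representative structure
#'
#' Before [buildCatalog()] the cluster map is empty; afterwards every entry
#' maps to exactly one representative and representatives are a subset of the
#' entries.
#'
#' @slot entries a named [Biostrings::AAStringSet].
#' @slot clusterMap data.frame with columns `member`, `representative`,
#'   `identity`, `coverage` (empty until the catalog is built).
#' @export
setClass("ProteinCatalog",
    representation(entries = "AAStringSet", clusterMap = "data.frame"))

setValidity("ProteinCatalog", function(object) {
    msg <- NULL
    if (length(object@entries) && is.null(names(object@entries)))
        msg <- c(msg, "entries must be named")
    cm <- object@clusterMap
    if (nrow(cm)) {
        if (anyDuplicated(cm$member))
            msg <- c(msg, "every member must map to exactly one representative")
        if (!all(cm$representative %in% names(object@entries)))
            msg <- c(msg, "representatives must be catalog entries")
    }
    if (is.null(msg)) TRUE else msg
})

#' @param entries a named [Biostrings::AAStringSet], named character vector of
#'   amino-acid sequences, or path to a protein FASTA file.
#' @rdname ProteinCatalog-class
#' @export
ProteinCatalog <- function(entries) {
    if (is.character(entries)) {
        entries <- if (length(entries) == 1L && file.exists(entries))
            readAAStringSet(entries) else AAStringSet(entries)
    }
    new("ProteinCatalog", entries = entries,
        clusterMap = data.frame(member = character(0),
                                representative = character(0),
                                identity = numeric(0),
                                coverage = numeric(0)))
}

#' SSUCollection: a named collection of 16S rRNA gene sequences
#'
#' One culture collection's inventory of (near) full-length 16S sequences,
#' the unit of within-collection dereplication and cross-collection overlap.
#'
#' @slot collectionName single character identifier.
#' @slot sequences a named [Biostrings::DNAStringSet].
#' @export
setClass("SSUCollection",
    representation(collectionName = "character", sequences = "DNAStringSet"))

setValidity("SSUCollection", function(object) {
    msg <- NULL
    if (length(object@sequences) == 0L)
        msg <- c(msg, "collection must contain at least one sequence")
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "sequence ids must be present and unique")
    if (is.null(msg)) TRUE else msg
})

#' @param collectionName single character identifier.
#' @param sequences a named [Biostrings::DNAStringSet], named character
#'   vector, or path to a FASTA file.
#' @rdname SSUCollection-class
#' @export
SSUCollection <- function(collectionName, sequences) {
    if (is.character(sequences)) {
        sequences <- if (length(sequences) == 1L && file.exists(sequences))
            readDNAStringSet(sequences) else DNAStringSet(sequences)
    }
    new("SSUCollection", collectionName = collectionName,
        sequences = sequences)
}
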