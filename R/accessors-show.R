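#' @rdname GenomeAssembly-class
setMethod("assemblyName", "GenomeAssembly", function(x) x@assemblyName)

#' @rdname GenomeAssembly-class
setMethod("contigs", "GenomeAssembly", function(x) x@contigs)

#' @rdname GenomeAssembly-class
setMethod("length", "GenomeAssembly",
          function(x) sum(Biostrings::width(x@contigs)))

setMethod("show", "GenomeAssembly", function(object) {
    cat(sprintf("GenomeAssembly '%s': %d contig(s), %s bp, G+C %.2f mol%%\n",
                object@assemblyName, base::length(object@contigs),
                format(length(object), big.mark = ","),
                gcContent(object)))
})

#' @rdname ClusterSet-class
setMethod("clusterMembership", "ClusterSet", function(x) x@membership)

#' @rdname ClusterSet-class
setMethod("clusterThreshold", "ClusterSet", function(x) x@threshold)

#' @rdname ClusterSet-class
setMethod("centroids", "ClusterSet",
          function(x) unique(x@membership$centroid))

#' @rdname ClusterSet-class
setMethod("length", "ClusterSet",
          function(x) base::length(unique(x@membership$centroid)))

setMethod("show", "ClusterSet", function(object) {
    cat(sprintf("ClusterSet: %d sequence(s) in %d cluster(s) at identity >= %g\n",
                nrow(object@membership), length(object), object@threshold))
})

#' @rdname StudyTable-class
setMethod("studyId", "StudyTable", function(x) x@studyId)

#' @rdname StudyTable-class
setMethod("abundances", "StudyTable", function(x) x@abund)

#' @rdname StudyTable-class
setMethod("readCounts", "StudyTable", function(x) x@readCounts)

#' @rdname StudyTable-class
setMethod("dim", "StudyTable", function(x) dim(x@abund))

setMethod("show", "StudyTable", function(object) {
    cat(sprintf("StudyTable '%s': %d sample(s) x %d taxa%s\n",
                object@studyId, nrow(object@abund), ncol(object@abund),
                if (base::length(object@readCounts))
                    " (read counts attached)" else ""))
})

#' @rdname ProteinCatalog-class
setMethod("entries", "ProteinCatalog", function(x) x@entries)

#' @rdname ProteinCatalog-class
setMethod("clusterMap", "ProteinCatalog", function(x) x@clusterMap)

#' @rdname ProteinCatalog-class
setMethod("representatives", "ProteinCatalog", function(x) {
    if (nrow(x@clusterMap) == 0L) x@entries
    else x@entries[unique(x@clusterMap$representative)]
})

#' @rdname ProteinCatalog-class
setMethod("length", "ProteinCatalog", function(x) base::length(x@entries))

setMethod("show", "ProteinCatalog", function(object) {
    built <- nrow(object@clusterMap) > 0L
    cat(sprintf("ProteinCatalog: %d entries%s\n", length(object),
                if (built) sprintf(", %d representative(s)",
                    base::length(unique(object@clusterMap$representative)))
                else " (not clustered)"))
})

#' @rdname SSUCollection-class
setMethod("collectionName", "SSUCollection", function(x) x@collectionName)

#' @rdname SSUCollection-class
setMethod("collectionSequences", "SSUCollection", function(x) x@sequences)

#' @rdname SSUCollection-class
setMethod("length", "SSUCollection", function(x) base::length(x@sequences))

setMethod("show", "SSUCollection", function(object) {
    cat(sprintf("SSUCollection '%s': %d sequence(s), widths %d-%d bp\n",
                object@collectionName, length(object),
                min(Biostrings::width(object@sequences)),
                max(Biostrings::width(object@sequences))))
})

#' @rdname MashSketch-class
setMethod("sketchHashes", "MashSketch", function(x) x@hashes)

setMethod("show", "MashSketch", function(object) {
    cat(sprintf("MashSketch: k=%d, %d/%d minimum hashes\n",
                object@k, base::length(object@hashes), object@sketchSize))
})
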