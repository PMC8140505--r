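#' @rdname GenomeAssembly-class
#' @param object,x an object.
#' @export
setGeneric("assemblyName", function(x) standardGeneric("assemblyName"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterThreshold", function(x) standardGeneric("clusterThreshold"))

#' @rdname ClusterSet-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname StudyTable-class
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @rdname StudyTable-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname StudyTable-class
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname ProteinCatalog-class
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))

#' @rdname ProteinCatalog-class
#' @export
setGeneric("clusterMap", function(x) standardGeneric("clusterMap"))

#' @rdname ProteinCatalog-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname SSUCollection-class
#' @export
setGeneric("collectionName", function(x) standardGeneric("collectionName"))

#' @rdname SSUCollection-class
#' @export
setGeneric("collectionSequences",
           function(x) standardGeneric("collectionSequences"))

#' @rdname MashSketch-class
#' @export
setGeneric("sketchHashes", function(x) standardGeneric("sketchHashes"))

#' @rdname gcContent
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))
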