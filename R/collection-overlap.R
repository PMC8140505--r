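# Cross-collection comparison of novel-taxon inventories: within-collection
# dereplication at the 98.7% species boundary, single-linkage shared/unique
# calls at K2P distance < 0.013, and "wanted taxa" coverage queries.

#' Dereplicate a collection to species-level representatives
#'
#' Sequences shorter than `minLen` (default 1000 bp) are dropped with a
#' warning; the remainder are clustered with [greedyCluster()] at
#' `threshold` and the centroids are returned as a new collection.
#'
#' @param x an [SSUCollection].
#' @param threshold clustering identity threshold (default 0.987).
#' @param minLen minimum retained sequence length in bp.
#' @return an [SSUCollection] of cluster representatives.
#' @export
dereplicate <- function(x, threshold = 0.987, minLen = 1000L) {
    stopifnot(is(x, "SSUCollection"))
    seqs <- collectionSequences(x)
    short <- Biostrings::width(seqs) < minLen
    if (any(short)) {
        warning(sum(short), " sequence(s) shorter than ", minLen,
                " bp dropped from collection '", collectionName(x), "'")
        seqs <- seqs[!short]
    }
    if (base::length(seqs) == 0L)
        stop("collection '", collectionName(x),
             "' is empty after the length filter")
    cs <- greedyCluster(seqs, threshold)
    SSUCollection(collectionName(x), seqs[centroids(cs)])
}

#' Shared and study-unique taxa across collections
#'
#' Builds a graph over the representatives of all collections with an edge
#' wherever the K2P distance is strictly below `maxDist` (default 0.013);
#' connected components define taxa (single-linkage, so chains of close
#' pairs merge even when their endpoints are farther apart). A component
#' spanning two or more collections is shared by exactly those collections;
#' a component confined to one collection is study-unique. Saturated K2P
#' pairs are treated as beyond the threshold, with a warning.
#'
#' @param collections list of [SSUCollection] objects (dereplicate first;
#'   see [dereplicate()]).
#' @param maxDist K2P distance boundary (strict <).
#' @return list with `components` (data.frame: id, collection, component),
#'   `sharedCounts` (named integer: taxa spanning 1, 2, ... collections),
#'   `vennCounts` (named integer: taxa per collection-combination region),
#'   and `nTaxa` (total nonredundant taxa).
#' @examples
#' a <- SSUCollection("A", makeSSUPair(1200, 1, seed = 1)[1])
#' cross <- crossOverlap(list(a, SSUCollection("B", makeSSUPair(1200, 1,
#'     seed = 1)[1])))
#' cross$nTaxa
#' @export
crossOverlap <- function(collections, maxDist = 0.013) {
    stopifnot(length(collections) >= 1L,
              all(vapply(collections, is, logical(1), "SSUCollection")))
    colNames <- vapply(collections, collectionName, "")
    if (anyDuplicated(colNames)) stop("collection names must be unique")
    seqs <- do.call(c, lapply(collections, collectionSequences))
    member <- rep(colNames, vapply(collections, length, integer(1)))
    ids <- paste(member, unlist(lapply(collections, function(x)
        names(collectionSequences(x)))), sep = ":")
    n <- base::length(seqs)
    uf <- unionFind(n)
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            d <- tryCatch(k2pDistance(nucAlignment(seqs[[i]], seqs[[j]])),
                          k2pSaturationError = function(e) {
                              warning("K2P saturated for pair ", ids[i],
                                      " / ", ids[j],
                                      "; treated as distance >= threshold")
                              Inf
                          })
            if (d < maxDist) uf$union(i, j)
        }
    }
    comp <- uf$components()
    components <- data.frame(id = ids, collection = member, component = comp)
    perComp <- split(member, comp)
    span <- vapply(perComp, function(m) base::length(unique(m)), integer(1))
    sharedCounts <- table(factor(span, levels = seq_along(collections)))
    region <- vapply(perComp, function(m)
        paste(sort(unique(m)), collapse = "&"), "")
    list(components = components,
         sharedCounts = setNames(as.integer(sharedCounts),
                                 paste0("span", seq_along(collections))),
         vennCounts = vapply(split(region, region), base::length, integer(1)),
         nTaxa = base::length(perComp))
}

#' Coverage of "wanted" target taxa by a query collection
#'
#' A target is covered iff its best alignment identity to any query
#' sequence strictly exceeds `threshold` (default 0.987).
#'
#' @param queries an [SSUCollection] (e.g. a biobank's 16S inventory).
#' @param targets an [SSUCollection] of wanted taxa (e.g. priority OTUs).
#' @param threshold identity boundary (strict >).
#' @return data.frame with columns `target`, `bestQuery`, `identity`,
#'   `covered`.
#' @export
wantedCoverage <- function(queries, targets, threshold = 0.987) {
    stopifnot(is(queries, "SSUCollection"), is(targets, "SSUCollection"))
    q <- collectionSequences(queries)
    t <- collectionSequences(targets)
    rows <- lapply(seq_along(t), function(i) {
        ids <- vapply(seq_along(q),
                      function(j) alignIdentity(t[[i]], q[[j]]), numeric(1))
        best <- which.max(ids)
        data.frame(target = names(t)[i], bestQuery = names(q)[best],
                   identity = ids[best], covered = ids[best] > threshold)
    })
    do.call(rbind, rows)
}
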