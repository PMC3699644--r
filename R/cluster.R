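#' Hierarchical clustering of samples
#'
#' Clusters samples by their expression profiles. Defaults — `log2(RPM + 1)`
#' transform, Euclidean distance and average (UPGMA) linkage — are standard
#' for depth-normalized bulk expression profiles and reproduce the expected
#' ((young CEC, old CEC), culture), stroma sample relationship on the
#' bundled reference tables (see the vignette; a Pearson-correlation
#' distance, `1 - r`, is also available but on marker-selected gene subsets
#' it understates the culture sample's divergence). The result is
#' deterministic and invariant to gene-row and
#' sample-column order: samples are sorted lexicographically before
#' agglomeration so equal-distance merges resolve to the smallest member
#' label.
#'
#' @param x a [MarkerExperiment-class] with unit `"rpm"` and >= 2 samples.
#' @param transform `"log2p1"` (log2(RPM+1)) or `"none"`.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage `"average"` or `"complete"`.
#' @return a [SampleDendrogram-class].
#' @details Genes with zero variance across samples carry no clustering
#'   information and are dropped; if fewer than 2 genes remain (e.g. a
#'   constant matrix) the correlation distance is undefined and an error is
#'   raised.
#' @export
clusterSamples <- function(x, transform = c("log2p1", "none"),
                           distance = c("euclidean", "correlation"),
                           linkage = c("average", "complete")) {
    stopifnot(is(x, "MarkerExperiment"))
    transform <- match.arg(transform)
    distance <- match.arg(distance)
    linkage <- match.arg(linkage)
    if (exprUnit(x) != "rpm")
        stop("clustering expects RPM values; run rpmNormalize() first")
    if (ncol(x) < 2L)
        stop("need at least 2 samples to cluster")
    v <- exprValues(x)
    v <- v[, order(colnames(v)), drop = FALSE]   # canonical sample order
    if (transform == "log2p1") v <- log2(v + 1)
    keep <- apply(v, 1L, function(r) stats::var(r) > 0)
    if (sum(keep) < 2L)
        stop("need >= 2 genes with nonzero variance across samples ",
             "(constant matrix: distance undefined)")
    v <- v[keep, , drop = FALSE]
    d <- if (distance == "correlation") {
        1 - stats::cor(v, method = "pearson")
    } else {
        as.matrix(stats::dist(t(v), method = "euclidean"))
    }
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    new("SampleDendrogram", hclust = hc, dist = d, transform = transform,
        distance = distance, linkage = linkage)
}

#' @describeIn clusterSamples serialize the dendrogram to a newick file;
#'   branch lengths are merge-height differences.
#' @param dendro a [SampleDendrogram-class].
#' @param path output file; if `NULL` the newick string is returned.
#' @export
exportNewick <- function(dendro, path = NULL) {
    stopifnot(is(dendro, "SampleDendrogram"))
    phy <- ape::as.phylo(dendro@hclust)
    ## as.phylo() halves hclust heights; rescale so leaf-to-root depth equals
    ## the root merge height and branch lengths are merge-height differences
    phy$edge.length <- phy$edge.length * 2
    if (is.null(path))
        return(ape::write.tree(phy))
    ape::write.tree(phy, file = path)
    invisible(path)
}

#' @describeIn clusterSamples write the pairwise distance matrix as TSV.
#' @export
exportDistances <- function(dendro, path) {
    stopifnot(is(dendro, "SampleDendrogram"))
    utils::write.table(data.frame(sample_id = rownames(dendro@dist),
                                  dendro@dist, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @describeIn clusterSamples sample ids of each successive merge, from first
#'   to last: a list of character vectors, each the leaf set of the newly
#'   formed cluster.
#' @export
mergeOrder <- function(dendro) {
    stopifnot(is(dendro, "SampleDendrogram"))
    hc <- dendro@hclust
    members <- vector("list", nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
        pick <- function(j) if (j < 0) hc$labels[-j] else members[[j]]
        members[[i]] <- sort(c(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L])))
    }
    members
}

setMethod("show", "SampleDendrogram", function(object) {
    cat("SampleDendrogram over", length(object@hclust$labels), "samples",
        sprintf("(%s / %s / %s linkage)\n", object@transform,
                object@distance, object@linkage))
    m <- mergeOrder(object)
    for (i in seq_along(m))
        cat(sprintf("  merge %d @ %.4g: {%s}\n", i, object@hclust$height[i],
                    paste(m[[i]], collapse = ", ")))
    invisible(NULL)
})

#' @export
#' @method as.hclust SampleDendrogram
as.hclust.SampleDendrogram <- function(x, ...) x@hclust
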