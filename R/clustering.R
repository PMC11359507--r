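## Threshold-graph genome clustering: an edge joins two genomes when their
## similarity reaches the threshold, clusters are the connected components
## (single linkage -- the only parameter-free transitive closure of a
## pairwise criterion), and subclusters re-run the same machinery inside
## each cluster at a higher threshold. Historical defaults: PEQ 25 for
## clusters, 60 for subclusters.

.componentsAtThreshold <- function(v, threshold) {
  n <- nrow(v)
  adj <- v >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

## Order component ids by (size desc, smallest member id asc); returns the
## rank of each component id.
.orderComponents <- function(membership, ids) {
  sizes <- table(membership)
  min_id <- tapply(ids, membership, min)
  comp_ids <- names(sizes)
  ord <- comp_ids[order(-as.integer(sizes), min_id)]
  setNames(seq_along(ord), ord)
}

#' Cluster genomes by thresholding a similarity matrix
#'
#' Builds a graph with an edge between genomes i and j whenever
#' `matrix[i, j] >= threshold` and reports the connected components.
#' Multi-member components are ordered by (size descending, then smallest
#' member id) and labelled A, B, ..., Z, AA, ...; singletons are labelled
#' `"singleton"`.
#'
#' @param mat a [SimilarityMatrix-class].
#' @param threshold similarity threshold in (0, 100\] (default 25, the
#'   historical PEQ cluster threshold).
#' @return data.frame with columns genome_id, cluster, subcluster (NA
#'   here; see [assignSubclusters()]), singleton; the threshold is
#'   recorded in `attr(, "threshold")`. Deterministic under permutation
#'   of the input genomes.
#' @export
thresholdClusters <- function(mat, threshold = 25) {
  stopifnot(is(mat, "SimilarityMatrix"))
  if (threshold <= 0 || threshold > 100)
    stop("threshold must lie in (0, 100]")
  v <- simValues(mat)
  ids <- rownames(v)
  ord <- order(ids)               # id-sorted => permutation invariance
  v <- v[ord, ord, drop = FALSE]
  ids <- ids[ord]
  membership <- .componentsAtThreshold(v, threshold)
  rank <- .orderComponents(membership, ids)
  sizes <- table(membership)
  out <- data.frame(genome_id = ids, cluster = NA_character_,
                    subcluster = NA_character_, singleton = FALSE,
                    stringsAsFactors = FALSE)
  letter_n <- 0L
  letter_of <- character(0)
  for (comp in names(sort(rank))) {
    if (sizes[[comp]] > 1L) {
      letter_n <- letter_n + 1L
      letter_of[comp] <- letterLabels(letter_n)
    } else {
      letter_of[comp] <- "singleton"
    }
  }
  out$cluster <- unname(letter_of[as.character(membership)])
  out$singleton <- out$cluster == "singleton"
  attr(out, "threshold") <- threshold
  out
}

#' Subdivide clusters at a higher threshold
#'
#' Within each multi-member cluster, re-runs component clustering at
#' `threshold`. A cluster that stays whole receives no subcluster labels;
#' otherwise its parts are numbered 1, 2, ... by (size descending,
#' smallest member id) and labelled `<cluster><n>` (A1, A2, ...).
#'
#' @param mat the same [SimilarityMatrix-class] used for the clusters.
#' @param clusters output of [thresholdClusters()] on `mat`.
#' @param threshold subcluster threshold; must exceed the cluster
#'   threshold (default 60, the historical PEQ subcluster threshold).
#' @return `clusters` with the subcluster column filled in.
#' @export
assignSubclusters <- function(mat, clusters, threshold = 60) {
  stopifnot(is(mat, "SimilarityMatrix"))
  ct <- attr(clusters, "threshold")
  if (!is.null(ct) && threshold <= ct)
    stop("subcluster threshold (", threshold,
         ") must exceed the cluster threshold (", ct, ")")
  v <- simValues(mat)
  for (cl in setdiff(unique(clusters$cluster), "singleton")) {
    members <- clusters$genome_id[clusters$cluster == cl]
    if (length(members) < 2) next
    sub_v <- v[members, members, drop = FALSE]
    membership <- .componentsAtThreshold(sub_v, threshold)
    if (length(unique(membership)) == 1L) next   # stays whole
    rank <- .orderComponents(membership, members)
    labels <- paste0(cl, rank[as.character(membership)])
    clusters$subcluster[match(members, clusters$genome_id)] <- labels
  }
  clusters
}

#' Component count as a function of threshold
#'
#' Counts connected components of the threshold graph at each of a series
#' of ascending thresholds; raising the bar can only split components, so
#' the curve is non-decreasing. Useful for characterizing how sharply a
#' cluster fragments (near-linear vs sigmoidal profiles).
#'
#' @param mat a [SimilarityMatrix-class].
#' @param thresholds strictly ascending numeric vector within (0, 100\].
#' @return data.frame(threshold, n_components).
#' @export
clusterCountCurve <- function(mat, thresholds) {
  stopifnot(is(mat, "SimilarityMatrix"))
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0 | thresholds > 100))
    stop("thresholds must be strictly ascending within (0, 100]")
  v <- simValues(mat)
  counts <- vapply(thresholds, function(t)
    length(unique(.componentsAtThreshold(v, t))), integer(1))
  data.frame(threshold = thresholds, n_components = counts)
}

#' Write a cluster assignment as TSV
#'
#' @param clusters output of [thresholdClusters()] /
#'   [assignSubclusters()].
#' @param path output TSV (genome_id, cluster, subcluster).
#' @return `path`, invisibly.
#' @export
writeClusters <- function(clusters, path) {
  write.table(clusters[c("genome_id", "cluster", "subcluster")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
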