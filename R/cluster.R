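## Cluster delimitation: single-linkage connected components under
## "distance < merge_threshold" on the pooled reference+query K2P matrix.
## Each resulting cluster has, by construction, a nearest-neighbor distance
## of at least the threshold (strictly: a pair at exactly the threshold
## stays split, so between-cluster distances exceed it in the open sense
## used for barcode groups, >3% at the default).

#' Cluster settings
#'
#' @param merge_threshold K2P distance below which two records are linked
#'   (default 0.03).
#' @return an object of class `cluster_settings`.
#' @export
cluster_settings <- function(merge_threshold = 0.03) {
  stopifnot(merge_threshold > 0, merge_threshold < 1)
  structure(list(merge_threshold = merge_threshold), class = "cluster_settings")
}

#' Delimit species-cluster units from a distance matrix
#'
#' Single-linkage connected components: records are linked whenever their
#' distance is strictly below the merge threshold. Clusters are numbered
#' deterministically by their smallest member (first position in the matrix
#' order).
#'
#' @param d distance matrix (no saturated entries).
#' @param settings a [cluster_settings()] object.
#' @return an object of class `cluster_set`: `membership` (named integer
#'   vector), `clusters` (list of member id vectors), `nn_distance`
#'   (per-cluster minimum distance to any record outside the cluster; `Inf`
#'   for a lone cluster) and the settings.
#' @export
delimit <- function(d, settings = cluster_settings()) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (anyNA(d)) stop("saturated entries in distance matrix; cannot delimit")
  n <- nrow(d)
  ids <- rownames(d) %||% as.character(seq_len(n))

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  link <- which(d < settings$merge_threshold & upper.tri(d), arr.ind = TRUE)
  for (e in seq_len(nrow(link))) {
    ri <- find(link[e, 1]); rj <- find(link[e, 2])
    if (ri != rj) parent[min(ri, rj)] <- max(ri, rj)  # direction irrelevant
  }
  root <- vapply(seq_len(n), find, 0L)
  first <- tapply(seq_len(n), root, min)
  ord <- sort(unname(first))                       # number by smallest member
  cluster_id <- match(ave(seq_len(n), root, FUN = min), ord)

  membership <- stats::setNames(cluster_id, ids)
  clusters <- split(ids, cluster_id)
  names(clusters) <- NULL

  nn <- vapply(seq_along(clusters), function(k) {
    inside <- cluster_id == k
    if (all(inside)) return(Inf)
    min(d[inside, !inside])
  }, 0)

  structure(list(membership = membership, clusters = clusters,
                 nn_distance = nn, settings = settings),
            class = "cluster_set")
}

#' Cluster containing a record
#'
#' @param record_id record id.
#' @param clusters a `cluster_set`.
#' @return the integer cluster id.
#' @export
cluster_of <- function(record_id, clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  k <- clusters$membership[record_id]
  if (anyNA(k)) stop("unknown record id: ",
                     paste(record_id[is.na(k)], collapse = ", "))
  unname(k)
}

#' How many clusters does each morphology label split into?
#'
#' For each query label, counts the distinct clusters containing queries
#' carrying that label (a count above 1 signals an anomalously diverged
#' haplotype group within a morphospecies).
#'
#' @param clusters a `cluster_set` over pooled records.
#' @param query_labels named character vector: query record id -> morphology
#'   label.
#' @return `data.frame` with columns `morphology_label` and `n_clusters`.
#' @export
split_census <- function(clusters, query_labels) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (any(!nzchar(query_labels)))
    stop("every query must carry a morphology label")
  k <- cluster_of(names(query_labels), clusters)
  counts <- tapply(k, query_labels, function(x) length(unique(x)))
  data.frame(morphology_label = names(counts),
             n_clusters = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d record(s) in %d cluster(s), threshold %g\n",
              length(x$membership), length(x$clusters),
              x$settings$merge_threshold))
  invisible(x)
}
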