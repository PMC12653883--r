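## End-to-end audit: pooled distance matrix, cluster delimitation, per-query
## identification and classification, report and summary.

#' Run the full identification audit
#'
#' @param references,queries barcode record `data.frame`s (queries need
#'   morphology labels).
#' @param synonymy a [synonymy_table()] (defaults to an empty one).
#' @param ranges optional [range_table()] for the geographic correction.
#' @param search a [search_settings()] object.
#' @param cluster a [cluster_settings()] object.
#' @param classifier a [classifier_settings()] object.
#' @return a list of class `audit_run`: `records` (list of `audit_record`),
#'   `report` (specimen-level table with `cluster_id`), `clusters`
#'   (`cluster_set` over pooled records), `cluster_report`, `summary`
#'   (over clusters containing at least one query), `distances` (pooled K2P
#'   matrix) and `tree` (NJ identification tree over pooled records, `NULL`
#'   for fewer than 3 records or a saturated matrix).
#' @export
run_audit <- function(references, queries, synonymy = synonymy_table(),
                      ranges = NULL,
                      search = search_settings(),
                      cluster = cluster_settings(),
                      classifier = classifier_settings()) {
  stopifnot(nrow(references) >= 1L, nrow(queries) >= 1L)
  validate_barcode_records(rbind(references, queries))

  pooled <- rbind(references, queries)
  code <- encode_sequences(stats::setNames(pooled$sequence, pooled$record_id))
  n_ref <- nrow(references)

  d <- distance_matrix(stats::setNames(pooled$sequence, pooled$record_id),
                       metric = "k2p")
  clusters <- delimit(d, cluster)

  ref_code <- code[seq_len(n_ref), , drop = FALSE]
  records <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    q <- queries[qi, ]
    sims <- similarity_to_all(code[n_ref + qi, ], ref_code)
    sims[references$record_id == q$record_id] <- NA  # never self-match
    hits <- build_hits(references, sims, search, synonymy)
    result <- consensus_identify(hits, search)
    records[[qi]] <- classify(q, hits, result, clusters, synonymy,
                              references, classifier, ranges)
  }

  report <- audit_report(records, cluster_ids = clusters$membership)
  cluster_report <- to_cluster_level(report)
  summary <- summarize_audit(cluster_report)

  tree <- if (nrow(pooled) >= 3L && !anyNA(d)) nj_tree(d) else NULL

  structure(list(records = records, report = report, clusters = clusters,
                 cluster_report = cluster_report, summary = summary,
                 distances = d, tree = tree),
            class = "audit_run")
}

#' @export
print.audit_run <- function(x, ...) {
  cat(sprintf("<audit_run> %d quer%s over %d cluster(s)\n",
              nrow(x$report), ifelse(nrow(x$report) == 1, "y", "ies"),
              x$summary$n_clusters))
  print(x$summary)
  invisible(x)
}

#' Write all artifacts of an audit run
#'
#' Writes `report.tsv`, `cluster_report.tsv` and, when a tree was built,
#' `tree.nwk` into a directory.
#'
#' @param run an `audit_run`.
#' @param dir output directory (created if missing).
#' @export
write_audit_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_audit_report(run$report, file.path(dir, "report.tsv"))
  write_tsv_table(run$cluster_report, file.path(dir, "cluster_report.tsv"))
  if (!is.null(run$tree))
    write_newick(run$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
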