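## Aggregation of specimen-level audit rows to species-cluster level, and
## the headline summary statistics (share of problematic clusters, share of
## clusters whose problems are not due to an incomplete reference library).

row_is_problematic <- function(report) {
  report$final_rank != "species" |
    (!is.na(report$confidence_pct) & report$confidence_pct < 100)
}

#' Aggregate audit rows to cluster level
#'
#' One output row per cluster containing at least one query. A cluster is
#' problematic when any member query is; its categories are the union of the
#' member categories, kept in the fixed category order.
#'
#' @param report audit report `data.frame` (see [audit_report()]).
#' @param cluster_ids named vector mapping query id -> cluster id; omitted
#'   when the report already has a `cluster_id` column.
#' @return `data.frame` with columns `cluster_id`, `n_queries`, `query_ids`,
#'   `problematic`, `categories`.
#' @export
to_cluster_level <- function(report, cluster_ids = NULL) {
  if (nrow(report) == 0L)
    return(data.frame(cluster_id = character(0), n_queries = integer(0),
                      query_ids = character(0), problematic = logical(0),
                      categories = character(0), stringsAsFactors = FALSE))
  cl <- if (!is.null(cluster_ids)) as.character(unname(cluster_ids[report$query_id]))
  else report$cluster_id
  if (is.null(cl) || anyNA(cl))
    stop("every query must be assigned to a cluster")
  prob <- row_is_problematic(report)
  cats <- strsplit(report$categories, ";", fixed = TRUE)
  agg <- lapply(split(seq_len(nrow(report)), cl), function(idx) {
    u <- unique(unlist(cats[idx]))
    data.frame(cluster_id = cl[idx[1]],
               n_queries = length(idx),
               query_ids = paste(report$query_id[idx], collapse = ";"),
               problematic = any(prob[idx]),
               categories = paste(
                 PROBLEM_CATEGORIES[PROBLEM_CATEGORIES %in% u],
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$cluster_id), ]
  rownames(out) <- NULL
  out
}

#' Headline summary of an audit
#'
#' @param cluster_records cluster-level records from [to_cluster_level()].
#' @param n_clusters total number of clusters audited; defaults to the number
#'   of cluster records, but can be larger when only problematic rows were
#'   tabulated (clean clusters then enter the denominators implicitly).
#' @return an object of class `audit_summary`: cluster counts, problematic and
#'   clean percentages (unrounded, plus printed forms: problematic/clean to 0
#'   decimals, the share of clusters without the incompleteness category to 1
#'   decimal), and per-category counts and percentages over all category
#'   assignments.
#' @export
summarize_audit <- function(cluster_records, n_clusters = nrow(cluster_records)) {
  if (n_clusters == 0L) stop("no clusters to summarize")
  if (n_clusters < nrow(cluster_records))
    stop("n_clusters smaller than the number of cluster records")
  n_problematic <- sum(cluster_records$problematic)
  cats <- strsplit(cluster_records$categories, ";", fixed = TRUE)
  flat <- unlist(cats)
  flat <- flat[nzchar(flat)]
  category_counts <- vapply(PROBLEM_CATEGORIES,
                            function(c) sum(flat == c), 0L)
  n_assignments <- sum(category_counts)
  n_db_incomplete <- sum(vapply(cats, function(x) "DB_INCOMPLETE" %in% x, FALSE))

  pct_problematic <- 100 * n_problematic / n_clusters
  structure(list(
    n_clusters = n_clusters,
    n_problematic = n_problematic,
    n_clean = n_clusters - n_problematic,
    pct_problematic = pct_problematic,
    pct_clean = 100 - pct_problematic,
    pct_problematic_printed = round_half_away(pct_problematic, 0),
    pct_clean_printed = round_half_away(100 - pct_problematic, 0),
    pct_problematic_1dp = round_half_away(pct_problematic, 1),
    category_counts = category_counts,
    category_pct = if (n_assignments > 0)
      round_half_away(100 * category_counts / n_assignments, 1)
    else category_counts * NA_real_,
    pct_not_db_incomplete = round_half_away(
      100 * (n_clusters - n_db_incomplete) / n_clusters, 1)),
    class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  cat(sprintf("<audit_summary> %d clusters: %d problematic (%g%%), %d clean (%g%%)\n",
              x$n_clusters, x$n_problematic, x$pct_problematic_printed,
              x$n_clean, x$pct_clean_printed))
  cat(sprintf("  problems not due to library incompleteness: %.1f%%\n",
              x$pct_not_db_incomplete))
  on <- x$category_counts[x$category_counts > 0]
  if (length(on))
    cat("  categories:",
        paste(sprintf("%s=%d", names(on), on), collapse = ", "), "\n")
  invisible(x)
}
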