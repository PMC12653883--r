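## Classification of problematic identifications into six categories, and
## the geographic-correction verdict. The category rules operationalize the
## expert criteria used when auditing a barcode reference library: sporadic
## congeneric conflicts point to reference mislabels, conspecific-grade hits
## from another genus or family to contamination or label swaps,
## well-represented congeneric sharing of a cluster to undifferentiated
## barcodes, known synonym/uncertain name pairs to unresolved taxonomy,
## sub-conspecific-grade best same-name hits inside a same-name cluster to
## anomalous haplotypes, and the absence of conspecific references to
## database incompleteness.

PROBLEM_CATEGORIES <- c("SPECIES_MISLABEL", "CROSS_GENUS_CONTAMINATION",
                        "UNDIFFERENTIATED", "TAXONOMY_UNCERTAINTY",
                        "ANOMALOUS_BARCODE", "DB_INCOMPLETE")

#' The six problem categories, in fixed serialization order
#'
#' @return character vector of category codes.
#' @export
problem_categories <- function() PROBLEM_CATEGORIES

#' Classifier settings
#'
#' @param mislabel_max_fraction a discordant name is "sporadic" when its
#'   share of the hit list is below this (default 0.20).
#' @param min_represented hits needed for a name to count as
#'   well-represented (default 2).
#' @param conspecific_floor_pct similarity below which same-name best hits
#'   signal an anomalous haplotype or an incomplete library (default 99).
#' @return an object of class `classifier_settings`.
#' @export
classifier_settings <- function(mislabel_max_fraction = 0.20,
                                min_represented = 2L,
                                conspecific_floor_pct = 99) {
  stopifnot(mislabel_max_fraction > 0, mislabel_max_fraction < 0.5,
            min_represented >= 1, conspecific_floor_pct > 0,
            conspecific_floor_pct <= 100)
  structure(list(mislabel_max_fraction = mislabel_max_fraction,
                 min_represented = as.integer(min_represented),
                 conspecific_floor_pct = conspecific_floor_pct),
            class = "classifier_settings")
}

majority_species <- function(hits) {
  tab <- table(hits$species)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {  # tie: higher best similarity, then alphabetical
    best <- vapply(top, function(s) max(hits$similarity[hits$species == s]), 0)
    top <- top[order(-best, top)]
  }
  top[1L]
}

#' Classify one query's identification problems
#'
#' Applies all matching category rules (multi-category records are allowed).
#' A query whose identification is not problematic gets an empty category
#' set. See the package vignette for the exact rules.
#'
#' @param query one-row query record (needs `record_id` and
#'   `morphology_label`).
#' @param hits the query's hit list from [top_k_search()].
#' @param result the query's [consensus_identify()] result.
#' @param clusters a `cluster_set` over pooled reference+query records.
#' @param synonymy a [synonymy_table()].
#' @param references the reference records (for conspecific-presence checks).
#' @param settings a [classifier_settings()] object.
#' @param ranges optional [range_table()]; when supplied the
#'   geographic-correction verdict is computed, otherwise it is `NA`.
#' @return an object of class `audit_record`.
#' @export
classify <- function(query, hits, result, clusters, synonymy, references,
                     settings = classifier_settings(), ranges = NULL) {
  morph <- canonical_name(synonymy, query$morphology_label)
  ref_species <- canonical_name(synonymy, references$species)

  empty <- data.frame(name = character(0), similarity = numeric(0),
                      stringsAsFactors = FALSE)
  rec <- function(categories, conflicts, geo) {
    structure(list(query_id = query$record_id,
                   morphology_label = query$morphology_label,
                   majority_id = if (nrow(hits)) majority_species(hits) else "",
                   conflicts = conflicts,
                   result = result,
                   categories = PROBLEM_CATEGORIES[PROBLEM_CATEGORIES %in% categories],
                   geographic_correction = geo),
              class = "audit_record")
  }

  if (!is_problematic(result))
    return(rec(character(0), empty, "N/A"))

  categories <- character(0)
  maj <- if (nrow(hits)) majority_species(hits) else ""
  if (nrow(hits)) {
    maj_rows <- hits[hits$species == maj, , drop = FALSE]
    maj_genus <- maj_rows$genus[1]
    maj_family <- maj_rows$family[1]
    disc <- hits[hits$species != maj, , drop = FALSE]
  } else {
    disc <- hits
  }

  q_cluster <- cluster_of(query$record_id, clusters)
  in_query_cluster <- function(ref_ids) {
    any(clusters$membership[ref_ids] == q_cluster, na.rm = TRUE)
  }

  ## conflict summary per discordant name
  if (nrow(disc)) {
    conflict_names <- unique(disc$species)
    conflicts <- data.frame(
      name = conflict_names,
      similarity = vapply(conflict_names, function(s)
        max(disc$similarity[disc$species == s]), 0),
      count = vapply(conflict_names, function(s)
        sum(disc$species == s), 0L),
      genus = vapply(conflict_names, function(s)
        disc$genus[disc$species == s][1], ""),
      family = vapply(conflict_names, function(s)
        disc$family[disc$species == s][1], ""),
      stringsAsFactors = FALSE, row.names = NULL)
    conflicts <- conflicts[order(-conflicts$similarity, conflicts$name), ]
    rownames(conflicts) <- NULL
    conflicts$share <- conflicts$count / nrow(hits)
  } else {
    conflicts <- empty
  }

  ## R2: conspecific-grade hit from a different genus or family
  if (nrow(disc)) {
    r2 <- disc$similarity >= settings$conspecific_floor_pct &
      (disc$genus != maj_genus | disc$family != maj_family)
    if (any(r2)) categories <- c(categories, "CROSS_GENUS_CONTAMINATION")
  }

  ## R4: discordant name in an unresolved pair with the majority name, or a
  ## raw hit label that canonicalizes onto the majority name
  r4_names <- character(0)
  if (nrow(hits)) {
    cand <- unique(disc$species)
    r4_names <- cand[vapply(cand, function(s)
      is_uncertain_pair(synonymy, s, maj), FALSE)]
    synonymized <- hits$species == maj & hits$species_raw != maj
    if (any(synonymized) || length(r4_names))
      categories <- c(categories, "TAXONOMY_UNCERTAINTY")
  }

  ## R1 / R3: sporadic vs well-represented congeneric conflicts inside the
  ## cluster dominated by the majority name (= the query's cluster; the query
  ## was identified there)
  if (nrow(disc)) {
    for (s in unique(disc$species)) {
      rows <- disc[disc$species == s, , drop = FALSE]
      if (rows$genus[1] != maj_genus) next
      share <- nrow(rows) / nrow(hits)
      in_cluster <- in_query_cluster(rows$ref_id)
      ## well-represented: enough copies AND enough share; sporadic is the
      ## complement (a name seen fewer than min_represented times is sporadic
      ## regardless of share - with short hit lists share alone is coarse)
      well_rep <- nrow(rows) >= settings$min_represented &&
        share >= settings$mislabel_max_fraction
      sporadic <- !well_rep
      if (sporadic && in_cluster)
        categories <- c(categories, "SPECIES_MISLABEL")
      if (well_rep && in_cluster && !(s %in% r4_names))
        categories <- c(categories, "UNDIFFERENTIATED")
    }
  }

  ## R5 / R6: the query's relation to its own (morphology-label) species
  same_name_refs <- references$record_id[ref_species == morph]
  best_same <- if (nrow(hits) && any(hits$species == morph))
    max(hits$similarity[hits$species == morph]) else -Inf
  if (length(same_name_refs)) {
    if (best_same < settings$conspecific_floor_pct &&
        in_query_cluster(same_name_refs))
      categories <- c(categories, "ANOMALOUS_BARCODE")
  } else {
    any_floor <- nrow(hits) > 0 &&
      any(hits$similarity >= settings$conspecific_floor_pct)
    if (!any_floor) categories <- c(categories, "DB_INCOMPLETE")
  }

  categories <- unique(categories)
  geo <- if (is.null(ranges)) NA_character_
  else geographic_correction(categories, conflicts$name, ranges)
  rec(categories, conflicts[, c("name", "similarity")], geo)
}

#' Geographic-correction verdict
#'
#' Applicable only to undifferentiated barcodes: the identification is
#' rescued (`"Yes"`) when no conflicting species' known range contains the
#' focal region; it is not rescued (`"No"`) when any conflicting species
#' occurs there or has an unknown range (conservative: species may occur far
#' beyond their recorded ranges). For any other problem the verdict is
#' `"N/A"`. Indeterminate labels ("Genus sp.") are not species and are
#' ignored.
#'
#' @param categories character vector of assigned categories.
#' @param conflict_names species names conflicting with the majority name.
#' @param ranges a [range_table()].
#' @return `"Yes"`, `"No"` or `"N/A"`.
#' @export
geographic_correction <- function(categories, conflict_names, ranges) {
  stopifnot(inherits(ranges, "range_table"))
  if (!("UNDIFFERENTIATED" %in% categories)) return("N/A")
  conflict_names <- conflict_names[!is_indeterminate_name(conflict_names)]
  if (length(conflict_names) == 0L) return("No")
  occurs <- vapply(conflict_names, function(s) {
    r <- range_of(ranges, s)
    identical(r, "unknown") || ranges$focal_region %in% r
  }, FALSE)
  if (any(occurs)) "No" else "Yes"
}

#' @export
print.audit_record <- function(x, ...) {
  cat(sprintf("<audit_record> %s (%s): %s%s\n", x$query_id,
              x$morphology_label,
              if (length(x$categories)) paste(x$categories, collapse = ";")
              else "clean",
              ifelse(is.na(x$geographic_correction), "",
                     paste0(" [geo: ", x$geographic_correction, "]"))))
  invisible(x)
}

#' Flatten audit records into the report table
#'
#' @param records list of `audit_record` objects.
#' @param cluster_ids optional named vector (query id -> cluster id) appended
#'   as a `cluster_id` column.
#' @return the audit report `data.frame` (see [write_audit_report()]).
#' @export
audit_report <- function(records, cluster_ids = NULL) {
  rows <- lapply(records, function(r) {
    data.frame(
      query_id = r$query_id,
      morphology_label = r$morphology_label,
      majority_id = r$majority_id,
      other_ids_with_similarity = format_conflicts(
        r$conflicts$name, round_half_away(r$conflicts$similarity, 2)),
      final_id = ifelse(is.na(r$result$taxon), "unidentified", r$result$taxon),
      final_rank = r$result$rank,
      confidence_pct = r$result$confidence,
      categories = paste(r$categories, collapse = ";"),
      geographic_correction = ifelse(is.na(r$geographic_correction), "N/A",
                                     r$geographic_correction),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(cluster_ids))
    df$cluster_id <- as.character(unname(cluster_ids[df$query_id]))
  rownames(df) <- NULL
  df
}
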