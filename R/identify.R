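## BOLD-style molecular identification: retrieve the top-k most similar
## references within a similarity search depth and derive a final taxon with
## a rank-escalating consensus and a confidence percentage.

#' Search settings for top-k identification
#'
#' @param k maximum number of hits retained (default 25).
#' @param depth_pct similarity floor of the search, in percent (default 94).
#' @param species_match_pct similarity regarded as conspecific-grade: a
#'   species-rank identification requires the best hit to reach it
#'   (default 99).
#' @param delta_top_pct window below the best hit defining the "co-best"
#'   species names (default 0.5).
#' @return an object of class `search_settings`.
#' @export
search_settings <- function(k = 25L, depth_pct = 94, species_match_pct = 99,
                            delta_top_pct = 0.5) {
  stopifnot(k >= 1, depth_pct > 0, depth_pct < species_match_pct,
            species_match_pct <= 100, delta_top_pct >= 0)
  structure(list(k = as.integer(k), depth_pct = depth_pct,
                 species_match_pct = species_match_pct,
                 delta_top_pct = delta_top_pct),
            class = "search_settings")
}

hit_columns <- function() {
  data.frame(ref_id = character(0), similarity = numeric(0),
             species_raw = character(0), species = character(0),
             genus = character(0), subfamily = character(0),
             family = character(0), stringsAsFactors = FALSE)
}

build_hits <- function(references, sims, settings, synonymy = NULL) {
  keep <- !is.na(sims) & sims >= settings$depth_pct
  if (!any(keep)) return(hit_columns())
  h <- data.frame(ref_id = references$record_id[keep],
                  similarity = sims[keep],
                  species_raw = references$species[keep],
                  genus = references$genus[keep],
                  subfamily = references$subfamily[keep],
                  family = references$family[keep],
                  stringsAsFactors = FALSE)
  h$species <- if (is.null(synonymy)) h$species_raw
  else canonical_name(synonymy, h$species_raw)
  h <- h[order(-h$similarity, h$ref_id), ]
  h <- utils::head(h, settings$k)
  rownames(h) <- NULL
  h[, c("ref_id", "similarity", "species_raw", "species", "genus",
        "subfamily", "family")]
}

#' Top-k most-similar-reference search
#'
#' Ranks the reference library by percent similarity to the query, keeps at
#' most `k` hits at or above the search depth, sorted by similarity
#' descending then reference id ascending. The query is never matched
#' against itself (same `record_id`); exact duplicates of its sequence under
#' other ids are legitimate hits. Hit species labels are canonicalized
#' through the synonymy table when one is supplied; the raw label is kept in
#' `species_raw`.
#'
#' @param query one-row barcode record `data.frame` (or list with
#'   `record_id` and `sequence`).
#' @param references reference barcode records.
#' @param settings a [search_settings()] object.
#' @param synonymy optional [synonymy_table()].
#' @return a hit list `data.frame`.
#' @export
top_k_search <- function(query, references, settings = search_settings(),
                         synonymy = NULL) {
  stopifnot(nrow(references) >= 1L)
  refs <- references[references$record_id != query$record_id, , drop = FALSE]
  if (nrow(refs) == 0L) return(hit_columns())
  code <- encode_sequences(c(query$sequence, refs$sequence))
  sims <- similarity_to_all(code[1, ], code[-1, , drop = FALSE])
  build_hits(refs, sims, settings, synonymy)
}

#' Consensus identification from a hit list
#'
#' The co-best names are the distinct species among hits within
#' `delta_top_pct` of the best similarity. A single co-best species whose
#' best hit reaches `species_match_pct` gives a species-rank identification
#' with confidence `round(100 * share of retained hits carrying that name)`.
#' Otherwise the identification escalates to the lowest rank (genus, then
#' subfamily, then family) on which the co-best names agree, with confidence
#' computed over the retained hits at that rank; with no agreement even at
#' family level the query is unidentified.
#'
#' @param hits a hit list from [top_k_search()].
#' @param settings a [search_settings()] object.
#' @return an object of class `identification_result` with fields `taxon`,
#'   `rank` (`species`, `genus`, `subfamily`, `family` or `none`),
#'   `confidence` (integer percent, `NA` when unidentified) and `hits`.
#' @export
consensus_identify <- function(hits, settings = search_settings()) {
  res <- function(taxon, rank, confidence) {
    structure(list(taxon = taxon, rank = rank, confidence = confidence,
                   hits = hits),
              class = "identification_result")
  }
  if (nrow(hits) == 0L) return(res(NA_character_, "none", NA_real_))
  best <- max(hits$similarity)
  co <- hits[hits$similarity >= best - settings$delta_top_pct, , drop = FALSE]
  co_species <- sort(unique(co$species))

  if (length(co_species) == 1L && best >= settings$species_match_pct) {
    conf <- round_half_away(100 * mean(hits$species == co_species))
    return(res(co_species, "species", conf))
  }
  for (rank in c("genus", "subfamily", "family")) {
    co_rank <- unique(co[[rank]])
    if (length(co_rank) == 1L) {
      conf <- round_half_away(100 * mean(hits[[rank]] == co_rank))
      return(res(co_rank, rank, conf))
    }
  }
  res(NA_character_, "none", NA_real_)
}

#' Is an identification problematic?
#'
#' An identification is problematic when it is coarser than species rank, or
#' at species rank with confidence below 100.
#'
#' @param result an `identification_result`.
#' @return logical.
#' @export
is_problematic <- function(result) {
  stopifnot(inherits(result, "identification_result"))
  result$rank != "species" ||
    (!is.na(result$confidence) && result$confidence < 100)
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification> %s [%s]%s, %d hit(s)\n",
              ifelse(is.na(x$taxon), "unidentified", x$taxon), x$rank,
              ifelse(is.na(x$confidence), "",
                     sprintf(" confidence %g%%", x$confidence)),
              nrow(x$hits)))
  invisible(x)
}
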