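## Synthetic reference libraries with the statistical structure the audit
## assumes: a hierarchical taxonomy whose divergence ladder places
## conspecific haplotypes well below the cluster threshold and congeners
## outside the search depth, plus one generative corruption process per
## problem category, applied in a fixed order with per-record ground truth.

#' Simulation configuration
#'
#' Divergences are expected substitutions per site. `intraspecific_divergence`
#' is the expected pairwise distance between conspecific haplotypes (each
#' haplotype radiates from the species ancestor at half that). The
#' inter-level divergences are branch depths: each species ancestor sits
#' `interspecific_divergence` below its genus ancestor, so congeneric species
#' lie about twice that apart (~8% at the default), which keeps congeners
#' outside a 94% search depth while conspecifics stay inside conspecific
#' grade. The corruption rates default to zero (a clean library).
#'
#' @param seed integer RNG seed; every source of randomness derives from it.
#' @param n_families,n_genera_per_family,n_species_per_genus taxonomy shape
#'   (defaults 2 x 5 x 5 = 50 species).
#' @param n_refs_per_species,n_queries_per_species library and query depth.
#' @param barcode_length alignment length (default 658).
#' @param titv_ratio transition:transversion weight kappa (default 2: a
#'   transition is drawn with probability kappa/(kappa+2)).
#' @param intraspecific_divergence expected pairwise conspecific distance
#'   (default 0.005).
#' @param interspecific_divergence species-ancestor branch depth below the
#'   genus ancestor (default 0.04).
#' @param intergeneric_divergence genus-ancestor branch depth (default 0.10).
#' @param interfamily_divergence family-ancestor branch depth (default 0.15).
#' @param p_species_mislabel per-reference probability of relabeling to a
#'   random congener.
#' @param p_cross_genus_swap per-reference probability of relabeling to a
#'   random species of another genus.
#' @param n_introgression_pairs congeneric species pairs sharing a haplotype.
#' @param introgression_copies recipient references per introgression pair.
#' @param n_synonym_pairs species given an unresolved second name.
#' @param syn_refs_renamed references renamed per synonym pair.
#' @param p_anomalous per-species probability of an anomalously diverged
#'   haplotype lineage (references plus one query).
#' @param anomaly_divergence depth of the anomalous lineage below the species
#'   ancestor (default 0.07, the ~7% scale seen in real anomalous barcodes).
#' @param n_anomalous_refs anomalous reference haplotypes per affected species.
#' @param anomaly_radiation branch depth of haplotypes below the anomalous
#'   ancestor (default 0.012: anomalous queries then sit 1-3% from their
#'   anomalous conspecific references - inside the cluster link but below
#'   conspecific grade).
#' @param p_missing_species per-species probability of deleting every
#'   reference (the species stays in the query set).
#' @param region_pool region codes; `focal_region` is the audited region.
#' @param range_size regions per species range.
#' @param p_focal probability that a species' range includes the focal region.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 2L, n_genera_per_family = 5L,
                       n_species_per_genus = 5L,
                       n_refs_per_species = 5L, n_queries_per_species = 2L,
                       barcode_length = 658L, titv_ratio = 2,
                       intraspecific_divergence = 0.005,
                       interspecific_divergence = 0.04,
                       intergeneric_divergence = 0.10,
                       interfamily_divergence = 0.15,
                       p_species_mislabel = 0,
                       p_cross_genus_swap = 0,
                       n_introgression_pairs = 0L,
                       introgression_copies = 2L,
                       n_synonym_pairs = 0L,
                       syn_refs_renamed = 2L,
                       p_anomalous = 0,
                       anomaly_divergence = 0.07,
                       n_anomalous_refs = 2L,
                       anomaly_radiation = 0.012,
                       p_missing_species = 0,
                       region_pool = c("VLG", "W-EU", "E-EU", "C-AS",
                                       "N-AF", "SIB", "IRN"),
                       range_size = 2L,
                       p_focal = 0.7,
                       focal_region = "VLG") {
  cfg <- as.list(environment())
  probs <- c(cfg$p_species_mislabel, cfg$p_cross_genus_swap, cfg$p_anomalous,
             cfg$p_missing_species, cfg$p_focal)
  stopifnot(all(probs >= 0 & probs <= 1))
  if (!(cfg$intraspecific_divergence < 0.03 &&
        0.03 < cfg$interspecific_divergence + cfg$interspecific_divergence &&
        cfg$interspecific_divergence < cfg$intergeneric_divergence &&
        cfg$intergeneric_divergence < cfg$interfamily_divergence))
    stop("inconsistent divergence ladder: need intraspecific < 0.03 < ",
         "pairwise interspecific, and interspecific < intergeneric < interfamily")
  stopifnot(cfg$focal_region %in% cfg$region_pool)
  structure(cfg, class = "sim_config")
}

## Substitute at `m` distinct random sites: transition with weight kappa
## against the two transversion targets. Deep (between-taxon) branches use
## the exact expected count round(L * d) so the divergence ladder is realized
## by construction, not merely in expectation; shallow (within-species)
## branches draw m ~ Poisson(L * d) truncated at the conspecific-grade cap.
substitute_sites <- function(code, m, kappa) {
  if (m == 0) return(code)
  L <- length(code)
  pos <- sample.int(L, min(m, L), replace = FALSE)
  p_ts <- kappa / (kappa + 2)
  transition_of <- c(3L, 4L, 1L, 2L)           # A<->G, C<->T
  tv_targets <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
  for (p in pos) {
    b <- code[p]
    code[p] <- if (stats::runif(1) < p_ts) transition_of[b]
    else sample(tv_targets[[b]], 1)
  }
  code
}

mutate_exact <- function(code, d, kappa) {
  substitute_sites(code, round(length(code) * d), kappa)
}

mutate_poisson_capped <- function(code, d, kappa, cap) {
  m <- min(stats::rpois(1, length(code) * d), cap)
  substitute_sites(code, m, kappa)
}

mark_corruption <- function(truth, idx, type) {
  multi <- truth$corruption[idx] != "none"
  truth$multi[idx] <- truth$multi[idx] | multi
  truth$corruption[idx] <- type
  truth
}

#' Simulate a reference library, query set and ground truth
#'
#' Generates sequences down a star-within-hierarchy phylogeny (family ->
#' genus -> species ancestors, haplotypes radiating from the species
#' ancestor), assigns ranges, then applies the corruption processes in a
#' fixed order: synonym renames, introgression haplotype copies, anomalous
#' haplotypes, species mislabels, cross-genus swaps, species deletions.
#' Query records always carry their true species as the morphology label.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_library`: `references` and `queries`
#'   (barcode record `data.frame`s), `ranges` ([range_table()]), `synonymy`
#'   ([synonymy_table()]), `truth` (list with per-record and per-species
#'   ground truth) and the `config`.
#' @export
simulate_library <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$barcode_length
  kappa <- config$titv_ratio

  ## taxonomy
  tax <- expand.grid(sp = seq_len(config$n_species_per_genus),
                     gen = seq_len(config$n_genera_per_family),
                     fam = seq_len(config$n_families))
  tax$genus_global <- (tax$fam - 1) * config$n_genera_per_family + tax$gen
  tax$family <- sprintf("Family%02d", tax$fam)
  tax$subfamily <- sprintf("Subfamily%02d", tax$fam)
  tax$genus <- sprintf("Genus%03d", tax$genus_global)
  tax$species <- paste0(tax$genus, " ", sprintf("species%02d", tax$sp))

  root <- sample.int(4L, L, replace = TRUE)
  fam_anc <- lapply(seq_len(config$n_families), function(f)
    mutate_exact(root, config$interfamily_divergence, kappa))
  gen_anc <- lapply(seq_len(max(tax$genus_global)), function(g) {
    f <- tax$fam[match(g, tax$genus_global)]
    mutate_exact(fam_anc[[f]], config$intergeneric_divergence, kappa)
  })
  sp_anc <- lapply(seq_len(nrow(tax)), function(s)
    mutate_exact(gen_anc[[tax$genus_global[s]]],
                 config$interspecific_divergence, kappa))

  ## haplotypes radiate from the species ancestor; the per-branch count is
  ## capped at conspecific grade (<1% of sites) and the ancestral haplotype
  ## itself is always sampled as each species' first reference, mirroring the
  ## modal haplotype of a well-sampled species
  hap_branch <- config$intraspecific_divergence / 2
  intra_cap <- max(1L, floor(0.01 * L))
  draw_hap <- function(s) decode_sequence(
    mutate_poisson_capped(sp_anc[[s]], hap_branch, kappa, intra_cap))

  n_sp <- nrow(tax)
  refs <- do.call(rbind, lapply(seq_len(n_sp), function(s) {
    data.frame(species_idx = s,
               sequence = c(decode_sequence(sp_anc[[s]]),
                            vapply(seq_len(config$n_refs_per_species - 1L),
                                   function(i) draw_hap(s), "")),
               stringsAsFactors = FALSE)
  }))
  queries <- do.call(rbind, lapply(seq_len(n_sp), function(s) {
    data.frame(species_idx = s,
               sequence = vapply(seq_len(config$n_queries_per_species),
                                 function(i) draw_hap(s), ""),
               stringsAsFactors = FALSE)
  }))
  refs$record_id <- sprintf("R%04d", seq_len(nrow(refs)))
  queries$record_id <- sprintf("Q%04d", seq_len(nrow(queries)))
  refs$true_species <- tax$species[refs$species_idx]
  queries$true_species <- tax$species[queries$species_idx]
  refs$displayed <- refs$true_species
  refs$corruption <- "none"; refs$multi <- FALSE
  queries$corruption <- "none"; queries$multi <- FALSE

  ## ranges: queries come from the focal fauna in spirit, but reference
  ## species may be allopatric - each range includes the focal region with
  ## probability p_focal plus random other regions up to range_size
  other_regions <- setdiff(config$region_pool, config$focal_region)
  sp_ranges <- lapply(seq_len(n_sp), function(s) {
    has_focal <- stats::runif(1) < config$p_focal
    n_other <- max(0L, config$range_size - as.integer(has_focal))
    r <- sample(other_regions, min(n_other, length(other_regions)))
    if (has_focal) c(config$focal_region, r) else r
  })
  names(sp_ranges) <- tax$species

  uncertain <- matrix(character(0), ncol = 2)

  ## 1. synonym renames (unresolved name pairs)
  if (config$n_synonym_pairs > 0) {
    syn_sp <- sample.int(n_sp, min(config$n_synonym_pairs, n_sp))
    for (s in syn_sp) {
      alias <- paste0(tax$species[s], "_alt")
      uncertain <- rbind(uncertain, c(tax$species[s], alias))
      cand <- which(refs$species_idx == s)[-1]  # spare the modal haplotype
      pick <- sample(cand, min(config$syn_refs_renamed, length(cand)))
      refs$displayed[pick] <- alias
      refs$multi[pick] <- refs$multi[pick] | refs$corruption[pick] != "none"
      refs$corruption[pick] <- "synonym_name"
      sp_ranges[[alias]] <- sp_ranges[[tax$species[s]]]
    }
  }

  ## 2. introgression haplotype copies between congeneric pairs
  if (config$n_introgression_pairs > 0) {
    genera <- unique(tax$genus_global)
    used <- integer(0)
    pairs_made <- 0L
    for (g in sample(genera)) {
      if (pairs_made >= config$n_introgression_pairs) break
      members <- setdiff(which(tax$genus_global == g), used)
      if (length(members) < 2) next
      ab <- sample(members, 2)
      used <- c(used, ab)
      donor_hap <- refs$sequence[which(refs$species_idx == ab[1])[1]]
      donor_code <- encode_sequences(donor_hap)[1, ]
      cand <- which(refs$species_idx == ab[2])[-1]  # spare the modal haplotype
      pick <- sample(cand, min(config$introgression_copies, length(cand)))
      for (i in pick) {
        refs$sequence[i] <- decode_sequence(
          substitute_sites(donor_code, stats::rpois(1, 0.5), kappa))
        refs$multi[i] <- refs$multi[i] | refs$corruption[i] != "none"
        refs$corruption[i] <- "introgressed_shared_haplotype"
      }
      pairs_made <- pairs_made + 1L
    }
  }

  ## 3. anomalous haplotype lineages
  anom_sp <- which(stats::runif(n_sp) < config$p_anomalous)
  for (s in anom_sp) {
    anom_anc <- mutate_exact(sp_anc[[s]], config$anomaly_divergence, kappa)
    add <- data.frame(
      species_idx = s,
      sequence = vapply(seq_len(config$n_anomalous_refs), function(i)
        decode_sequence(mutate_exact(anom_anc, config$anomaly_radiation,
                                     kappa)), ""),
      record_id = sprintf("R%04dA%d", s, seq_len(config$n_anomalous_refs)),
      true_species = tax$species[s],
      displayed = tax$species[s],
      corruption = "anomalous_haplotype",
      multi = FALSE, stringsAsFactors = FALSE)
    refs <- rbind(refs, add)
    qi <- which(queries$species_idx == s)[1]
    queries$sequence[qi] <- decode_sequence(
      mutate_exact(anom_anc, config$anomaly_radiation, kappa))
    queries$multi[qi] <- queries$multi[qi] | queries$corruption[qi] != "none"
    queries$corruption[qi] <- "anomalous_haplotype"
  }

  ## 4. sporadic within-genus mislabels (never the modal haplotype)
  first_ref <- !duplicated(refs$species_idx)
  if (config$p_species_mislabel > 0) {
    hit <- which(stats::runif(nrow(refs)) < config$p_species_mislabel &
                   !first_ref)
    for (i in hit) {
      g <- tax$genus_global[refs$species_idx[i]]
      others <- which(tax$genus_global == g &
                        seq_len(n_sp) != refs$species_idx[i])
      if (length(others) == 0) next
      target <- if (length(others) == 1) others else sample(others, 1)
      refs$displayed[i] <- tax$species[target]
      refs$multi[i] <- refs$multi[i] | refs$corruption[i] != "none"
      refs$corruption[i] <- "species_mislabel"
    }
  }

  ## 5. cross-genus / cross-family label swaps (never the modal haplotype)
  if (config$p_cross_genus_swap > 0) {
    hit <- which(stats::runif(nrow(refs)) < config$p_cross_genus_swap &
                   !first_ref)
    for (i in hit) {
      g <- tax$genus_global[refs$species_idx[i]]
      others <- which(tax$genus_global != g)
      target <- if (length(others) == 1) others else sample(others, 1)
      refs$displayed[i] <- tax$species[target]
      refs$multi[i] <- refs$multi[i] | refs$corruption[i] != "none"
      refs$corruption[i] <- "cross_genus_swap"
    }
  }

  ## 6. species deletions
  missing_sp <- which(stats::runif(n_sp) < config$p_missing_species)
  present <- rep(TRUE, n_sp)
  if (length(missing_sp)) {
    present[missing_sp] <- FALSE
    refs <- refs[!(refs$species_idx %in% missing_sp), , drop = FALSE]
  }

  region_str <- function(sp) vapply(sp_ranges[sp], paste, "", collapse = ";")
  tax_cols <- function(idx) {
    data.frame(genus = tax$genus[idx], subfamily = tax$subfamily[idx],
               family = tax$family[idx], stringsAsFactors = FALSE)
  }
  ## taxonomic columns follow the DISPLAYED name (a swapped label carries the
  ## wrong genus and family into the library, as a real mislabel would);
  ## unresolved alias names are congeneric with their valid name
  disp_idx <- match(refs$displayed, tax$species)
  disp_idx[is.na(disp_idx)] <- refs$species_idx[is.na(disp_idx)]

  references <- cbind(
    data.frame(record_id = refs$record_id, species = refs$displayed,
               stringsAsFactors = FALSE),
    tax_cols(disp_idx),
    data.frame(regions = region_str(refs$true_species), role = "reference",
               morphology_label = "", sequence = refs$sequence,
               stringsAsFactors = FALSE))
  query_records <- cbind(
    data.frame(record_id = queries$record_id, species = queries$true_species,
               stringsAsFactors = FALSE),
    tax_cols(queries$species_idx),
    data.frame(regions = region_str(queries$true_species), role = "query",
               morphology_label = queries$true_species,
               sequence = queries$sequence, stringsAsFactors = FALSE))
  rownames(references) <- rownames(query_records) <- NULL

  truth_records <- rbind(
    data.frame(record_id = refs$record_id, role = "reference",
               true_species = refs$true_species, displayed = refs$displayed,
               corruption = refs$corruption, multi = refs$multi,
               stringsAsFactors = FALSE),
    data.frame(record_id = queries$record_id, role = "query",
               true_species = queries$true_species,
               displayed = queries$true_species,
               corruption = queries$corruption, multi = queries$multi,
               stringsAsFactors = FALSE))
  rownames(truth_records) <- NULL

  structure(list(
    references = references,
    queries = query_records,
    ranges = range_table(sp_ranges, config$focal_region),
    synonymy = synonymy_table(uncertain_pairs = uncertain),
    truth = list(records = truth_records,
                 species = data.frame(species = tax$species,
                                      present_in_reference = present,
                                      stringsAsFactors = FALSE)),
    config = config),
    class = "sim_library")
}

#' One-process-at-a-time simulation configurations
#'
#' Builds a [sim_config()] in which exactly one corruption process is active,
#' at a rate giving adequate fault counts at the default 50-species shape.
#' Used to evaluate per-category precision and recall of the classifier.
#'
#' @param category one of [problem_categories()].
#' @param seed RNG seed.
#' @param ... further [sim_config()] overrides.
#' @return a `sim_config`.
#' @export
single_fault_config <- function(category, seed = 1L, ...) {
  category <- match.arg(category, PROBLEM_CATEGORIES)
  fault <- switch(category,
    SPECIES_MISLABEL = list(p_species_mislabel = 0.04),
    CROSS_GENUS_CONTAMINATION = list(p_cross_genus_swap = 0.04),
    UNDIFFERENTIATED = list(n_introgression_pairs = 5L),
    TAXONOMY_UNCERTAINTY = list(n_synonym_pairs = 5L),
    ANOMALOUS_BARCODE = list(p_anomalous = 0.1),
    DB_INCOMPLETE = list(p_missing_species = 0.1))
  do.call(sim_config, c(list(seed = seed), fault, list(...)))
}

#' Per-category precision and recall against simulation truth
#'
#' A query is truly affected by a corruption process when its hit list
#' contains a record corrupted by that process whose displayed label differs
#' from the query's morphology label (a corrupted record agreeing with the
#' query's own name cannot mislead its identification); the anomalous
#' category keys on the query itself being anomalous, and incompleteness on
#' the query's species having been deleted from the reference library.
#'
#' @param records list of `audit_record` (e.g. `run_audit(...)$records`).
#' @param truth the `truth` element of a [simulate_library()] result.
#' @return `data.frame` with one row per category: `n_truth`, `n_flagged`,
#'   `tp`, `precision`, `recall` (`NA` when the denominator is empty).
#' @export
score_recovery <- function(records, truth) {
  tr <- truth$records
  corrupted <- function(type) tr$record_id[tr$corruption == type &
                                             tr$role == "reference"]
  sets <- list(
    SPECIES_MISLABEL = corrupted("species_mislabel"),
    CROSS_GENUS_CONTAMINATION = corrupted("cross_genus_swap"),
    UNDIFFERENTIATED = corrupted("introgressed_shared_haplotype"),
    TAXONOMY_UNCERTAINTY = corrupted("synonym_name"))
  anomalous_queries <- tr$record_id[tr$corruption == "anomalous_haplotype" &
                                      tr$role == "query"]
  missing_species <- truth$species$species[!truth$species$present_in_reference]

  rows <- lapply(PROBLEM_CATEGORIES, function(cat) {
    flagged <- vapply(records, function(r) cat %in% r$categories, FALSE)
    in_truth <- vapply(records, function(r) {
      if (cat == "ANOMALOUS_BARCODE")
        return(r$query_id %in% anomalous_queries)
      if (cat == "DB_INCOMPLETE")
        return(r$morphology_label %in% missing_species)
      h <- r$result$hits
      any(h$ref_id %in% sets[[cat]] & h$species_raw != r$morphology_label)
    }, FALSE)
    tp <- sum(flagged & in_truth)
    data.frame(category = cat, n_truth = sum(in_truth),
               n_flagged = sum(flagged), tp = tp,
               precision = if (sum(flagged)) tp / sum(flagged) else NA_real_,
               recall = if (sum(in_truth)) tp / sum(in_truth) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
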