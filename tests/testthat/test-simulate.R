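# Small taxonomies keep the unit tests quick; the full default shape is
# exercised by the acceptance suite.
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_families = 1L, n_genera_per_family = 3L,
             n_species_per_genus = 3L, ...)
}

test_that("the same seed and config reproduce the library exactly", {
  s1 <- simulate_library(small_cfg(5, n_synonym_pairs = 2L, p_anomalous = 0.2))
  s2 <- simulate_library(small_cfg(5, n_synonym_pairs = 2L, p_anomalous = 0.2))
  expect_identical(s1, s2)
})

test_that("an inconsistent divergence ladder is rejected before generation", {
  expect_error(sim_config(intraspecific_divergence = 0.05), "ladder")
  expect_error(sim_config(intergeneric_divergence = 0.02), "ladder")
})

test_that("a clean library realizes the divergence ladder and clusters by species", {
  sim <- simulate_library(small_cfg(3))
  expect_true(all(sim$truth$records$corruption == "none"))

  pooled <- rbind(sim$references, sim$queries)
  d <- distance_matrix(pooled, metric = "k2p")
  species <- c(sim$references$species, sim$queries$species)
  same <- outer(species, species, "==")
  up <- upper.tri(d)
  expect_lt(max(d[up & same]), 0.03)   # within species below the threshold
  expect_gt(min(d[up & !same]), 0.03)  # between species above it

  cs <- delimit(d)
  expect_equal(length(cs$clusters), length(unique(species)))
  for (cl in cs$clusters) {
    expect_equal(length(unique(species[match(cl, pooled$record_id)])), 1)
  }

  # realized mean conspecific distance near the configured value
  mean_intra <- mean(d[up & same])
  expect_lt(abs(mean_intra - 0.005) / 0.005, 0.30)
})

test_that("anomalous lineages sit far from the main cluster but inside it at 3%", {
  sim <- simulate_library(small_cfg(7, p_anomalous = 1))
  tr <- sim$truth$records
  anom_refs <- tr$record_id[tr$corruption == "anomalous_haplotype" &
                              tr$role == "reference"]
  expect_gt(length(anom_refs), 0)
  pooled <- rbind(sim$references, sim$queries)
  d <- distance_matrix(pooled, metric = "k2p")
  for (id in anom_refs) {
    sp <- tr$true_species[tr$record_id == id]
    main <- tr$record_id[tr$true_species == sp & tr$corruption == "none" &
                           tr$role == "reference"]
    expect_gte(min(d[id, main]), 0.05)
  }
  # anomalous query clusters with its anomalous conspecific references
  cs <- delimit(d)
  anom_q <- tr$record_id[tr$corruption == "anomalous_haplotype" & tr$role == "query"]
  for (id in anom_q) {
    sp <- tr$true_species[tr$record_id == id]
    mates <- intersect(anom_refs, tr$record_id[tr$true_species == sp])
    expect_true(any(cluster_of(mates, cs) == cluster_of(id, cs)))
  }
})

test_that("introgression pairs share one haplotype cluster holding both names", {
  sim <- simulate_library(small_cfg(9, n_introgression_pairs = 1L))
  tr <- sim$truth$records
  intro <- tr[tr$corruption == "introgressed_shared_haplotype", ]
  expect_equal(nrow(intro), 2)
  donor_sp <- unique(tr$true_species[tr$true_species != intro$true_species[1] &
                                       tr$role == "reference"])
  pooled <- rbind(sim$references, sim$queries)
  d <- distance_matrix(pooled, metric = "k2p")
  cs <- delimit(d)
  k <- cluster_of(intro$record_id[1], cs)
  members <- cs$clusters[[k]]
  names_in <- unique(sim$references$species[match(members, sim$references$record_id)])
  names_in <- names_in[!is.na(names_in)]
  expect_equal(length(names_in), 2)   # recipient labels inside the donor cluster
})

test_that("query morphology labels always carry the true species", {
  sim <- simulate_library(small_cfg(11, p_species_mislabel = 0.3,
                                    p_cross_genus_swap = 0.2))
  tr <- sim$truth$records
  q <- tr[tr$role == "query", ]
  expect_equal(sim$queries$morphology_label,
               q$true_species[match(sim$queries$record_id, q$record_id)])
  # displayed == true wherever corruption is none
  clean <- tr[tr$corruption == "none", ]
  expect_equal(clean$displayed, clean$true_species)
})

test_that("a clean library audits clean end to end", {
  sim <- simulate_library(small_cfg(13))
  run <- run_audit(sim$references, sim$queries, synonymy = sim$synonymy,
                   ranges = sim$ranges)
  expect_equal(run$summary$n_problematic, 0)
  expect_true(all(vapply(run$records, function(r) length(r$categories) == 0, TRUE)))
  sc <- score_recovery(run$records, sim$truth)
  expect_equal(sum(sc$n_truth), 0)
  expect_equal(sum(sc$n_flagged), 0)
})

test_that("deleted species are recovered as database incompleteness", {
  sim <- simulate_library(small_cfg(17, p_missing_species = 0.5))
  missing <- sim$truth$species$species[!sim$truth$species$present_in_reference]
  expect_gt(length(missing), 0)
  expect_false(any(sim$references$species %in% missing))
  run <- run_audit(sim$references, sim$queries, synonymy = sim$synonymy,
                   ranges = sim$ranges)
  sc <- score_recovery(run$records, sim$truth)
  row <- sc[sc$category == "DB_INCOMPLETE", ]
  expect_equal(row$recall, 1)
  expect_equal(row$precision, 1)
})
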