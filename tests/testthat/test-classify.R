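# Each scenario builds a hit list, a cluster assignment and a reference table
# directly, runs consensus_identify + classify, and checks the category set.

run_classify <- function(query_label, hits, membership, synonymy = synonymy_table(),
                         references = NULL, ranges = NULL,
                         settings = classifier_settings()) {
  query <- list(record_id = "q", morphology_label = query_label)
  references <- references %||% fake_references(hits$species)
  result <- consensus_identify(hits, search_settings())
  classify(query, hits, result, fake_clusters(membership), synonymy,
           references, settings, ranges)
}

one_cluster <- function(hits) {
  setNames(rep(1L, nrow(hits) + 1L), c(hits$ref_id, "q"))
}

test_that("conspecific-grade hits from another genus flag contamination", {
  hits <- make_hits(c(rep("Erynnis tages", 24), "Colias alfacariensis"),
                    rep(100, 25),
                    family = c(rep("Hesperiidae", 24), "Pieridae"))
  rec <- run_classify("Erynnis tages", hits, one_cluster(hits))
  expect_equal(rec$categories, "CROSS_GENUS_CONTAMINATION")
  expect_equal(rec$majority_id, "Erynnis tages")
  expect_equal(rec$conflicts$name, "Colias alfacariensis")
})

test_that("well-represented congeneric sharing flags undifferentiated barcodes", {
  hits <- make_hits(c(rep("Carcharodus alceae", 5),
                      rep("Carcharodus floccifera", 5),
                      rep("Carcharodus stauderi", 5)), rep(100, 15))
  rec <- run_classify("Carcharodus alceae", hits, one_cluster(hits))
  expect_equal(rec$categories, "UNDIFFERENTIATED")
})

test_that("sporadic congeneric conflicts inside the cluster flag mislabels", {
  hits <- make_hits(c(rep("Pieris napi", 24), "Pieris rapae"),
                    c(rep(100, 24), 100))
  rec <- run_classify("Pieris napi", hits, one_cluster(hits))
  expect_equal(rec$categories, "SPECIES_MISLABEL")

  # the same conflict outside the query's cluster is not a mislabel
  m <- one_cluster(hits)
  m[hits$ref_id[25]] <- 2L
  rec2 <- run_classify("Pieris napi", hits, m)
  expect_false("SPECIES_MISLABEL" %in% rec2$categories)
})

test_that("synonym and uncertain-pair conflicts flag taxonomy uncertainty", {
  syn <- synonymy_table(uncertain_pairs = cbind("Muschampia proteides",
                                                "Muschampia sovietica"))
  hits <- make_hits(c(rep("Muschampia proteides", 10),
                      rep("Muschampia sovietica", 8)), rep(100, 18))
  rec <- run_classify("Muschampia proteides", hits, one_cluster(hits), syn)
  expect_equal(rec$categories, "TAXONOMY_UNCERTAINTY")

  # a raw label canonicalizing onto the majority name also counts
  syn2 <- synonymy_table(canonical = c("Muschampia sovietica" = "Muschampia proteides"))
  hits2 <- make_hits(rep("Muschampia proteides", 18), rep(100, 18),
                     species_raw = c(rep("Muschampia proteides", 10),
                                     rep("Muschampia sovietica", 8)))
  # force a problematic identification: one extra congeneric conflict
  hits2 <- rbind(hits2, make_hits("Muschampia proto", 100, ref_id = "H099"))
  rec2 <- run_classify("Muschampia proteides", hits2, one_cluster(hits2), syn2)
  expect_true("TAXONOMY_UNCERTAINTY" %in% rec2$categories)
})

test_that("sub-grade same-name hits in a same-name cluster flag anomalous barcodes", {
  hits <- make_hits(rep("Hyponephele lycaon", 3), c(98.26, 98.2, 98.11))
  rec <- run_classify("Hyponephele lycaon", hits, one_cluster(hits))
  expect_equal(rec$categories, "ANOMALOUS_BARCODE")
  expect_equal(rec$result$rank, "genus")
})

test_that("absent conspecific references flag database incompleteness", {
  hits <- make_hits(rep("Polyommatus altivagans", 3), c(98.72, 98.5, 98.3))
  rec <- run_classify("Polyommatus damocles", hits, one_cluster(hits))
  expect_equal(rec$categories, "DB_INCOMPLETE")

  # with an empty hit list the verdict is the same
  h0 <- make_hits(character(0), numeric(0))
  rec0 <- run_classify("Polyommatus damocles", h0, c(q = 1L),
                       references = fake_references("Polyommatus altivagans"))
  expect_equal(rec0$categories, "DB_INCOMPLETE")
  expect_equal(rec0$result$rank, "none")
})

test_that("clean identifications carry no categories, and classification is deterministic", {
  hits <- make_hits(rep("Aglais io", 25), rep(100, 25))
  rec <- run_classify("Aglais io", hits, one_cluster(hits))
  expect_length(rec$categories, 0)
  expect_false(is_problematic(rec$result) && length(rec$categories) == 0)
  expect_equal(rec$geographic_correction, "N/A")

  hits2 <- make_hits(c(rep("Aa bb", 12), rep("Aa cc", 8), "Zz yy"),
                     c(rep(100, 20), 99.5), family = c(rep("Aidae", 20), "Zidae"))
  syn <- synonymy_table(uncertain_pairs = cbind("Aa bb", "Aa cc"))
  r1 <- run_classify("Aa bb", hits2, one_cluster(hits2), syn)
  r2 <- run_classify("Aa bb", hits2, one_cluster(hits2), syn)
  expect_identical(r1$categories, r2$categories)
  # multi-category records serialize in fixed enum order
  expect_equal(r1$categories,
               intersect(problem_categories(), r1$categories))
  expect_true(all(c("CROSS_GENUS_CONTAMINATION", "TAXONOMY_UNCERTAINTY")
                  %in% r1$categories))
})

test_that("geographic correction follows the footnote semantics", {
  rt <- range_table(list("Colias crocea" = c("VLG", "W-EU"),
                         "Davidina lederi" = "MNG",
                         "Davidina dzhulukuli" = "ALT"), "VLG")
  # conflicting species present in the focal region: not rescued
  expect_equal(geographic_correction("UNDIFFERENTIATED", "Colias crocea", rt), "No")
  # all conflicting species absent: rescued
  expect_equal(geographic_correction("UNDIFFERENTIATED",
                                     c("Davidina lederi", "Davidina dzhulukuli"),
                                     rt), "Yes")
  # unknown range: conservative No
  expect_equal(geographic_correction("UNDIFFERENTIATED", "Ghost species", rt), "No")
  # indeterminate labels are ignored
  expect_equal(geographic_correction("UNDIFFERENTIATED",
                                     c("Davidina sp.", "Davidina lederi"), rt),
               "Yes")
  # not applicable when the problem is not undifferentiated barcodes
  expect_equal(geographic_correction("SPECIES_MISLABEL", "Colias crocea", rt), "N/A")
})

test_that("classified audit records flow into the report and back", {
  hits <- make_hits(c(rep("Apatura ilia", 20), rep("Apatura metis", 5)),
                    c(rep(100, 20), rep(99.53, 5)))
  rt <- range_table(list("Apatura metis" = "VLG"), "VLG")
  rec <- run_classify("Apatura ilia", hits, one_cluster(hits), ranges = rt)
  expect_equal(rec$geographic_correction, "No")
  df <- audit_report(list(rec))
  expect_equal(df$other_ids_with_similarity, "Apatura metis (99.53)")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_audit_report(df, f)
  expect_equal(read_audit_report(f), df)
})
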