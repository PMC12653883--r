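test_that("top_k_search ranks by similarity, applies the depth floor", {
  set.seed(21)
  q_seq <- random_sequence(658)
  refs <- make_records(
    c("dup", "near", "deep"),
    c(q_seq,                        # exact copy of the query
      diverge_sequence(q_seq, 3),   # ~99.5%
      diverge_sequence(q_seq, 46)), # ~93.0%, below the 94% depth
    species = c("Aa bb", "Aa bb", "Aa cc"), genus = "Aa")
  query <- list(record_id = "q", sequence = q_seq)
  hits <- top_k_search(query, refs, search_settings())
  expect_equal(hits$ref_id, c("dup", "near"))
  expect_equal(hits$similarity[1], 100)

  # the query never matches its own record id, but duplicates are legitimate
  refs2 <- refs; refs2$record_id[1] <- "q"
  hits2 <- top_k_search(query, refs2, search_settings())
  expect_equal(hits2$ref_id, "near")
})

test_that("top_k_search equals a brute-force all-pairs sort", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    base <- random_sequence(300)
    refs <- make_records(sprintf("r%03d", 1:n),
                         vapply(1:n, function(i)
                           diverge_sequence(base, sample(0:25, 1)), ""),
                         species = "Aa bb")
    query <- list(record_id = "q", sequence = base)
    st <- search_settings(k = 25, depth_pct = 94)
    hits <- top_k_search(query, refs, st)

    sims <- vapply(refs$sequence, function(s) naive_similarity(base, s), 0,
                   USE.NAMES = FALSE)
    ord <- order(-sims, refs$record_id)
    keep <- ord[sims[ord] >= 94][seq_len(min(25, sum(sims >= 94)))]
    expect_equal(hits$ref_id, refs$record_id[keep])
    expect_equal(hits$similarity, sims[keep], tolerance = 1e-9)
  }
})

test_that("depth and k are monotone: tightening never adds hits", {
  set.seed(23)
  base <- random_sequence(300)
  refs <- make_records(sprintf("r%02d", 1:40),
                       vapply(1:40, function(i)
                         diverge_sequence(base, sample(0:25, 1)), ""),
                       species = "Aa bb")
  query <- list(record_id = "q", sequence = base)
  h0 <- top_k_search(query, refs, search_settings(k = 25, depth_pct = 94))
  h_deeper <- top_k_search(query, refs, search_settings(k = 25, depth_pct = 96))
  h_fewer <- top_k_search(query, refs, search_settings(k = 10, depth_pct = 94))
  expect_true(all(h_deeper$ref_id %in% h0$ref_id))
  expect_true(all(h_fewer$ref_id %in% h0$ref_id))
  expect_lte(nrow(h_deeper), nrow(h0))
  expect_lte(nrow(h_fewer), 10)
})

test_that("consensus identification escalates rank and scores confidence", {
  st <- search_settings()

  # unanimous conspecific hits
  h <- make_hits(rep("Erynnis tages", 25), rep(100, 25))
  r <- consensus_identify(h, st)
  expect_equal(r[c("taxon", "rank", "confidence")],
               list(taxon = "Erynnis tages", rank = "species", confidence = 100))
  expect_false(is_problematic(r))

  # one discordant hit well below the best: species rank, confidence 24/25
  h <- make_hits(c(rep("Aa bb", 24), "Aa cc"), c(rep(100, 24), 98))
  r <- consensus_identify(h, st)
  expect_equal(r[c("taxon", "rank", "confidence")],
               list(taxon = "Aa bb", rank = "species", confidence = 96))
  expect_true(is_problematic(r))

  # four congeneric species tied at the top: genus only, confidence 100
  h <- make_hits(c(rep("Colias erate", 10), rep("Colias crocea", 8),
                   rep("Colias marnoana", 4), rep("Colias poliographus", 3)),
                 c(rep(100, 10), rep(100, 8), rep(100, 4), rep(99.84, 3)))
  r <- consensus_identify(h, st)
  expect_equal(r[c("taxon", "rank", "confidence")],
               list(taxon = "Colias", rank = "genus", confidence = 100))

  # several genera of one subfamily, none conspecific-grade
  h <- make_hits(c("Hyponephele lycaon", "Maniola jurtina", "Pyronia tithonus"),
                 c(98.3, 98.2, 98.1), subfamily = "Satyrinae",
                 family = "Nymphalidae")
  r <- consensus_identify(h, st)
  expect_equal(r[c("taxon", "rank", "confidence")],
               list(taxon = "Satyrinae", rank = "subfamily", confidence = 100))

  # a single co-best species below conspecific grade is genus-rank evidence
  h <- make_hits(rep("Polyommatus altivagans", 3), c(98.72, 98.5, 98.4))
  r <- consensus_identify(h, st)
  expect_equal(r$rank, "genus")
  expect_equal(r$taxon, "Polyommatus")

  # empty hit list
  r <- consensus_identify(make_hits(character(0), numeric(0)), st)
  expect_equal(r$rank, "none")
  expect_true(is_problematic(r))
})

test_that("consensus is invariant to order-preserving permutations of ties", {
  st <- search_settings()
  h <- make_hits(c(rep("Aa bb", 5), rep("Aa cc", 5)), rep(100, 10))
  r1 <- consensus_identify(h, st)
  r2 <- consensus_identify(h[c(6:10, 1:5), ], st)
  expect_equal(r1[c("taxon", "rank", "confidence")],
               r2[c("taxon", "rank", "confidence")])
})

test_that("is_problematic follows the rank/confidence rule", {
  mk <- function(rank, conf) structure(
    list(taxon = "x", rank = rank, confidence = conf,
         hits = make_hits("x", 100)), class = "identification_result")
  expect_false(is_problematic(mk("species", 100)))
  expect_true(is_problematic(mk("species", 96)))
  expect_true(is_problematic(mk("genus", 100)))
  expect_true(is_problematic(mk("none", NA)))
})
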