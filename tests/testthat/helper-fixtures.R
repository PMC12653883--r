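# Shared fixture builders and naive oracles (kept independent of the package
# implementation paths they check).

random_sequence <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# substitute exactly n distinct sites with a different base
diverge_sequence <- function(seq, n) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# naive per-pair similarity oracle: character-wise comparison
naive_similarity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  100 * (1 - sum(ca[ok] != cb[ok]) / sum(ok))
}

make_records <- function(ids, seqs, species = "", genus = "", subfamily = "",
                         family = "", role = "reference",
                         morphology_label = "") {
  barcode_records(record_id = ids, sequence = seqs, species = species,
                  genus = genus, subfamily = subfamily, family = family,
                  role = role, morphology_label = morphology_label)
}

# hit-list builder matching the column contract of top_k_search()
make_hits <- function(species, similarity, genus = NULL, subfamily = NULL,
                      family = NULL, species_raw = NULL,
                      ref_id = sprintf("H%03d", seq_along(species))) {
  if (length(species) == 0L) {
    return(data.frame(ref_id = character(0), similarity = numeric(0),
                      species_raw = character(0), species = character(0),
                      genus = character(0), subfamily = character(0),
                      family = character(0), stringsAsFactors = FALSE))
  }
  genus <- genus %||% vapply(strsplit(species, " "), `[[`, "", 1)
  data.frame(ref_id = ref_id, similarity = similarity,
             species_raw = species_raw %||% species, species = species,
             genus = genus,
             subfamily = subfamily %||% paste0(genus, "inae"),
             family = family %||% paste0(genus, "idae"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal cluster assignment for classifier unit tests
fake_clusters <- function(membership) {
  structure(list(membership = membership,
                 clusters = split(names(membership), membership),
                 nn_distance = rep(Inf, length(unique(membership))),
                 settings = cluster_settings()),
            class = "cluster_set")
}

# minimal reference table for classifier unit tests
fake_references <- function(species) {
  data.frame(record_id = sprintf("H%03d", seq_along(species)),
             species = species, stringsAsFactors = FALSE)
}

# canonical labeling: two partitions are equal iff the relabeled vectors match
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "barcodeaudit", mustWork = TRUE)
}
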