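## Reading and writing external representations: FASTA barcode sets with
## sidecar specimen metadata, range and synonymy tables, and the audit
## report. All tables are UTF-8, tab-separated; lines starting with '#'
## are comments.

BARCODE_METADATA_COLS <- c("record_id", "species", "genus", "subfamily",
                           "family", "regions", "role", "morphology_label")

read_tsv_table <- function(file) {
  utils::read.delim(file, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", quote = "",
                    fileEncoding = "UTF-8", check.names = FALSE)
}

write_tsv_table <- function(df, file) {
  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' Read a barcode set from FASTA plus a specimen metadata table
#'
#' Joins a FASTA file of aligned COI barcodes with a tab-separated metadata
#' table keyed by FASTA identifier. Sequences are uppercased and 'U' is
#' normalized to 'T'; only IUPAC nucleotide codes and '-' are accepted.
#'
#' @param fasta path to a FASTA file.
#' @param metadata path to a tab-separated table with columns `record_id`,
#'   `species`, `genus`, `subfamily`, `family`, `regions` (semicolon-joined
#'   region codes), `role` (`reference` or `query`) and `morphology_label`
#'   (required for queries).
#' @return A `data.frame` of barcode records, one row per FASTA entry, in
#'   FASTA order, with the metadata columns joined and a `sequence` column.
#' @export
read_barcode_records <- function(fasta, metadata) {
  ## read as raw strings: the DNA alphabet check (with position reporting)
  ## is done by validate_barcode_records, not silently by the parser
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- names(seqs)
  ids <- sub("\\s.*$", "", ids)   # FASTA description after first whitespace
  if (anyDuplicated(ids))
    stop("duplicate record id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- read_tsv_table(metadata)
  missing_cols <- setdiff(BARCODE_METADATA_COLS, names(meta))
  if (length(missing_cols))
    stop("metadata table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$record_id))
    stop("duplicate record id in metadata: ",
         paste(unique(meta$record_id[duplicated(meta$record_id)]), collapse = ", "))
  absent <- setdiff(ids, meta$record_id)
  if (length(absent))
    stop("no metadata row for FASTA id(s): ", paste(absent, collapse = ", "))
  rows <- meta[match(ids, meta$record_id), BARCODE_METADATA_COLS]
  rows$sequence <- toupper(as.character(seqs))
  rows$sequence <- gsub("U", "T", rows$sequence, fixed = TRUE)
  validate_barcode_records(rows)
  rownames(rows) <- NULL
  rows
}

#' Assemble barcode records from vectors (in-code constructor)
#'
#' @param record_id,sequence,species,genus,subfamily,family,regions,role,morphology_label
#'   record fields; scalars are recycled.
#' @return a validated barcode record `data.frame`.
#' @export
barcode_records <- function(record_id, sequence, species = "", genus = "",
                            subfamily = "", family = "", regions = "",
                            role = "reference", morphology_label = "") {
  df <- data.frame(record_id = record_id,
                   species = species, genus = genus, subfamily = subfamily,
                   family = family, regions = regions, role = role,
                   morphology_label = morphology_label,
                   sequence = toupper(sequence),
                   stringsAsFactors = FALSE)
  df$sequence <- gsub("U", "T", df$sequence, fixed = TRUE)
  validate_barcode_records(df)
  df
}

validate_barcode_records <- function(df) {
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id: ",
         paste(unique(df$record_id[duplicated(df$record_id)]), collapse = ", "))
  n <- nchar(df$sequence)
  if (any(n < 200 | n > 1600))
    stop("sequence length outside [200, 1600] for: ",
         paste(df$record_id[n < 200 | n > 1600], collapse = ", "))
  for (i in seq_len(nrow(df))) {
    pos <- first_illegal_char(df$sequence[i])
    if (pos > 0L)
      stop("illegal character in sequence of '", df$record_id[i],
           "' at position ", pos)
  }
  if (!all(df$role %in% c("reference", "query")))
    stop("role must be 'reference' or 'query'")
  bad <- df$role == "query" & (is.na(df$morphology_label) | df$morphology_label == "")
  if (any(bad))
    stop("query records need a morphology_label: ",
         paste(df$record_id[bad], collapse = ", "))
  invisible(df)
}

#' Write barcode records back to FASTA + metadata
#'
#' @param records barcode record `data.frame`.
#' @param fasta,metadata output paths.
#' @export
write_barcode_records <- function(records, fasta, metadata) {
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$record_id
  Biostrings::writeXStringSet(x, fasta, width = 80L)
  write_tsv_table(records[, BARCODE_METADATA_COLS], metadata)
  invisible(fasta)
}

#' Drop barcodes shorter than a minimum usable length
#'
#' Keeps records whose count of non-gap characters is at least `min_length`
#' (mirrors the common curation floor of 500 bp within the 658 bp barcode
#' region). Order-preserving and idempotent; logs the number removed.
#'
#' @param records barcode record `data.frame`.
#' @param min_length minimum number of non-gap characters.
#' @return the filtered `data.frame`.
#' @export
filter_min_length <- function(records, min_length = 500L) {
  stopifnot(min_length > 0)
  if (nrow(records) == 0L) return(records)
  n_bases <- nchar(gsub("-", "", records$sequence, fixed = TRUE))
  keep <- n_bases >= min_length
  if (any(!keep))
    message(sum(!keep), " record(s) below ", min_length, " bp removed")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ------------------------------------------------------------------
## Range table

#' Read a species range table
#'
#' @param file tab-separated table with columns `species` and `regions`
#'   (semicolon-joined region codes).
#' @param focal_region the region identifications are audited for.
#' @return an object of class `range_table`.
#' @export
read_range_table <- function(file, focal_region) {
  df <- read_tsv_table(file)
  stopifnot(all(c("species", "regions") %in% names(df)))
  range_table(stats::setNames(strsplit(df$regions, ";", fixed = TRUE),
                              df$species),
              focal_region)
}

#' Construct a range table
#'
#' @param map named list: species binomial -> character vector of region codes.
#' @param focal_region region code the audit is carried out for.
#' @return an object of class `range_table`.
#' @export
range_table <- function(map, focal_region) {
  stopifnot(is.list(map), length(focal_region) == 1L, nzchar(focal_region))
  structure(list(map = map, focal_region = focal_region),
            class = "range_table")
}

#' Regions where a species occurs
#'
#' @param ranges a `range_table`.
#' @param species species binomial.
#' @return a character vector of region codes, or the string `"unknown"` for
#'   a species absent from the table (never an empty set).
#' @export
range_of <- function(ranges, species) {
  stopifnot(inherits(ranges, "range_table"))
  r <- ranges$map[[species]]
  if (is.null(r) || length(r) == 0L) "unknown" else r
}

#' @export
write_range_table <- function(ranges, file) {
  df <- data.frame(species = names(ranges$map),
                   regions = vapply(ranges$map, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  write_tsv_table(df, file)
}

## ------------------------------------------------------------------
## Synonymy table

#' Construct a synonymy / taxonomic-uncertainty table
#'
#' `canonical` maps names to their valid name (junior synonyms are merged
#' before consensus identification); `uncertain_pairs` lists unordered name
#' pairs whose status is unresolved (both names stay distinct, but a conflict
#' between them is attributed to taxonomy, not to a reference error).
#'
#' @param canonical named character vector: name -> valid name. May be empty.
#' @param uncertain_pairs two-column character matrix (or data.frame) of
#'   unordered name pairs; may have zero rows.
#' @return an object of class `synonymy_table`.
#' @export
synonymy_table <- function(canonical = character(0),
                           uncertain_pairs = matrix(character(0), ncol = 2)) {
  canonical <- canonical[names(canonical) != canonical]  # identities implicit
  ## idempotence / acyclicity: the valid side must not map further
  chained <- intersect(unname(canonical), names(canonical))
  if (length(chained))
    stop("synonymy table is not idempotent; chained name(s): ",
         paste(chained, collapse = ", "))
  up <- as.matrix(uncertain_pairs)
  if (ncol(up) != 2 && length(up) > 0) stop("uncertain_pairs must have 2 columns")
  structure(list(canonical = canonical, uncertain_pairs = up),
            class = "synonymy_table")
}

#' Read a synonymy table
#'
#' @param file tab-separated table with columns `name`, `valid_name`,
#'   `uncertain_flag` (0/1). Flagged rows are unresolved pairs; unflagged
#'   rows are canonicalized.
#' @return a `synonymy_table`.
#' @export
read_synonymy_table <- function(file) {
  df <- read_tsv_table(file)
  stopifnot(all(c("name", "valid_name", "uncertain_flag") %in% names(df)))
  unc <- df$uncertain_flag %in% c("1", "TRUE", "true", "yes")
  canon <- stats::setNames(df$valid_name[!unc], df$name[!unc])
  synonymy_table(canonical = canon,
                 uncertain_pairs = cbind(df$name[unc], df$valid_name[unc]))
}

#' @export
write_synonymy_table <- function(synonymy, file) {
  canon <- synonymy$canonical
  up <- synonymy$uncertain_pairs
  df <- data.frame(name = c(names(canon), up[, 1]),
                   valid_name = c(unname(canon), up[, 2]),
                   uncertain_flag = c(rep("0", length(canon)),
                                      rep("1", nrow(up))),
                   stringsAsFactors = FALSE)
  write_tsv_table(df, file)
}

#' Resolve names to their valid form
#'
#' Idempotent: resolving an already-valid name is a no-op.
#'
#' @param synonymy a `synonymy_table`.
#' @param names character vector of names.
#' @return character vector of valid names.
#' @export
canonical_name <- function(synonymy, names) {
  stopifnot(inherits(synonymy, "synonymy_table"))
  hit <- match(names, names(synonymy$canonical))
  out <- names
  out[!is.na(hit)] <- unname(synonymy$canonical[hit[!is.na(hit)]])
  out
}

#' Is a name pair flagged as unresolved taxonomy?
#'
#' @param synonymy a `synonymy_table`.
#' @param a,b names (unordered pair).
#' @return logical.
#' @export
is_uncertain_pair <- function(synonymy, a, b) {
  up <- synonymy$uncertain_pairs
  if (length(up) == 0L || nrow(up) == 0L) return(FALSE)
  any((up[, 1] == a & up[, 2] == b) | (up[, 1] == b & up[, 2] == a))
}

## ------------------------------------------------------------------
## Audit report

AUDIT_REPORT_COLS <- c("query_id", "morphology_label", "majority_id",
                       "other_ids_with_similarity", "final_id", "final_rank",
                       "confidence_pct", "categories", "geographic_correction")

format_conflicts <- function(names, sims) {
  if (length(names) == 0L) return("")
  paste(sprintf("%s (%.2f)", names, sims), collapse = "; ")
}

parse_conflicts <- function(s) {
  if (is.na(s) || s == "")
    return(data.frame(name = character(0), similarity = numeric(0)))
  parts <- strsplit(s, "; ", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.*) \\(([0-9.]+)\\)$", parts))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("cannot parse conflict entry: ", parts[bad][1])
  data.frame(name = vapply(m, `[[`, "", 2),
             similarity = as.numeric(vapply(m, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Write the audit report
#'
#' Tab-separated, deterministic column order; similarities printed with
#' exactly two decimals; categories joined by ';' in their fixed order.
#'
#' @param rows audit report `data.frame` (as produced by [audit_report()]
#'   or read back by [read_audit_report()]).
#' @param file output path.
#' @export
write_audit_report <- function(rows, file) {
  extra <- setdiff(names(rows), AUDIT_REPORT_COLS)
  df <- rows[, c(AUDIT_REPORT_COLS, extra), drop = FALSE]
  df$confidence_pct <- ifelse(is.na(rows$confidence_pct), "",
                              format(rows$confidence_pct, trim = TRUE))
  write_tsv_table(df, file)
}

#' Read an audit report
#'
#' @param file path to a report written by [write_audit_report()] (extra
#'   columns such as a cluster id are preserved).
#' @return a `data.frame` with `confidence_pct` numeric.
#' @export
read_audit_report <- function(file) {
  df <- read_tsv_table(file)
  missing <- setdiff(AUDIT_REPORT_COLS, names(df))
  if (length(missing))
    stop("report lacks columns: ", paste(missing, collapse = ", "))
  df$confidence_pct <- suppressWarnings(as.numeric(df$confidence_pct))
  df
}
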