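## Internal helpers shared across modules.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

## Rounding half away from zero (print convention for similarities and
## confidences; base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Encode sequences as an n x L integer matrix: A=1, C=2, G=3, T=4,
## anything else (ambiguity codes, gaps) = 0. Sites coded 0 are excluded
## from every pairwise comparison (pairwise deletion).
encode_sequences <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences to encode")
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences must be of equal length (aligned barcode region); got lengths ",
         paste(sort(unique(nchar(seqs))), collapse = ", "))
  m <- matrix(0L, nrow = length(seqs), ncol = L)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    code <- match(ch, c("A", "C", "G", "T"))
    code[is.na(code)] <- 0L
    m[i, ] <- code
  }
  rownames(m) <- names(seqs)
  m
}

decode_sequence <- function(code) {
  paste(c("A", "C", "G", "T")[code], collapse = "")
}

## Validate one uppercase sequence; returns position of first illegal
## character or 0L when clean.
first_illegal_char <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% IUPAC_CODES))
  if (length(bad)) bad[1L] else 0L
}

genus_of <- function(binomial) {
  vapply(strsplit(binomial, " ", fixed = TRUE),
         function(x) x[[1L]], character(1))
}

## Indeterminate labels ("Genus sp.") are not species names: they never
## enter conflict sets used for geographic correction.
is_indeterminate_name <- function(name) {
  grepl("(^|\\s)sp\\.?$", name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
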