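## Pairwise distances on aligned barcodes: p-distance, percent similarity
## and the Kimura 2-parameter correction, with pairwise deletion of sites
## carrying a gap or ambiguity code in either sequence. Ambiguity codes
## never count as matches or mismatches, even when compatible.

#' Compare two aligned sequences site by site
#'
#' Counts alignment positions where both sequences carry an unambiguous
#' A/C/G/T, and splits the differences into transitions (A<->G, C<->T) and
#' transversions (everything else).
#'
#' @param seq_a,seq_b equal-length uppercase sequences.
#' @return an object of class `pairwise_comparison` with fields
#'   `sites_compared`, `transitions`, `transversions`, `P` and `Q`
#'   (transition and transversion proportions).
#' @export
compare_pair <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences differ in length (", nchar(seq_a), " vs ", nchar(seq_b),
         "); inputs must come from the aligned barcode region")
  m <- encode_sequences(c(seq_a, seq_b))
  a <- m[1, ]; b <- m[2, ]
  ok <- a > 0L & b > 0L
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  ## coding A=1 C=2 G=3 T=4: transitions pair {1,3} and {2,4}
  diff <- a != b
  ts <- sum(diff & ((a + b == 4L & abs(a - b) == 2L) | (a + b == 6L & abs(a - b) == 2L)))
  tv <- sum(diff) - ts
  structure(list(sites_compared = n, transitions = ts, transversions = tv,
                 P = ts / n, Q = tv / n),
            class = "pairwise_comparison")
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, in substitutions per site.
#' Saturated comparisons (non-positive log argument) yield `NA`.
#'
#' @param cmp a `pairwise_comparison`, or a numeric `P` when `Q` is given.
#' @param Q transversion proportion (when `cmp` is numeric `P`).
#' @return non-negative numeric distance; `NA` when saturated.
#' @export
k2p_distance <- function(cmp, Q = NULL) {
  if (inherits(cmp, "pairwise_comparison")) {
    P <- cmp$P; Q <- cmp$Q
  } else {
    P <- cmp
    if (is.null(Q)) stop("Q required when P is given as a number")
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- P
  d[] <- NA_real_
  valid <- !is.na(w1) & w1 > 0 & w2 > 0
  d[valid] <- -0.5 * log(w1[valid]) - 0.25 * log(w2[valid])
  ## guard tiny negative round-off at P = Q = 0
  d[!is.na(d) & d < 0 & d > -1e-12] <- 0
  d
}

#' Percent similarity (BOLD-style percent identity)
#'
#' `100 * (1 - (transitions + transversions) / sites_compared)`, reported to
#' two decimals, rounding half away from zero.
#'
#' @param cmp a `pairwise_comparison`.
#' @return similarity percentage in `[0, 100]`.
#' @export
similarity_percent <- function(cmp) {
  stopifnot(inherits(cmp, "pairwise_comparison"))
  round_half_away(100 * (1 - (cmp$transitions + cmp$transversions) /
                           cmp$sites_compared), 2)
}

## ------------------------------------------------------------------
## Whole-matrix computation, vectorized through indicator cross-products:
## for base b let X_b be the n x L indicator of "unambiguous b"; then
## sites_compared = V V', matches = sum_b X_b X_b', transitions =
## X_A X_G' + X_G X_A' + X_C X_T' + X_T X_C'.

pairwise_counts <- function(code) {
  X <- lapply(1:4, function(b) (code == b) * 1)
  V <- X[[1]] + X[[2]] + X[[3]] + X[[4]]
  S <- tcrossprod(V)
  match_ct <- tcrossprod(X[[1]]) + tcrossprod(X[[2]]) +
    tcrossprod(X[[3]]) + tcrossprod(X[[4]])
  ts_half <- X[[1]] %*% t(X[[3]]) + X[[2]] %*% t(X[[4]])
  TS <- ts_half + t(ts_half)
  DIFF <- S - match_ct
  list(sites = S, transitions = TS, transversions = DIFF - TS, diffs = DIFF)
}

#' Pairwise distance matrix for a set of records
#'
#' @param records barcode record `data.frame` (or a named character vector of
#'   equal-length sequences).
#' @param metric `"k2p"` or `"p"`.
#' @return a symmetric numeric matrix with zero diagonal, dimnames set to the
#'   record ids in input order, attribute `metric`, and `NA` entries where the
#'   K2P correction is saturated (attribute `saturated` gives the id pairs).
#' @export
distance_matrix <- function(records, metric = c("k2p", "p")) {
  metric <- match.arg(metric)
  if (is.data.frame(records)) {
    seqs <- stats::setNames(records$sequence, records$record_id)
  } else {
    seqs <- records
  }
  if (length(seqs) < 2L) stop("need at least 2 records")
  code <- encode_sequences(seqs)
  ct <- pairwise_counts(code)
  if (any(ct$sites[upper.tri(ct$sites)] == 0))
    stop("no comparable sites for at least one pair")
  P <- ct$transitions / ct$sites
  Q <- ct$transversions / ct$sites
  d <- if (metric == "p") P + Q else k2p_distance(P, Q)
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  sat <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  attr(d, "metric") <- metric
  attr(d, "saturated") <- if (nrow(sat))
    cbind(names(seqs)[sat[, 1]], names(seqs)[sat[, 2]])
  else matrix(character(0), ncol = 2)
  d
}

## Similarity (%) of one encoded query row against every row of an encoded
## reference matrix; unrounded. Used by the search engine.
similarity_to_all <- function(q_code, ref_code) {
  okq <- q_code > 0L
  Vr <- ref_code > 0L
  S <- as.vector(Vr %*% okq)
  eq <- sweep(ref_code, 2, q_code, "==") & Vr & rep(okq, each = nrow(ref_code))
  matches <- rowSums(eq)
  ifelse(S > 0, 100 * (1 - (S - matches) / S), NA_real_)
}
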