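## Neighbor joining (Saitou-Nei Q-criterion) with deterministic tie-breaking
## and non-negative branch lengths. Implemented here rather than delegated so
## that ties on the Q matrix are broken by the lowest (row, column) index pair
## and negative branch estimates are clamped to zero with the excess moved to
## the sister branch; ape::nj is used as an independent cross-check in the
## test suite.

#' Neighbor-joining identification tree
#'
#' Builds the standard NJ tree from a distance matrix. On an additive matrix
#' the pairwise path lengths of the result reproduce the input exactly. The
#' tree is returned unrooted, as an `ape` `phylo` object with a deterministic
#' trifurcating root.
#'
#' @param d symmetric distance matrix with dimnames (see [distance_matrix()]).
#' @return a `phylo` object with branch lengths.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (anyNA(d)) {
    sat <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    labs <- rownames(d) %||% as.character(seq_len(n))
    stop("saturated distance for pair(s): ",
         paste(sprintf("%s/%s", labs[sat[, 1]], labs[sat[, 2]]),
               collapse = ", "))
  }
  tips <- rownames(d) %||% as.character(seq_len(n))

  ## active nodes carry provisional ids: 1..n tips, then n+1, n+2, ...
  active <- seq_len(n)
  D <- unname(d)
  next_internal <- n + 1L
  edges <- matrix(0L, nrow = 0, ncol = 2)
  lens <- numeric(0)

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Qm <- (m - 2) * D - outer(r, r, "+")
    Qm[lower.tri(Qm, diag = TRUE)] <- Inf
    qmin <- min(Qm)
    cand <- which(Qm == qmin, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]

    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bi <- 0; bj <- D[i, j] }
    if (bj < 0) { bj <- 0; bi <- D[i, j] }

    u <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lens <- c(lens, bi, bj)

    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    active <- c(active[keep], u)
  }

  ## final three-point resolution at a trifurcating root
  x <- 1L; y <- 2L; z <- 3L
  bx <- max(0, (D[x, y] + D[x, z] - D[y, z]) / 2)
  by <- max(0, (D[x, y] + D[y, z] - D[x, z]) / 2)
  bz <- max(0, (D[x, z] + D[y, z] - D[x, y]) / 2)
  root <- next_internal
  edges <- rbind(edges, c(root, active[x]), c(root, active[y]), c(root, active[z]))
  lens <- c(lens, bx, by, bz)

  ## renumber internals to the phylo convention: root = n + 1, the rest
  ## descending from creation order so every id in n+1 .. n+Nnode is used
  n_int <- root - n
  remap <- function(id) {
    ifelse(id <= n, id, n + 1L + (root - id))
  }
  edge <- cbind(remap(edges[, 1]), remap(edges[, 2]))
  tr <- structure(list(edge = edge, edge.length = lens,
                       tip.label = tips, Nnode = n_int),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}
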