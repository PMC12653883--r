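## Fixed-format Newick serialization: rooted notation, branch lengths always
## printed with six decimals, no internal labels, trailing semicolon. A
## single-leaf tree serializes as "(label:length);".

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object with branch lengths (multifurcations allowed),
#'   or a one-row degenerate tree for a single labeled leaf.
#' @param file optional path; when given, the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("unlabeled leaf")
  n <- length(tree$tip.label)
  fmt <- function(x) sprintf("%.6f", x)

  if (n == 1L) {
    len <- if (nrow(tree$edge) >= 1L) tree$edge.length[1] else 0
    s <- sprintf("(%s:%s);", tree$tip.label[1], fmt(len))
  } else {
    kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    root <- n + 1L
    render <- function(node) {
      idx <- kids[[as.character(node)]]
      parts <- vapply(idx, function(e) {
        child <- tree$edge[e, 2]
        sub <- if (child <= n) tree$tip.label[child] else render(child)
        paste0(sub, ":", fmt(tree$edge.length[e]))
      }, character(1))
      paste0("(", paste(parts, collapse = ","), ")")
    }
    s <- paste0(render(root), ";")
  }
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' A degenerate single-leaf tree
#'
#' Convenience constructor so that one-record datasets can still be
#' serialized with [write_newick()].
#'
#' @param label leaf label.
#' @param length branch length (default 0).
#' @return a minimal `phylo`-classed object with one tip.
#' @export
single_leaf_tree <- function(label, length = 0) {
  structure(list(edge = matrix(c(2L, 1L), nrow = 1),
                 edge.length = length, tip.label = label, Nnode = 1L),
            class = "phylo")
}
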