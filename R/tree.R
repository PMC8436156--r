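#' Parse a newick tree with branch lengths
#'
#' Thin wrapper around [ape::read.tree()] that enforces the requirements of
#' the downstream relatedness computation: a rooted tree, uniquely labelled
#' leaves, and a non-negative branch length on every edge (no defaulting of
#' missing lengths).
#'
#' @param text A newick string. Ignored when `file` is given.
#' @param file Path to a newick file.
#' @return An object of class `phylo` (see [ape::read.tree()]).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tree_heights(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) {
    ape::read.tree(file = file)
  } else {
    if (!is.character(text) || length(text) != 1L) {
      abort("`text` must be a single newick string.")
    }
    tryCatch(
      ape::read.tree(text = text),
      error = function(e) abort(paste0("malformed newick: ", conditionMessage(e)))
    )
  }
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort("malformed newick: could not parse a tree from the input")
  }
  validate_phylo(tr)
  tr
}

validate_phylo <- function(tr) {
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    abort("tree has edges without branch lengths; every edge must carry a length")
  }
  if (any(tr$edge.length < 0)) {
    abort("tree has negative branch lengths")
  }
  tr$tip.label <- trimws(tr$tip.label)
  if (anyDuplicated(tr$tip.label)) {
    dups <- unique(tr$tip.label[duplicated(tr$tip.label)])
    abort(paste0("duplicate taxon labels: ", paste(dups, collapse = ", ")))
  }
  invisible(tr)
}

#' Root-to-tip heights of a tree
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Named numeric vector of root-to-tip path lengths, one per leaf.
#' @export
tree_heights <- function(tree) {
  validate_phylo(tree)
  depths <- ape::node.depth.edgelength(tree)
  setNames(depths[seq_along(tree$tip.label)], trimws(tree$tip.label))
}

#' Scale a tree to unit height, optionally equalising tip heights
#'
#' The Brownian-motion relatedness matrix used by [pmm_fit()] is conventionally
#' built on an ultrametric tree of height 1, so that the diagonal of the
#' relatedness matrix is 1 and variance components are expressed in trait
#' units. This function rescales branch lengths so every root-to-tip path has
#' length 1. Trees whose tip heights differ by more than `tolerance`
#' (relative to the maximum height) are rejected unless `extend_tips = TRUE`,
#' in which case each terminal branch is lengthened to reach the maximum
#' height before rescaling. Silent coercion of strongly non-ultrametric trees
#' hides data problems, hence the explicit opt-in.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param tolerance Maximum allowed relative spread of root-to-tip heights
#'   when `extend_tips = FALSE`.
#' @param extend_tips Extend terminal branches to the maximum height instead
#'   of rejecting non-ultrametric input.
#' @return A `phylo` object with all root-to-tip heights equal to 1.
#' @examples
#' tr <- make_ultrametric(parse_newick("((A:1,B:1):1,C:2);"))
#' tree_heights(tr)
#' @export
make_ultrametric <- function(tree, tolerance = 1e-6, extend_tips = FALSE) {
  validate_phylo(tree)
  h <- tree_heights(tree)
  H <- max(h)
  if (H <= 0) abort("tree has zero height")
  dev <- (H - h) / H
  if (!extend_tips && any(dev > tolerance)) {
    bad <- names(h)[dev > tolerance]
    abort(paste0(
      "tree is not ultrametric within tolerance ", format(tolerance),
      "; offending taxa: ", paste(bad, collapse = ", "),
      ". Use extend_tips = TRUE to lengthen terminal branches."
    ))
  }
  # equalise exactly: lengthen each terminal edge to the max height
  tip_edges <- match(seq_along(tree$tip.label), tree$edge[, 2])
  add <- H - h
  new_len <- tree$edge.length[tip_edges] + add
  if (any(new_len < 0)) abort("terminal branch adjustment produced a negative length")
  tree$edge.length[tip_edges] <- new_len
  tree$edge.length <- tree$edge.length / H
  tree
}

#' Phylogenetic relatedness matrix
#'
#' Builds the between-species covariance kernel of a Brownian motion on the
#' tree: entry `(i, j)` is the root-to-MRCA shared path length of taxa `i`
#' and `j`, and the diagonal holds the root-to-tip heights (all 1 on a
#' unit-height ultrametric tree). The matrix is symmetric positive
#' semi-definite by construction.
#'
#' @param tree A `phylo` object, normally unit-height ultrametric (see
#'   [make_ultrametric()]).
#' @return A symmetric numeric matrix with taxa as dimnames and a logical
#'   attribute `unit_height`.
#' @examples
#' A <- relatedness_matrix(make_ultrametric(parse_newick("((A:1,B:1):1,C:2);")))
#' A["A", "B"]
#' @export
relatedness_matrix <- function(tree) {
  validate_phylo(tree)
  taxa <- trimws(tree$tip.label)
  n <- length(taxa)
  depths <- ape::node.depth.edgelength(tree)
  A <- matrix(0, n, n, dimnames = list(taxa, taxa))
  if (n == 1L) {
    A[1, 1] <- depths[1]
  } else {
    mrca_nodes <- ape::mrca(tree)
    A[] <- depths[mrca_nodes]
    diag(A) <- depths[seq_len(n)]
  }
  attr(A, "unit_height") <- all(abs(diag(A) - 1) < 1e-8)
  A
}

#' Write a relatedness matrix as CSV with taxa on both margins
#'
#' @param A Matrix from [relatedness_matrix()].
#' @param path Output file path.
#' @export
write_relatedness_csv <- function(A, path) {
  df <- tibble::as_tibble(A, rownames = "taxon")
  readr::write_csv(df, path)
  invisible(path)
}
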