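#' Rooted tree container used throughout cladetrim
#'
#' A `ttree` stores a rooted, possibly multifurcating topology in flat,
#' preorder-indexed vectors (node 1 is the root; every child has a larger
#' index than its parent). Leaves carry a mandatory name; internal nodes may
#' carry either a statistical support value or a plain-text name, and any
#' node but the root may carry a non-negative branch length in
#' substitutions/site.
#'
#' @details Fields:
#' \describe{
#'   \item{parent}{integer; `NA` for the root.}
#'   \item{children}{list of integer vectors; empty for leaves.}
#'   \item{label}{character; leaf name, or internal node name, else `NA`.}
#'   \item{length}{numeric branch length; `NA` when absent. Absent lengths
#'     are treated as 0 by all path-length computations.}
#'   \item{support}{numeric; internal nodes only, `NA` when absent.}
#'   \item{is_leaf}{logical.}
#'   \item{leaf_order}{leaf names in serialization (preorder) order.}
#' }
#'
#' @param nested a nested list of nodes, each
#'   `list(children = list(...), label =, length =, support =)`.
#' @return a `ttree` object.
#' @export
build_ttree <- function(nested) {
  acc <- new.env(parent = emptyenv())
  acc$parent <- integer(0)
  acc$children <- list()
  acc$label <- character(0)
  acc$length <- numeric(0)
  acc$support <- numeric(0)
  acc$is_leaf <- logical(0)

  visit <- function(node, parent_idx) {
    idx <- length(acc$parent) + 1L
    acc$parent[idx] <- parent_idx
    acc$children[[idx]] <- integer(0)
    acc$label[idx] <- if (is.null(node$label)) NA_character_ else node$label
    acc$length[idx] <- if (is.null(node$length)) NA_real_ else node$length
    acc$support[idx] <- if (is.null(node$support)) NA_real_ else node$support
    kids <- node$children
    acc$is_leaf[idx] <- is.null(kids) || length(kids) == 0L
    if (!acc$is_leaf[idx]) {
      for (k in kids) acc$children[[idx]] <- c(acc$children[[idx]], visit(k, idx))
    }
    idx
  }
  visit(nested, NA_integer_)

  tree <- structure(
    list(parent = acc$parent, children = acc$children, label = acc$label,
         length = acc$length, support = acc$support, is_leaf = acc$is_leaf,
         leaf_order = acc$label[acc$is_leaf]),
    class = "ttree")
  validate_ttree(tree)
}

validate_ttree <- function(tree) {
  leaves <- tree$leaf_order
  if (length(leaves) < 2L)
    ct_stop(sprintf("a tree needs at least 2 leaves, got %d", length(leaves)))
  if (anyNA(leaves) || any(!nzchar(leaves)))
    ct_stop("every leaf must have a non-empty name")
  if (anyDuplicated(leaves)) {
    dup <- leaves[duplicated(leaves)][1]
    ct_stop(sprintf("duplicate leaf name: '%s'", dup))
  }
  bl <- tree$length[!is.na(tree$length)]
  if (any(bl < 0))
    ct_stop("negative branch length encountered")
  if (any(!is.na(tree$support[tree$is_leaf])))
    ct_stop("support value attached to a leaf")
  tree
}

#' @export
print.ttree <- function(x, ...) {
  cat(sprintf("<ttree: %d leaves, %d internal nodes, %s branch lengths, %s supports>\n",
              sum(x$is_leaf), sum(!x$is_leaf),
              if (all(is.na(x$length[-1]))) "no" else "with",
              if (all(is.na(x$support))) "no" else "with"))
  invisible(x)
}

#' Leaf names of a tree in serialization order
#' @param tree a `ttree`.
#' @return character vector.
#' @export
tree_leaves <- function(tree) tree$leaf_order

n_leaves <- function(tree) sum(tree$is_leaf)

internal_nodes <- function(tree) which(!tree$is_leaf)

# Node indices of all leaves under `node`, in preorder (= leaf_order) order.
descendant_leaf_idx <- function(tree, node) {
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (tree$is_leaf[v]) out <- c(out, v)
    else stack <- c(tree$children[[v]], stack)
  }
  out
}

#' Leaf names under a node
#' @param tree a `ttree`.
#' @param node internal or leaf node index.
#' @return character vector of leaf names in leaf_order.
#' @export
clade_leaves <- function(tree, node) {
  tree$label[descendant_leaf_idx(tree, node)]
}

# Flat -> nested conversion (used by restriction and serialization).
as_nested <- function(tree, node = 1L) {
  n <- list(label = tree$label[node],
            length = tree$length[node],
            support = tree$support[node])
  if (!tree$is_leaf[node])
    n$children <- lapply(tree$children[[node]], function(k) as_nested(tree, k))
  n
}
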