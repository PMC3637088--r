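#' Induced subtree on a subset of leaves
#'
#' Restricts a tree to the topology induced by `keep`: pruned leaves are
#' removed, internal nodes left with a single child are suppressed (the
#' child is spliced to its grandparent and keeps its own support/name), and
#' all branch lengths are dropped, so the result is a cladogram. Supports
#' and names of surviving internal nodes are preserved, as is the relative
#' order of surviving leaves. The relative resolution of every retained
#' leaf triple is unchanged.
#'
#' @param tree a `ttree`.
#' @param keep character vector of leaf names to retain; at least 2,
#'   all present in the tree.
#' @return a `ttree` cladogram whose leaf set equals `keep`.
#' @examples
#' tr <- parse_newick("((A,B)0.9,(C,D)0.8);")
#' write_newick(restrict_to_leaves(tr, c("A", "C", "D")))
#' @export
restrict_to_leaves <- function(tree, keep) {
  keep <- unique(keep)
  unknown <- setdiff(keep, tree$leaf_order)
  if (length(unknown))
    ct_stop(sprintf("unknown leaf name(s) in keep: %s",
                    paste(unknown, collapse = ", ")))
  if (length(keep) < 2L)
    ct_stop("need at least 2 leaves to keep")

  prune <- function(node) {
    n <- as_nested_shallow(tree, node)
    if (tree$is_leaf[node]) {
      if (tree$label[node] %in% keep) return(n) else return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(tree$children[[node]], prune))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])  # unary suppression
    n$children <- kids
    n
  }
  root <- prune(1L)
  root$length <- NULL
  build_ttree(root)
}

# One node without recursing into children; lengths dropped by design.
as_nested_shallow <- function(tree, node) {
  n <- list()
  if (!is.na(tree$label[node])) n$label <- tree$label[node]
  if (!is.na(tree$support[node])) n$support <- tree$support[node]
  n
}
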