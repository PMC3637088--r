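#' Internal nodes meeting the support threshold
#'
#' Returns every internal node (root included) whose support value is
#' greater than or equal to `threshold`, in preorder. With `threshold == 0`
#' every internal node is returned, whether or not it carries a support
#' value; with any positive threshold, nodes lacking a support value are
#' excluded.
#'
#' @param tree a `ttree`.
#' @param threshold support threshold, `>= 0`, same scale as the tree.
#' @return integer vector of node indices.
#' @export
supported_nodes <- function(tree, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    ct_stop("threshold must be a single number >= 0")
  ints <- internal_nodes(tree)
  if (threshold == 0) return(ints)
  ints[!is.na(tree$support[ints]) & tree$support[ints] >= threshold]
}

#' Supported clades whose leaves unanimously match one dereplication rule
#'
#' One candidate per supported node whose full leaf set gets a non-absent
#' [matching_rule()]. Multifurcating nodes are treated exactly like
#' bifurcating ones, and the root counts as a clade.
#'
#' @param tree a `ttree`.
#' @param map a [taxonomy_map()].
#' @param params a [trim_params()].
#' @return list of candidates, each
#'   `list(node, category, rule, leaves)`, ordered by the position of the
#'   clade's first leaf in the tree's leaf order (parents before children).
#' @export
candidate_clades <- function(tree, map, params) {
  out <- list()
  for (node in supported_nodes(tree, params$threshold)) {
    leaves <- clade_leaves(tree, node)
    rule <- matching_rule(params, map, leaves)
    if (!is.null(rule))
      out[[length(out) + 1L]] <-
        list(node = node, category = rule$category, rule = rule,
             leaves = leaves)
  }
  out
}

#' Reduce candidates to the maximal ("largest") clades
#'
#' Drops every candidate whose leaf set is strictly contained in that of
#' another candidate of the same category; candidates of different
#' categories never absorb one another. Because clade leaf sets in a rooted
#' tree are either nested or disjoint, the surviving clades of any one
#' category are pairwise leaf-disjoint. A taxonomic category scattered
#' across the tree in several supported clades therefore yields several
#' maximal clades, one per placement.
#'
#' @param candidates list from [candidate_clades()], all from one tree.
#' @param leaf_order the tree's leaf order (used only for output ordering);
#'   when `NULL`, the candidates' existing order is kept stable.
#' @return list of maximal candidates, ordered by first-leaf position.
#' @export
maximal_clades <- function(candidates, leaf_order = NULL) {
  n <- length(candidates)
  if (n == 0L) return(candidates)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    li <- candidates[[i]]$leaves
    for (j in seq_len(n)) {
      if (i == j || candidates[[j]]$category != candidates[[i]]$category) next
      lj <- candidates[[j]]$leaves
      if (length(li) < length(lj) && all(li %in% lj)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- candidates[keep]
  if (!is.null(leaf_order)) {
    first <- vapply(out, function(c) match(c$leaves[[1]], leaf_order), integer(1))
    out <- out[order(first)]
  }
  out
}
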