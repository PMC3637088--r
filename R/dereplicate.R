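#' Root-of-clade-to-leaf path lengths
#'
#' For each leaf under `clade_node`, the sum of branch lengths on the path
#' from the clade's basal node down to that leaf — exclusive of the clade
#' node's own subtending branch. Absent branch lengths contribute 0, so a
#' cladogram yields all-zero depths.
#'
#' @param tree a `ttree`.
#' @param clade_node node index.
#' @return named numeric vector, names in leaf order under the node.
#' @export
leaf_depths <- function(tree, clade_node) {
  depths <- numeric(0)
  walk <- function(node, acc) {
    if (node != clade_node) {
      bl <- tree$length[node]
      acc <- acc + if (is.na(bl)) 0 else bl
    }
    if (tree$is_leaf[node]) {
      depths[[tree$label[node]]] <<- acc
    } else {
      for (k in tree$children[[node]]) walk(k, acc)
    }
  }
  walk(clade_node, 0)
  depths
}

#' Median of clade depths
#'
#' Standard sample median: middle value for odd counts, arithmetic mean of
#' the two central values for even counts. The median (rather than the
#' mean) damps the influence of unusually long-branching OTUs.
#'
#' @param depths non-empty numeric vector (see [leaf_depths()]).
#' @return the median depth.
#' @export
median_depth <- function(depths) {
  if (length(depths) == 0L) ct_stop("cannot take the median of zero depths")
  s <- sort(unname(depths))
  n <- length(s)
  # explicit formula (not stats::median) so that representative selection,
  # whose ties hinge on |depth - median| at machine precision, is bit-for-bit
  # reproducible across implementations of the same definition
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

#' Pick the representative leaves of a clade
#'
#' Ranks leaves by closeness of their depth to the clade median and keeps
#' the best `retain`; ties in `|depth - median|` are broken by earlier
#' position in `leaf_order`, making selection fully deterministic. When the
#' clade has at most `retain` leaves, all are kept.
#'
#' @param depths named numeric vector from [leaf_depths()].
#' @param leaf_order the tree's leaf order.
#' @param retain number of representatives, `>= 1`.
#' @return retained leaf names, in `leaf_order`.
#' @export
select_representatives <- function(depths, leaf_order, retain) {
  retain <- as.integer(retain)
  if (is.na(retain) || retain < 1L) ct_stop("retain must be >= 1")
  if (length(depths) <= retain)
    return(names(depths)[order(match(names(depths), leaf_order))])
  m <- median_depth(depths)
  pos <- match(names(depths), leaf_order)
  ord <- order(abs(depths - m), pos)
  sel <- names(depths)[ord[seq_len(retain)]]
  sel[order(match(sel, leaf_order))]
}

#' Dereplicate a tree
#'
#' The full procedure: find the supported clades, keep those whose OTUs
#' unanimously belong to one taxonomic category, reduce to the maximal
#' clades, and within each, retain the rule's number of representatives
#' closest to the clade's median root-to-leaf path length. Clades already
#' at or below their retain count are reported with zero removals. OTUs
#' outside every maximal clade — including all unmapped OTUs — are always
#' retained.
#'
#' When maximal clades of two different categories are nested (an inner
#' clade matching a deeper-rank rule inside an outer clade matching a
#' shallower one), the most inclusive clade governs and the contained one
#' is not processed separately.
#'
#' @param tree a `ttree`.
#' @param map a [taxonomy_map()].
#' @param params a [trim_params()].
#' @return a `trim_result`: `list(retained_otus, records, params)`, where
#'   each record is `list(category, rank, clade_leaves, retained,
#'   removed_count, median, support)`.
#' @export
dereplicate <- function(tree, map, params) {
  clades <- maximal_clades(candidate_clades(tree, map, params),
                           leaf_order = tree$leaf_order)
  # cross-category nesting: most inclusive clade wins
  n <- length(clades)
  if (n > 1L) {
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      li <- clades[[i]]$leaves
      for (j in seq_len(n)) {
        if (i == j) next
        lj <- clades[[j]]$leaves
        if (length(li) < length(lj) && all(li %in% lj)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    clades <- clades[keep]
  }

  records <- lapply(clades, function(cl) {
    depths <- leaf_depths(tree, cl$node)
    retained <- select_representatives(depths, tree$leaf_order, cl$rule$retain)
    list(category = cl$category,
         rank = cl$rule$rank,
         clade_leaves = cl$leaves,
         retained = retained,
         removed_count = length(cl$leaves) - length(retained),
         median = median_depth(depths),
         support = tree$support[cl$node])
  })
  removed <- unlist(lapply(records, function(r) setdiff(r$clade_leaves, r$retained)))
  structure(list(retained_otus = setdiff(tree$leaf_order, removed),
                 records = records,
                 params = params),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  total_in <- length(x$retained_otus) +
    sum(vapply(x$records, `[[`, integer(1), "removed_count"))
  cat(sprintf("<trim_result: %d -> %d OTUs, %d clade record(s)>\n",
              total_in, length(x$retained_otus), length(x$records)))
  invisible(x)
}
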