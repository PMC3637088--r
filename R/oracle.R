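#' Brute-force reference dereplication
#'
#' An independent, straight-line reimplementation of [dereplicate()] for
#' cross-checking on small trees (at most 25 leaves): every internal node
#' is enumerated, support and taxonomic unanimity are tested by direct
#' iteration over rules and leaves, containment is filtered by pairwise
#' leaf-set comparison, and representatives are chosen by exhaustively
#' scoring every size-`retain` subset against the clade median. It shares
#' no code path with the main pipeline beyond the `ttree` container.
#'
#' @param tree a `ttree` with at most 25 leaves.
#' @param map a [taxonomy_map()].
#' @param params a [trim_params()].
#' @return a `trim_result` comparable with [dereplicate()]'s.
#' @export
brute_force_dereplicate <- function(tree, map, params) {
  if (sum(tree$is_leaf) > 25L)
    ct_stop("brute_force_dereplicate is guarded to trees with <= 25 leaves")

  # --- every internal node and its leaf set, by its own recursion ---
  gather <- function(node) {
    if (tree$is_leaf[node]) return(tree$label[node])
    res <- character(0)
    for (k in tree$children[[node]]) res <- c(res, gather(k))
    res
  }
  cands <- list()
  for (node in seq_along(tree$parent)) {
    if (tree$is_leaf[node]) next
    sup <- tree$support[node]
    if (params$threshold > 0 && (is.na(sup) || sup < params$threshold)) next
    leaves <- gather(node)
    # direct rule scan: deepest matching explicit rule, first declared on ties
    best <- NULL
    for (r in params$rules) {
      ok <- TRUE
      for (lf in leaves) {
        lin <- map[[lf]]
        if (is.null(lin) || length(lin) < r$rank || lin[[r$rank]] != r$category) {
          ok <- FALSE
          break
        }
      }
      if (ok && (is.null(best) || r$rank > best$rank)) best <- r
    }
    if (is.null(best) && !is.null(params$default_rule)) {
      d <- params$default_rule
      labs <- character(0)
      ok <- TRUE
      for (lf in leaves) {
        lin <- map[[lf]]
        if (is.null(lin) || length(lin) < d$rank) { ok <- FALSE; break }
        labs <- c(labs, lin[[d$rank]])
      }
      if (ok && length(unique(labs)) == 1L)
        best <- list(category = labs[[1]], rank = d$rank, retain = d$retain)
    }
    if (!is.null(best))
      cands[[length(cands) + 1L]] <-
        list(node = node, leaves = leaves, rule = best)
  }

  # --- pairwise containment: same category first, then any category ---
  drop_contained <- function(lst, same_category) {
    keep <- rep(TRUE, length(lst))
    for (i in seq_along(lst)) {
      for (j in seq_along(lst)) {
        if (i == j) next
        if (same_category &&
            lst[[i]]$rule$category != lst[[j]]$rule$category) next
        if (length(lst[[i]]$leaves) < length(lst[[j]]$leaves) &&
            all(lst[[i]]$leaves %in% lst[[j]]$leaves)) {
          keep[i] <- FALSE
        }
      }
    }
    lst[keep]
  }
  cands <- drop_contained(cands, same_category = TRUE)
  cands <- drop_contained(cands, same_category = FALSE)
  if (length(cands) > 1L) {
    first <- vapply(cands, function(c) match(c$leaves[[1]], tree$leaf_order),
                    integer(1))
    cands <- cands[order(first)]
  }

  # --- exhaustive representative selection ---
  lex_less <- function(a, b) {
    for (k in seq_along(a)) {
      if (a[k] < b[k]) return(TRUE)
      if (a[k] > b[k]) return(FALSE)
    }
    FALSE
  }
  records <- lapply(cands, function(cl) {
    # depth per leaf: walk parent pointers up to the clade node, then sum
    # the edges in root-to-leaf order
    depths <- vapply(cl$leaves, function(lf) {
      v <- which(tree$label == lf & tree$is_leaf)
      edges <- numeric(0)
      while (v != cl$node) {
        bl <- tree$length[v]
        edges <- c(edges, if (is.na(bl)) 0 else bl)
        v <- tree$parent[v]
      }
      # accumulate root-to-leaf in plain double steps (not sum(), whose
      # long-double pipeline rounds differently) so exact ties in
      # |depth - median| are ties for both implementations
      d <- 0
      for (e in rev(edges)) d <- d + e
      d
    }, numeric(1))
    s <- sort(unname(depths))
    n <- length(s)
    med <- if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
    k <- cl$rule$retain
    if (length(cl$leaves) <= k) {
      retained <- cl$leaves[order(match(cl$leaves, tree$leaf_order))]
    } else {
      subsets <- utils::combn(cl$leaves, k, simplify = FALSE)
      best <- NULL
      best_score <- NULL
      best_pos <- NULL
      for (sub in subsets) {
        score <- sort(abs(depths[sub] - med))
        pos <- sort(match(sub, tree$leaf_order))
        if (is.null(best) || lex_less(score, best_score) ||
            (!lex_less(best_score, score) && lex_less(pos, best_pos))) {
          best <- sub
          best_score <- score
          best_pos <- pos
        }
      }
      retained <- best[order(match(best, tree$leaf_order))]
    }
    list(category = cl$rule$category, rank = cl$rule$rank,
         clade_leaves = cl$leaves, retained = retained,
         removed_count = length(cl$leaves) - length(retained),
         median = med, support = tree$support[cl$node])
  })
  removed <- unlist(lapply(records, function(r) setdiff(r$clade_leaves, r$retained)))
  structure(list(retained_otus = setdiff(tree$leaf_order, removed),
                 records = records, params = params),
            class = "trim_result")
}
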