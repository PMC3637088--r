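# Synthetic data: random trees with planted, supported, taxonomically
# homogeneous clades plus matching taxonomy tables. Every other module is
# testable from these with no external downloads.

#' Describe a planted clade
#'
#' @param category category label; also the prefix of the clade's leaf
#'   names (`<category>_1`, `<category>_2`, ...).
#' @param n_leaves clade size, `>= 1` (a size-1 "clade" is just a leaf with
#'   the stated lineage).
#' @param support support value planted on the clade's basal node.
#' @param lineage ordered lineage shared by the clade's leaves; default
#'   `c("Root", category)`, i.e. the category sits at rank 2.
#' @return a plant description for [plant_spec()].
#' @export
planted_clade <- function(category, n_leaves, support,
                          lineage = c("Root", category)) {
  if (n_leaves < 1L) ct_stop("planted clade size must be >= 1")
  list(category = category, n_leaves = as.integer(n_leaves),
       support = support, lineage = lineage)
}

#' Specify a synthetic tree
#'
#' The generated world: `n_background` leaves with distinct singleton
#' lineages (so no rule can ever unite two of them), plus the planted
#' clades, joined into a random rooted bifurcating topology by repeated
#' random coalescence. Branch lengths are i.i.d. exponential with mean
#' `bl_mean` (default 0.1 substitutions/site, a typical protein-tree
#' scale); supports of non-planted internal nodes are drawn from
#' `support_noise` (default uniform on [0, 1)).
#'
#' @param n_background number of background leaves, `>= 0`.
#' @param clades list of [planted_clade()]s.
#' @param bl_mean mean of the exponential branch-length model, `> 0`.
#' @param support_noise function `n -> numeric(n)` for non-planted supports.
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return a `plant_spec`.
#' @export
plant_spec <- function(n_background, clades = list(), bl_mean = 0.1,
                       support_noise = function(n) stats::runif(n),
                       seed = 1L) {
  if (bl_mean <= 0) ct_stop("bl_mean must be > 0")
  total <- n_background + sum(vapply(clades, `[[`, integer(1), "n_leaves"))
  if (total < 2L) ct_stop("spec must yield at least 2 leaves")
  cats <- vapply(clades, `[[`, character(1), "category")
  if (anyDuplicated(cats))
    ct_stop("planted clade categories must be distinct")
  structure(list(n_background = as.integer(n_background), clades = clades,
                 bl_mean = bl_mean, support_noise = support_noise,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

# Random rooted bifurcating topology over a pool of nested subtrees:
# repeatedly join two uniformly chosen members until one remains.
coalesce_pool <- function(pool) {
  while (length(pool) > 1L) {
    ij <- sample.int(length(pool), 2L)
    joined <- list(children = list(pool[[ij[1]]], pool[[ij[2]]]),
                   .internal = TRUE)
    pool <- c(pool[-ij], list(joined))
  }
  pool[[1L]]
}

#' Generate a random tree with planted clades
#'
#' Fully reproducible from `spec$seed` (the caller's RNG state is left
#' untouched): the same spec always serializes to the identical Newick
#' string and taxonomy table. Each planted clade is attached as one
#' monophyletic unit whose basal node carries the stated support, so its
#' leaf set is ground truth for clade detection.
#'
#' @param spec a [plant_spec()].
#' @return `list(tree, taxonomy, expected)`, where `expected` is a list of
#'   `list(category, leaves)`, one per planted clade.
#' @export
generate_tree <- function(spec) {
  with_local_seed(spec$seed, {
    entries <- list()
    expected <- list()
    pool <- list()

    for (cl in spec$clades) {
      leaves <- sprintf("%s_%d", cl$category, seq_len(cl$n_leaves))
      for (nm in leaves) entries[[nm]] <- cl$lineage
      expected[[length(expected) + 1L]] <-
        list(category = cl$category, leaves = leaves)
      if (cl$n_leaves == 1L) {
        sub <- list(label = leaves)
      } else {
        sub <- coalesce_pool(lapply(leaves, function(nm) list(label = nm)))
        sub$.planted_support <- cl$support
      }
      pool <- c(pool, list(sub))
    }
    if (spec$n_background > 0L) {
      bg <- sprintf("bg%d_sp", seq_len(spec$n_background))
      for (i in seq_along(bg)) entries[[bg[i]]] <- sprintf("bgtax%d", i)
      pool <- c(pool, lapply(bg, function(nm) list(label = nm)))
    }
    root <- if (length(pool) == 1L) pool[[1L]] else coalesce_pool(pool)

    # second pass: branch lengths everywhere but the root, supports on
    # internal nodes (planted basal supports override the noise draw)
    decorate <- function(node, is_root) {
      if (!is_root) node$length <- stats::rexp(1L, rate = 1 / spec$bl_mean)
      if (!is.null(node$children)) {
        node$support <- if (!is.null(node$.planted_support))
          node$.planted_support else spec$support_noise(1L)
        node$.planted_support <- NULL
        node$.internal <- NULL
        node$children <- lapply(node$children, decorate, is_root = FALSE)
      }
      node
    }
    root <- decorate(root, is_root = TRUE)
    list(tree = build_ttree(root), taxonomy = taxonomy_map(entries),
         expected = expected)
  })
}
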