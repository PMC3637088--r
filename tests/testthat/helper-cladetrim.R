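# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no files ship with the package.

# Structural tree equality: preorder flattening is canonical, so field-wise
# comparison is exact (branch lengths to `tol`).
expect_same_tree <- function(a, b, tol = 1e-9) {
  expect_identical(a$parent, b$parent)
  expect_identical(a$children, b$children)
  expect_identical(a$label, b$label)
  expect_identical(a$is_leaf, b$is_leaf)
  expect_equal(a$support, b$support, tolerance = 1e-12)
  la <- ifelse(is.na(a$length), 0, a$length)
  lb <- ifelse(is.na(b$length), 0, b$length)
  expect_identical(is.na(a$length), is.na(b$length))
  expect_true(all(abs(la - lb) <= tol))
}

expect_same_result <- function(x, y) {
  expect_identical(x$retained_otus, y$retained_otus)
  expect_length(y$records, length(x$records))
  for (k in seq_along(x$records)) {
    rx <- x$records[[k]]
    ry <- y$records[[k]]
    expect_identical(rx$category, ry$category)
    expect_identical(as.integer(rx$rank), as.integer(ry$rank))
    expect_identical(rx$clade_leaves, ry$clade_leaves)
    expect_identical(rx$retained, ry$retained)
    expect_identical(as.integer(rx$removed_count), as.integer(ry$removed_count))
    expect_equal(rx$median, ry$median, tolerance = 1e-12)
    expect_identical(is.na(rx$support), is.na(ry$support))
    if (!is.na(rx$support)) expect_equal(rx$support, ry$support)
  }
}

same_result <- function(x, y) {
  isTRUE(tryCatch({ expect_same_result(x, y); TRUE },
                  expectation_failure = function(e) FALSE))
}

# Random problem instance: synthetic tree + taxonomy + a parameter set that
# exercises explicit rules, shared supergroups (deepest-rank precedence),
# default rules and varying thresholds. Always <= 25 leaves (oracle guard).
random_instance <- function(seed) {
  set.seed(seed)
  n_clades <- sample(1:3, 1)
  cats <- paste0("cat", seq_len(n_clades), letters[seed %% 26 + 1])
  shared_supergroup <- runif(1) < 0.3
  clades <- lapply(cats, function(cat) {
    lineage <- if (shared_supergroup) c("Root", "SG", cat) else c("Root", cat)
    planted_clade(cat, n_leaves = sample(1:5, 1),
                  support = round(runif(1, 0.5, 1), 3), lineage = lineage)
  })
  n_bg <- sample(0:8, 1)
  if (n_bg + sum(vapply(clades, `[[`, integer(1), "n_leaves")) < 2L) n_bg <- 2L
  g <- generate_tree(plant_spec(n_bg, clades, bl_mean = 0.1,
                                seed = sample.int(.Machine$integer.max, 1)))
  cat_rank <- if (shared_supergroup) 3L else 2L
  rules <- lapply(cats[runif(n_clades) < 0.9], function(cat)
    list(category = cat, rank = cat_rank, retain = sample(1:3, 1)))
  if (shared_supergroup && runif(1) < 0.7)
    rules <- c(rules, list(list(category = "SG", rank = 2L,
                                retain = sample(1:3, 1))))
  default_rule <- if (runif(1) < 0.3) list(rank = 1L, retain = sample(1:2, 1))
  params <- trim_params(sample(c(0, 0.7, 0.8, 0.9), 1), rules, default_rule)
  has_sg_rule <- any(vapply(rules, function(r) r$category == "SG", logical(1)))
  list(tree = g$tree, map = g$taxonomy, params = params,
       expected = g$expected,
       # TRUE when one OTU can fall under rules at two different ranks
       # (supergroup rule above the category rules, or a default rule):
       # the matched rule of a clade can then deepen after pruning, so the
       # idempotence/threshold-monotonicity properties only apply when FALSE
       layered = has_sg_rule || !is.null(default_rule))
}

# Rooted-triplet oracle: which pair of {a,b,c} is grouped, by brute-force
# scan of every clade leaf set ("none" when the triple is unresolved).
resolve_triplet <- function(tree, trip) {
  for (node in which(!tree$is_leaf)) {
    lv <- clade_leaves(tree, node)
    inside <- trip %in% lv
    if (sum(inside) == 2L) return(paste(sort(trip[inside]), collapse = "|"))
  }
  "none"
}

# Caterpillar Newick for a supported clade with all internal supports `s`.
supported_clade_nwk <- function(leaves, s) {
  out <- leaves[1]
  for (lf in leaves[-1]) out <- sprintf("(%s,%s)%s", out, lf, s)
  out
}
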