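test_that("leaf_depths sums paths from the basal node, exclusive of its own branch", {
  tr <- parse_newick("(((A:1,B:3):2,C:4)0.9:9,D:1);")
  clade <- which(!tr$is_leaf)[2]  # ((A,B),C); its own 9-long branch not counted
  expect_equal(leaf_depths(tr, clade), c(A = 3, B = 5, C = 4))
  # absent lengths contribute 0
  tr2 <- parse_newick("(((A,B),C)0.9,D);")
  expect_equal(leaf_depths(tr2, which(!tr2$is_leaf)[2]), c(A = 0, B = 0, C = 0))
})

test_that("leaf_depths equals an independent parent-pointer path walk", {
  for (seed in 1:60) {
    tree <- random_instance(seed)$tree
    for (node in which(!tree$is_leaf)) {
      got <- leaf_depths(tree, node)
      for (lf in names(got)) {
        v <- which(tree$label == lf & tree$is_leaf)
        d <- 0
        while (v != node) {
          if (!is.na(tree$length[v])) d <- d + tree$length[v]
          v <- tree$parent[v]
        }
        expect_equal(unname(got[lf]), d, tolerance = 1e-12)
      }
    }
  }
})

test_that("median_depth is the sample median, even counts averaged", {
  expect_equal(median_depth(c(A = 3, B = 5, C = 4)), 4)
  expect_equal(median_depth(c(A = 1, B = 3)), 2)
  expect_error(median_depth(numeric(0)), class = "cladetrim_validation_error")
  set.seed(11)
  for (i in 1:200) {
    x <- round(runif(sample(1:9, 1), 0, 5), 2)
    s <- sort(x)
    n <- length(s)
    ref <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(median_depth(x), ref, tolerance = 1e-15)
  }
})

test_that("select_representatives ranks by closeness to the median with stable ties", {
  lo <- c("A", "B", "C")
  expect_identical(select_representatives(c(A = 3, B = 5, C = 4), lo, 1), "C")
  expect_identical(select_representatives(c(A = 1, B = 1, C = 1), lo, 2),
                   c("A", "B"))
  # retain >= clade size keeps everything, in leaf order
  expect_identical(select_representatives(c(C = 1, A = 2), c("A", "B", "C"), 5),
                   c("A", "C"))
  expect_error(select_representatives(c(A = 1, B = 2), lo, 0),
               class = "cladetrim_validation_error")
})

test_that("select_representatives matches the exhaustive subset oracle", {
  lex_cmp <- function(a, b) {
    for (k in seq_along(a)) {
      if (a[k] < b[k]) return(-1L)
      if (a[k] > b[k]) return(1L)
    }
    0L
  }
  set.seed(99)
  for (i in 1:300) {
    n <- sample(2:9, 1)
    leaf_order <- paste0("L", sample(n))
    # quantized depths so exact ties happen often
    depths <- setNames(sample(0:6, n, replace = TRUE) / 4, sample(leaf_order))
    retain <- sample(1:min(4, n), 1)
    got <- select_representatives(depths, leaf_order, retain)
    if (n <= retain) {
      expect_identical(got, names(depths)[order(match(names(depths), leaf_order))])
      next
    }
    m <- stats::median(depths)
    best <- NULL
    for (sub in utils::combn(names(depths), retain, simplify = FALSE)) {
      score <- sort(abs(depths[sub] - m))
      pos <- sort(match(sub, leaf_order))
      if (is.null(best)) better <- TRUE
      else {
        cs <- lex_cmp(score, best$score)
        better <- cs == -1L || (cs == 0L && lex_cmp(pos, best$pos) == -1L)
      }
      if (better) best <- list(sub = sub, score = score, pos = pos)
    }
    expect_identical(sort(got), sort(best$sub))
    expect_identical(got, best$sub[order(match(best$sub, leaf_order))])
  }
})

test_that("dereplicate handles the printed edge cases", {
  # clade smaller than its retain count: untouched, zero-removal record
  map <- load_taxonomy(c("am1\tE;Amoebozoa", "t1\tE;Alveolata", "t2\tE;Alveolata"))
  tr <- parse_newick("((am1:1,(t1:1,t2:1)0.95:1)0.9:1,(t1b:1,t2b:1)0.99:1);")
  map2 <- taxonomy_map(c(unclass(map), list(t1b = c("E", "Alveolata"),
                                            t2b = c("E", "Alveolata"))))
  p <- trim_params(0.8, list(list(category = "Amoebozoa", rank = 2, retain = 2),
                             list(category = "Alveolata", rank = 2, retain = 2)))
  res <- dereplicate(tr, map2, p)
  expect_true("am1" %in% res$retained_otus)
  expect_identical(length(res$retained_otus), 5L)
  expect_true(all(vapply(res$records, `[[`, integer(1), "removed_count") == 0L))

  # no supported node at the threshold: nothing removed, zero records
  tr <- parse_newick("((v1:1,v2:1)0.5:1,(v3:1,v4:1)0.7:1);")
  mapv <- load_taxonomy(sprintf("v%d\tE;V", 1:4))
  pv <- trim_params(0.8, list(list(category = "V", rank = 2, retain = 1)))
  res <- dereplicate(tr, mapv, pv)
  expect_identical(res$retained_otus, sprintf("v%d", 1:4))
  expect_length(res$records, 0L)

  # threshold 0 examines every clade, support present or not
  res0 <- dereplicate(tr, mapv, trim_params(0, list(list(category = "V", rank = 2,
                                                         retain = 1))))
  expect_identical(res0$retained_otus, "v1")
})

test_that("dereplicate agrees with the brute-force oracle on planted scenarios", {
  g <- generate_tree(plant_spec(6, list(planted_clade("X", 5, 1.0),
                                        planted_clade("Y", 4, 0.95)), seed = 3))
  p <- trim_params(0.8, list(list(category = "X", rank = 2, retain = 2),
                             list(category = "Y", rank = 2, retain = 1)))
  res <- dereplicate(g$tree, g$taxonomy, p)
  expect_same_result(res, brute_force_dereplicate(g$tree, g$taxonomy, p))
  expect_identical(sum(vapply(res$records, `[[`, integer(1), "removed_count")),
                   (5L - 2L) + (4L - 1L))
})

test_that("conservation, idempotence and monotonicity hold over random instances", {
  for (seed in 1:80) {
    inst <- random_instance(seed)
    res <- dereplicate(inst$tree, inst$map, inst$params)
    n_in <- length(tree_leaves(inst$tree))
    removed <- sum(vapply(res$records, `[[`, integer(1), "removed_count"))

    # conservation
    expect_identical(length(res$retained_otus) + removed, n_in)
    # never removes unmapped OTUs or OTUs outside every maximal clade
    in_clades <- unlist(lapply(res$records, `[[`, "clade_leaves"))
    expect_true(all(setdiff(tree_leaves(inst$tree), in_clades) %in%
                      res$retained_otus))

    # median attainment: odd clade, retain 1 -> the retained depth IS the median
    for (r in res$records) {
      if (length(r$clade_leaves) %% 2L == 1L && length(r$retained) == 1L &&
          r$removed_count > 0L) {
        node <- NULL
        for (n in which(!inst$tree$is_leaf))
          if (identical(clade_leaves(inst$tree, n), r$clade_leaves)) node <- n
        expect_identical(unname(leaf_depths(inst$tree, node)[r$retained]),
                         r$median)
      }
    }

    # idempotence on the restricted tree (single-rank rule layer only: with
    # rank-layered rules the matched rule of a pruned clade can deepen)
    if (!inst$layered && length(res$retained_otus) >= 2L) {
      tr2 <- restrict_to_leaves(inst$tree, res$retained_otus)
      res2 <- dereplicate(tr2, inst$map, inst$params)
      expect_identical(res2$retained_otus, res$retained_otus)
    }

    # threshold monotonicity, in the single-rule setting
    if (length(inst$params$rules) >= 1L) {
      p_lo <- trim_params(inst$params$threshold, inst$params$rules[1])
      p_hi <- trim_params(inst$params$threshold + 0.15, inst$params$rules[1])
      rm_lo <- n_in - length(dereplicate(inst$tree, inst$map, p_lo)$retained_otus)
      rm_hi <- n_in - length(dereplicate(inst$tree, inst$map, p_hi)$retained_otus)
      expect_lte(rm_hi, rm_lo)
    }

    # retain monotonicity (single-rule bump)
    p_big <- inst$params
    p_big$rules <- lapply(p_big$rules, function(r) { r$retain <- r$retain + 1L; r })
    if (!is.null(p_big$default_rule))
      p_big$default_rule$retain <- p_big$default_rule$retain + 1L
    res_big <- dereplicate(inst$tree, inst$map, p_big)
    expect_lte(n_in - length(res_big$retained_otus), removed)
  }
})
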