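# Output serializers. All three outputs are pure functions of their inputs
# (no timestamps), so repeated runs are byte-identical.

record_support_chr <- function(r) {
  if (is.na(r$support)) "NA" else fmt_num(r$support)
}

#' Write the retained-OTU list
#'
#' The primary output: one retained OTU name per line, in the input tree's
#' leaf order, followed by a `#`-prefixed summary block giving, per
#' dereplicated clade, its category, rank, size, retained and removed
#' counts, support and median depth. Parsing the non-`#` lines back
#' recovers `result$retained_otus` exactly.
#'
#' @param result a `trim_result` from [dereplicate()].
#' @param path optional file path to also write to.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_retained_list <- function(result, path = NULL) {
  recs <- result$records
  total_removed <- sum(vapply(recs, `[[`, integer(1), "removed_count"))
  lines <- c(
    result$retained_otus,
    "# --- dereplication summary ---",
    sprintf("# clades_dereplicated: %d", length(recs)),
    sprintf("# otus_removed: %d", total_removed),
    "# category\trank\tclade_size\tretained\tremoved\tsupport\tmedian")
  for (r in recs) {
    lines <- c(lines, sprintf(
      "# %s\t%d\t%d\t%d\t%d\t%s\t%s",
      r$category, r$rank, length(r$clade_leaves), length(r$retained),
      r$removed_count, record_support_chr(r), fmt_num(r$median)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write the trimmed reference cladogram
#'
#' The secondary output: the input topology restricted to the retained
#' OTUs, serialized without branch lengths but with supports. It is a
#' guide for the eye, not for analysis — after pruning, its topology is
#' not necessarily phylogenetically meaningful.
#'
#' @param tree the original `ttree`.
#' @param result a `trim_result` from [dereplicate()] on that tree.
#' @param path optional file path to also write to.
#' @return a Newick string (invisibly when `path` is given).
#' @export
write_reference_tree <- function(tree, result, path = NULL) {
  if (length(result$retained_otus) < 2L)
    ct_stop("fewer than 2 OTUs retained; no reference tree can be written")
  nwk <- write_newick(restrict_to_leaves(tree, result$retained_otus),
                      with_branch_lengths = FALSE, with_supports = TRUE)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Write the machine-readable removal table
#'
#' TSV with a header row and one row per dereplicated clade: category,
#' rank, support, clade size, retained names (`;`-joined), removed count
#' and median depth, in the deterministic record order (first-leaf
#' position).
#'
#' @inheritParams write_retained_list
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_removal_table <- function(result, path = NULL) {
  lines <- "category\trank\tsupport\tclade_size\tretained_names\tremoved_count\tmedian"
  for (r in result$records) {
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\t%d\t%s\t%d\t%s",
      r$category, r$rank, record_support_chr(r), length(r$clade_leaves),
      paste(r$retained, collapse = ";"), r$removed_count, fmt_num(r$median)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
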