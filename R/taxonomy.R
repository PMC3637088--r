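#' OTU-to-lineage reference table
#'
#' A `taxonomy_map` associates each OTU name (which must match a tree leaf
#' name exactly) with an ordered lineage of rank labels, most inclusive
#' first: position 1 is the domain-level category, position 2 the next rank
#' down, and so on. Ranks are positional; named ranks (class, family, ...)
#' are only a documentation convention, so non-taxonomic labels such as
#' sample sites or project tags work equally well.
#'
#' @param entries named list: OTU name -> character vector lineage.
#' @return a `taxonomy_map`.
#' @export
taxonomy_map <- function(entries = list()) {
  nm <- names(entries)
  if (length(entries) && (is.null(nm) || any(!nzchar(nm))))
    ct_stop("every taxonomy entry needs an OTU name")
  if (anyDuplicated(nm))
    ct_stop(sprintf("duplicate OTU name: '%s'", nm[duplicated(nm)][1]))
  for (otu in nm) {
    lin <- entries[[otu]]
    if (!is.character(lin) || length(lin) == 0L || any(!nzchar(lin)))
      ct_stop(sprintf("empty lineage for OTU '%s'", otu))
  }
  structure(entries, class = "taxonomy_map")
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat(sprintf("<taxonomy_map: %d OTUs>\n", length(x)))
  invisible(x)
}

#' Read a taxonomy table
#'
#' Format: one OTU per line, `<otu_name>\t<rank1>;<rank2>;...;<rankK>`,
#' UTF-8, `#`-prefixed comment lines and blank lines skipped. An empty file
#' is valid and yields an empty map (every OTU then unmapped, hence never
#' dereplicated).
#'
#' @param text character vector of lines, or a single string with newlines,
#'   or a file path (when `is_path = TRUE`).
#' @param is_path treat `text` as a path and read it.
#' @return a [taxonomy_map()].
#' @export
load_taxonomy <- function(text, is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  lines <- as_lines(text)
  entries <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line)) || grepl("^\\s*#", line)) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      ct_stop(sprintf("taxonomy line %d: expected '<otu>\\t<lineage>'", ln))
    otu <- trimws(parts[1])
    lineage <- trimws(strsplit(parts[2], ";", fixed = TRUE)[[1]])
    lineage <- lineage[nzchar(lineage)]
    if (!nzchar(otu) || length(lineage) == 0L)
      ct_stop(sprintf("taxonomy line %d: empty OTU name or lineage", ln))
    if (otu %in% names(entries))
      ct_stop(sprintf("taxonomy line %d: duplicate OTU name '%s'", ln, otu))
    entries[[otu]] <- lineage
  }
  taxonomy_map(entries)
}

#' Serialize a taxonomy table
#' @param map a [taxonomy_map()].
#' @param path optional file path; when given the lines are also written.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_taxonomy <- function(map, path = NULL) {
  lines <- vapply(names(map), function(otu) {
    paste0(otu, "\t", paste(map[[otu]], collapse = ";"))
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Dereplication parameter set
#'
#' Holds the support threshold plus the per-category dereplication rules.
#' Each rule names a taxonomic category, the 1-based lineage rank at which
#' that category is read, and how many representative OTUs to retain per
#' clade. An optional default rule applies, at its stated rank, to any
#' clade whose OTUs unanimously share a category not named by an explicit
#' rule. A threshold of 0 means every internal node is examined regardless
#' of support.
#'
#' @param threshold support threshold, `>= 0`, on the same scale as the
#'   tree's support values (no 0-1 vs 0-100 rescaling is performed).
#' @param rules list of `list(category =, rank =, retain =)`.
#' @param default_rule `NULL` or `list(rank =, retain =)`.
#' @return a `trim_params`.
#' @export
trim_params <- function(threshold, rules = list(), default_rule = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    ct_stop("threshold must be a single number >= 0")
  seen <- character(0)
  rules <- lapply(rules, function(r) {
    r$rank <- as.integer(r$rank)
    r$retain <- as.integer(r$retain)
    if (is.na(r$rank) || r$rank < 1L) ct_stop("rule rank must be >= 1")
    if (is.na(r$retain) || r$retain < 1L) ct_stop("rule retain must be >= 1")
    if (!is.character(r$category) || !nzchar(r$category))
      ct_stop("rule category must be a non-empty string")
    key <- paste0(r$category, "\r", r$rank)
    if (key %in% seen)
      ct_stop(sprintf("duplicate rule for (%s, rank %d)", r$category, r$rank))
    seen <<- c(seen, key)
    r[c("category", "rank", "retain")]
  })
  if (!is.null(default_rule)) {
    default_rule$rank <- as.integer(default_rule$rank)
    default_rule$retain <- as.integer(default_rule$retain)
    if (is.na(default_rule$rank) || default_rule$rank < 1L ||
        is.na(default_rule$retain) || default_rule$retain < 1L)
      ct_stop("default rule rank and retain must be >= 1")
    default_rule <- default_rule[c("rank", "retain")]
  }
  structure(list(threshold = threshold, rules = rules,
                 default_rule = default_rule),
            class = "trim_params")
}

#' @export
print.trim_params <- function(x, ...) {
  cat(sprintf("<trim_params: threshold %s, %d rule(s)%s>\n",
              fmt_num(x$threshold), length(x$rules),
              if (is.null(x$default_rule)) "" else ", with default"))
  invisible(x)
}

#' Read a parameter file
#'
#' Line-oriented, tab-separated, `#` comments and blank lines skipped:
#' \preformatted{
#' threshold<TAB>0.8
#' rule<TAB>Viridiplantae<TAB>3<TAB>2
#' default<TAB>5<TAB>2
#' }
#' Exactly one `threshold` line is required; `rule` lines may repeat
#' (distinct category/rank pairs); at most one `default` line.
#'
#' @inheritParams load_taxonomy
#' @return a [trim_params()].
#' @export
load_params <- function(text, is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  lines <- as_lines(text)
  threshold <- NULL
  rules <- list()
  default_rule <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line)) || grepl("^\\s*#", line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    kw <- trimws(f[1])
    bad <- function(msg) ct_stop(sprintf("parameter line %d: %s", ln, msg))
    if (kw == "threshold") {
      if (!is.null(threshold)) bad("duplicate threshold line")
      if (length(f) != 2L || !is_numeric_token(trimws(f[2])))
        bad("expected 'threshold\\t<number>'")
      threshold <- as.numeric(f[2])
      if (threshold < 0) bad("threshold must be >= 0")
    } else if (kw == "rule") {
      if (length(f) != 4L) bad("expected 'rule\\t<category>\\t<rank>\\t<retain>'")
      rank <- suppressWarnings(as.integer(f[3]))
      retain <- suppressWarnings(as.integer(f[4]))
      if (is.na(rank) || rank < 1L) bad("rule rank must be an integer >= 1")
      if (is.na(retain) || retain < 1L) bad("rule retain must be an integer >= 1")
      for (r in rules)
        if (r$category == trimws(f[2]) && r$rank == rank)
          bad(sprintf("duplicate rule for (%s, rank %d)", trimws(f[2]), rank))
      rules[[length(rules) + 1L]] <-
        list(category = trimws(f[2]), rank = rank, retain = retain)
    } else if (kw == "default") {
      if (!is.null(default_rule)) bad("duplicate default line")
      if (length(f) != 3L) bad("expected 'default\\t<rank>\\t<retain>'")
      rank <- suppressWarnings(as.integer(f[2]))
      retain <- suppressWarnings(as.integer(f[3]))
      if (is.na(rank) || rank < 1L || is.na(retain) || retain < 1L)
        bad("default rank and retain must be integers >= 1")
      default_rule <- list(rank = rank, retain = retain)
    } else {
      bad(sprintf("unknown directive '%s'", kw))
    }
  }
  if (is.null(threshold))
    ct_stop("parameter file has no threshold line")
  trim_params(threshold, rules, default_rule)
}

#' Category of an OTU at a lineage rank
#'
#' Pure lookup: `lineage[rank]` when the OTU is mapped and its lineage is
#' deep enough, else `NA` (absent). Absence is a value, not an error —
#' unmapped OTUs simply never match any rule.
#'
#' @param map a [taxonomy_map()].
#' @param otu OTU name.
#' @param rank 1-based rank index.
#' @return rank label, or `NA_character_`.
#' @export
category_at_rank <- function(map, otu, rank) {
  lin <- map[[otu]]
  if (is.null(lin) || length(lin) < rank) NA_character_ else lin[[rank]]
}

#' Find the dereplication rule unanimously matched by a leaf set
#'
#' A rule matches when every OTU in `leaf_set` has exactly the rule's
#' category at the rule's rank (case-sensitive string equality); any OTU
#' that is unmapped, or whose lineage is too short, disqualifies the rule.
#' Explicit rules are checked first; when several match, the rule at the
#' deepest (largest) rank wins, and among equal ranks the first declared.
#' Otherwise the default rule matches when all OTUs share the same
#' non-absent label at the default rank, yielding a rule for that label.
#'
#' @param params a [trim_params()].
#' @param map a [taxonomy_map()].
#' @param leaf_set non-empty character vector of OTU names.
#' @return `list(category, rank, retain, source)` or `NULL` when no rule
#'   unanimously matches.
#' @export
matching_rule <- function(params, map, leaf_set) {
  if (length(leaf_set) == 0L) ct_stop("leaf_set must be non-empty")
  best <- NULL
  for (r in params$rules) {
    cats <- vapply(leaf_set, category_at_rank, character(1),
                   map = map, rank = r$rank)
    if (!anyNA(cats) && all(cats == r$category)) {
      if (is.null(best) || r$rank > best$rank) best <- r
    }
  }
  if (!is.null(best)) {
    best$source <- "rule"
    return(best)
  }
  d <- params$default_rule
  if (!is.null(d)) {
    cats <- vapply(leaf_set, category_at_rank, character(1),
                   map = map, rank = d$rank)
    if (!anyNA(cats) && length(unique(cats)) == 1L)
      return(list(category = cats[[1]], rank = d$rank, retain = d$retain,
                  source = "default"))
  }
  NULL
}
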