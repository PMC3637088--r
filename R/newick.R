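#' Parse a Newick tree, preserving branch lengths and support values
#'
#' Reads one Newick statement into a [build_ttree()] object. Two conventions
#' for statistical support on internal nodes are understood:
#' \describe{
#'   \item{`"label"`}{(default) the FastTree/RAxML style, where the support
#'     occupies the internal-node label slot: `"(A,B)0.97:0.1"`. A label that
#'     does not parse as a plain number is kept as the node's name, never
#'     dropped.}
#'   \item{`"comment"`}{the support is a bare number inside a square-bracket
#'     comment attached to the internal node, before or after the branch
#'     length: `"(A,B)[0.97]:0.1"` or `"(A,B):0.1[97]"`. Internal-node labels
#'     are then always names. Non-numeric comments are skipped.}
#' }
#' Quoted labels (`'...'`, with `''` escaping an embedded quote) are taken
#' literally; in unquoted labels underscores are converted to spaces only
#' when `underscores_as_spaces = TRUE`.
#'
#' Support values are kept exactly as written: no rescaling is attempted
#' between 0-1 (posterior/SH-like) and 0-100 (bootstrap) scales, so
#' downstream thresholds must be on the same scale as the file.
#'
#' @param text a Newick string (may span several lines) ending in `;`.
#' @param support_style `"label"` or `"comment"`, see Details.
#' @param underscores_as_spaces convert `_` to space in unquoted labels.
#' @return a `ttree`.
#' @examples
#' tr <- parse_newick("((A:1,B:1)0.99:0.5,C:2);")
#' tree_leaves(tr)
#' @export
parse_newick <- function(text, support_style = c("label", "comment"),
                         underscores_as_spaces = FALSE) {
  support_style <- match.arg(support_style)
  s <- strsplit(paste(text, collapse = ""), "")[[1]]
  p <- new.env(parent = emptyenv())
  p$i <- 1L

  peek <- function() if (p$i <= length(s)) s[p$i] else NA_character_
  advance <- function() p$i <- p$i + 1L
  skip_ws <- function() while (!is.na(peek()) && grepl("[[:space:]]", peek())) advance()

  read_quoted <- function() {
    advance()  # opening '
    out <- character(0)
    repeat {
      ch <- peek()
      if (is.na(ch)) ct_parse_error("unterminated quoted label", p$i)
      advance()
      if (ch == "'") {
        if (identical(peek(), "'")) { out <- c(out, "'"); advance() }
        else break
      } else out <- c(out, ch)
    }
    paste(out, collapse = "")
  }

  read_label <- function() {
    skip_ws()
    if (identical(peek(), "'")) return(read_quoted())
    out <- character(0)
    repeat {
      ch <- peek()
      if (is.na(ch) || ch %in% c(",", "(", ")", ":", ";", "[", "]") ||
          grepl("[[:space:]]", ch)) break
      out <- c(out, ch)
      advance()
    }
    lab <- paste(out, collapse = "")
    if (underscores_as_spaces) lab <- gsub("_", " ", lab, fixed = TRUE)
    lab
  }

  # Returns the comment body, or NA if no comment here.
  read_comment <- function() {
    skip_ws()
    if (!identical(peek(), "[")) return(NA_character_)
    advance()
    out <- character(0)
    repeat {
      ch <- peek()
      if (is.na(ch)) ct_parse_error("unterminated [comment]", p$i)
      advance()
      if (ch == "]") break
      out <- c(out, ch)
    }
    paste(out, collapse = "")
  }

  read_number <- function(what) {
    skip_ws()
    start <- p$i
    out <- character(0)
    repeat {
      ch <- peek()
      if (is.na(ch) || !grepl("[-+0-9.eE]", ch)) break
      out <- c(out, ch)
      advance()
    }
    tok <- paste(out, collapse = "")
    if (!is_numeric_token(tok))
      ct_parse_error(sprintf("expected a %s, got '%s'", what, tok), start)
    as.numeric(tok)
  }

  parse_node <- function() {
    skip_ws()
    node <- list()
    if (identical(peek(), "(")) {
      advance()
      kids <- list(parse_node())
      repeat {
        skip_ws()
        ch <- peek()
        if (identical(ch, ",")) { advance(); kids <- c(kids, list(parse_node())) }
        else if (identical(ch, ")")) { advance(); break }
        else ct_parse_error("expected ',' or ')'", p$i)
      }
      node$children <- kids
      lab <- read_label()
      if (nzchar(lab)) node$label <- lab
    } else {
      if (is.na(peek()) || peek() %in% c(")", ",", ";", ":"))
        ct_parse_error("expected a leaf label", p$i)
      lab <- read_label()
      if (!nzchar(lab)) ct_parse_error("empty leaf label", p$i)
      node$label <- lab
    }
    internal <- !is.null(node$children)
    com1 <- read_comment()
    skip_ws()
    if (identical(peek(), ":")) {
      advance()
      node$length <- read_number("branch length")
      if (node$length < 0)
        ct_parse_error("negative branch length", p$i)
    }
    com2 <- read_comment()
    if (internal) {
      if (support_style == "label") {
        if (!is.null(node$label) && is_numeric_token(node$label)) {
          node$support <- as.numeric(node$label)
          node$label <- NULL
        }
      } else {
        for (com in c(com1, com2)) {
          if (!is.na(com) && is_numeric_token(trimws(com))) {
            node$support <- as.numeric(trimws(com))
            break
          }
        }
      }
    }
    node
  }

  root <- parse_node()
  skip_ws()
  if (!identical(peek(), ";"))
    ct_parse_error("expected ';' terminating the tree", p$i)
  advance()
  skip_ws()
  if (!is.na(peek()))
    ct_parse_error("trailing characters after ';'", p$i)
  build_ttree(root)
}

needs_quoting <- function(lab) grepl("[][ '(),:;\t]", lab)

quote_label <- function(lab) {
  if (needs_quoting(lab))
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  else lab
}

#' Serialize a tree to Newick
#'
#' Inverse of [parse_newick()] under the internal-label support convention.
#' With `with_branch_lengths = FALSE` no `:length` fields are emitted at all,
#' yielding a cladogram. Supports are written as internal-node labels; an
#' internal node carrying both no support and a name gets its name.
#'
#' @param tree a `ttree`.
#' @param with_branch_lengths emit `:length` fields.
#' @param with_supports emit supports as internal node labels.
#' @return a single Newick string ending in `;`.
#' @examples
#' tr <- parse_newick("((A:1,B:1)0.99:0.5,C:2);")
#' write_newick(tr, with_branch_lengths = FALSE)
#' @export
write_newick <- function(tree, with_branch_lengths = TRUE, with_supports = TRUE) {
  validate_ttree(tree)
  emit <- function(node) {
    if (tree$is_leaf[node]) {
      out <- quote_label(tree$label[node])
    } else {
      inner <- vapply(tree$children[[node]], emit, character(1))
      lab <- ""
      if (with_supports && !is.na(tree$support[node]))
        lab <- fmt_num(tree$support[node])
      else if (!is.na(tree$label[node]))
        lab <- quote_label(tree$label[node])
      out <- paste0("(", paste(inner, collapse = ","), ")", lab)
    }
    if (with_branch_lengths && node != 1L && !is.na(tree$length[node]))
      out <- paste0(out, ":", fmt_num(tree$length[node]))
    out
  }
  paste0(emit(1L), ";")
}
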