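# Internal helpers shared across modules.

ct_stop <- function(msg, class = "cladetrim_validation_error", ...) {
  stop(errorCondition(msg, class = c(class, "cladetrim_error", "error"), ...))
}

ct_parse_error <- function(msg, offset = NA_integer_) {
  ct_stop(sprintf("parse error at character %d: %s", offset, msg),
          class = "cladetrim_parse_error", offset = offset)
}

# Strict numeric token: what counts as a support value when it appears in the
# internal-node label slot. Deliberately excludes "Inf"/"NA"/hex so that
# alphanumeric clade names are never swallowed as supports.
is_numeric_token <- function(x) {
  grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
}

# Number formatting for serialized output. 15 significant digits keeps
# branch-length and support round-trips near machine precision while still
# printing round values compactly; integers get a trailing ".0" so lengths
# are visually distinct from support labels.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (grepl("^-?[0-9]+$", s)) s <- paste0(s, ".0")
    s
  }, character(1))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Coerce "character stream" inputs: a single string with embedded newlines,
# a character vector of lines, or a connection/file path via readLines upstream.
as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sub("\r$", "", text)
}
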