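#' Construct a sentiment lexicon
#'
#' A lexicon bundles everything the rule engine needs: word valences on the
#' \eqn{[-5, 5]} scale, multiplicative modifier (intensifier/attenuator)
#' factors, negation markers, and the two rule parameters. A token may carry a
#' valence and also act as a negator; the sets are not required to be
#' disjoint.
#'
#' @param valences Named numeric vector, token -> valence in \eqn{[-5, 5]}.
#' @param modifiers Named numeric vector, token -> positive factor applied to
#'   the next valence-bearing token in the same sentence.
#' @param negators Character vector of negation tokens.
#' @param exclamation_factor Multiplier applied once per terminal `!` of a
#'   sentence (at most three count). Must exceed 1.
#' @param negation_window Number of following tokens a negator can reach
#'   within its sentence.
#' @return An object of class `bedmot_lexicon`.
#' @export
lexicon <- function(valences = numeric(), modifiers = numeric(),
                    negators = character(), exclamation_factor = 1.5,
                    negation_window = 3L) {
  valences <- unlist(valences)
  if (length(valences) && is.null(names(valences)))
    stop("`valences` must be a named vector")
  if (any(valences < -5 | valences > 5))
    stop("valences must lie in [-5, 5]; offending token(s): ",
         paste(names(valences)[valences < -5 | valences > 5], collapse = ", "))
  modifiers <- unlist(modifiers)
  if (length(modifiers) && is.null(names(modifiers)))
    stop("`modifiers` must be a named vector")
  if (any(modifiers <= 0)) stop("modifier factors must be > 0")
  if (!is.numeric(exclamation_factor) || exclamation_factor <= 1)
    stop("`exclamation_factor` must be > 1")
  negation_window <- as.integer(negation_window)
  if (negation_window < 1L) stop("`negation_window` must be a positive integer")
  structure(
    list(valences = valences, modifiers = modifiers,
         negators = unique(as.character(negators)),
         exclamation_factor = exclamation_factor,
         negation_window = negation_window),
    class = "bedmot_lexicon")
}

#' @export
print.bedmot_lexicon <- function(x, ...) {
  cat("Sentiment lexicon:", length(x$valences), "valence tokens,",
      length(x$modifiers), "modifiers,", length(x$negators), "negators\n")
  cat("  negation window:", x$negation_window,
      " exclamation factor:", x$exclamation_factor, "\n")
  invisible(x)
}

# Read a two-column (token<TAB>number) or one-column TSV; '#' lines and blank
# lines are skipped; duplicate tokens resolve last-wins with a warning.
read_lexicon_tsv <- function(path, n_fields) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad))
    stop(sprintf("malformed row in %s at line %d: expected %d tab-separated field(s)",
                 path, idx[bad[1]], n_fields))
  tokens <- vapply(parts, `[[`, character(1), 1L)
  if (n_fields == 1L) {
    if (anyDuplicated(tokens))
      warning(sprintf("duplicate token(s) in %s; keeping last occurrence", path))
    return(unique(tokens))
  }
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(vals))
    stop(sprintf("malformed row in %s at line %d: non-numeric value",
                 path, idx[which(is.na(vals))[1]]))
  if (anyDuplicated(tokens)) {
    warning(sprintf("duplicate token(s) in %s; keeping last occurrence", path))
    last <- !duplicated(tokens, fromLast = TRUE)
    tokens <- tokens[last]
    vals <- vals[last]
  }
  stats::setNames(vals, tokens)
}

#' Load a lexicon from TSV files
#'
#' Valence and modifier files are UTF-8, tab-separated `token<TAB>value` with
#' no header; the negator file has one token per line. Lines starting with
#' `#` are comments. Duplicate tokens keep the last occurrence (with a
#' warning); valences outside \eqn{[-5, 5]} are rejected.
#'
#' @param valence_path,modifier_path,negator_path File paths; the latter two
#'   may be `NULL` for an empty rule set.
#' @inheritParams lexicon
#' @return A `bedmot_lexicon`.
#' @export
load_lexicon <- function(valence_path, modifier_path = NULL,
                         negator_path = NULL, exclamation_factor = 1.5,
                         negation_window = 3L) {
  valences <- read_lexicon_tsv(valence_path, 2L)
  modifiers <- if (is.null(modifier_path)) numeric() else
    read_lexicon_tsv(modifier_path, 2L)
  negators <- if (is.null(negator_path)) character() else
    read_lexicon_tsv(negator_path, 1L)
  lexicon(valences, modifiers, negators, exclamation_factor, negation_window)
}

#' Write a lexicon to a directory of TSV files
#'
#' Emits `valences.tsv`, `modifiers.tsv` and `negators.tsv` in the dialect
#' read by [load_lexicon()]. Output is byte-deterministic for a given
#' lexicon.
#'
#' @param lex A `bedmot_lexicon`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_lexicon <- function(lex, dir) {
  stopifnot(inherits(lex, "bedmot_lexicon"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("valences.tsv", "modifiers.tsv", "negators.tsv"))
  writeLines(sprintf("%s\t%.10g", names(lex$valences), lex$valences),
             paths[1], useBytes = FALSE)
  writeLines(sprintf("%s\t%.10g", names(lex$modifiers), lex$modifiers), paths[2])
  writeLines(lex$negators, paths[3])
  invisible(paths)
}
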