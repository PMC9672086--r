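# Hybrid lexicon- and rule-based polarity scoring of short free texts.
# Three steps: tokenize, adjust word valences by contextual rules (modifier,
# non-interrogative negation, exclamation), pool to a document score.

#' Tokenize a text into sentences and lowercase word tokens
#'
#' Sentences are split on runs of terminal punctuation (`.`, `!`, `?`). A
#' sentence is interrogative iff its terminal punctuation run contains `?`;
#' the number of `!` in the run is recorded. Tokens are maximal runs of
#' Unicode letters (Danish \code{æøå} preserved), lowercased;
#' hyphenated words split and digits carry no token.
#'
#' @param text A character scalar (possibly empty or `NA`).
#' @return A data frame of class `sentiment_tokens` with columns `token`,
#'   `position` (0-based over the document) and `sentence` (0-based), plus an
#'   attribute `sentences`: a data frame with `sentence`, `interrogative`,
#'   `n_exclaim`.
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single string")
  empty <- data.frame(token = character(), position = integer(),
                      sentence = integer(), stringsAsFactors = FALSE)
  empty_s <- data.frame(sentence = integer(), interrogative = logical(),
                        n_exclaim = integer())
  if (is.na(text) || !nzchar(trimws(text))) {
    attr(empty, "sentences") <- empty_s
    class(empty) <- c("sentiment_tokens", "data.frame")
    return(empty)
  }
  chunks <- regmatches(text, gregexpr("[^.!?]+[.!?]*", text))[[1]]
  tok_l <- list(); sent_rows <- list(); pos0 <- 0L; si <- 0L
  for (ch in chunks) {
    term <- regmatches(ch, regexpr("[.!?]+$", ch))
    interrogative <- length(term) == 1L && grepl("?", term, fixed = TRUE)
    n_exclaim <- if (length(term)) lengths(regmatches(term, gregexpr("!", term, fixed = TRUE))) else 0L
    toks <- regmatches(tolower(ch), gregexpr("\\p{L}+", tolower(ch), perl = TRUE))[[1]]
    if (!length(toks)) next
    tok_l[[length(tok_l) + 1L]] <- data.frame(
      token = toks, position = pos0 + seq_along(toks) - 1L,
      sentence = si, stringsAsFactors = FALSE)
    sent_rows[[length(sent_rows) + 1L]] <- data.frame(
      sentence = si, interrogative = interrogative,
      n_exclaim = as.integer(n_exclaim))
    pos0 <- pos0 + length(toks)
    si <- si + 1L
  }
  out <- if (length(tok_l)) do.call(rbind, tok_l) else empty
  attr(out, "sentences") <- if (length(sent_rows)) do.call(rbind, sent_rows) else empty_s
  class(out) <- c("sentiment_tokens", "data.frame")
  out
}

#' Apply valence-adjustment rules to tokenized text
#'
#' Looks up the raw valence of each token and adjusts it by three rules, in
#' order: (1) a modifier token multiplies the next valence-bearing token of
#' the same sentence by its factor; (2) a negator flips the sign of
#' valence-bearing tokens within the following `negation_window` tokens of
#' the same sentence, unless the sentence is interrogative (stacked negators
#' each flip, so a double negation cancels); (3) each `!` terminating a
#' sentence (at most three) multiplies all its adjusted valences by
#' `exclamation_factor`.
#'
#' @param tokens Output of [tokenize()].
#' @param lex A [lexicon()].
#' @return The token data frame with added columns `raw_valence`,
#'   `adjusted_valence` (both `NA` for tokens absent from the lexicon) and
#'   logical rule flags `rule_modifier`, `rule_negation`, `rule_exclamation`.
#' @export
apply_rules <- function(tokens, lex) {
  stopifnot(inherits(tokens, "sentiment_tokens"), inherits(lex, "bedmot_lexicon"))
  sent <- attr(tokens, "sentences")
  n <- nrow(tokens)
  raw <- unname(lex$valences[tokens$token])
  adj <- raw
  rule_mod <- rule_neg <- rule_exc <- logical(n)
  if (n) {
    for (s in sent$sentence) {
      idx <- which(tokens$sentence == s)
      srow <- sent[sent$sentence == s, ]
      # modifiers: each scopes over the next valence-bearing token
      for (i in idx[tokens$token[idx] %in% names(lex$modifiers)]) {
        after <- idx[idx > i & !is.na(raw[idx])]
        if (length(after)) {
          q <- after[1]
          adj[q] <- adj[q] * lex$modifiers[[tokens$token[i]]]
          rule_mod[q] <- TRUE
        }
      }
      # negation: suppressed in interrogative sentences
      if (!srow$interrogative) {
        for (i in idx[tokens$token[idx] %in% lex$negators]) {
          targets <- idx[idx > i & idx <= i + lex$negation_window & !is.na(raw[idx])]
          adj[targets] <- -adj[targets]
          rule_neg[targets] <- TRUE
        }
      }
      # exclamation amplification, capped at three marks
      if (srow$n_exclaim > 0L) {
        f <- lex$exclamation_factor ^ min(srow$n_exclaim, 3L)
        hit <- idx[!is.na(raw[idx])]
        adj[hit] <- adj[hit] * f
        rule_exc[hit] <- TRUE
      }
    }
  }
  tokens$raw_valence <- raw
  tokens$adjusted_valence <- adj
  tokens$rule_modifier <- rule_mod
  tokens$rule_negation <- rule_neg
  tokens$rule_exclamation <- rule_exc
  tokens
}

#' Pooling operators for token valences
#'
#' `pool_sum` and `pool_mean` are the two classical aggregations;
#' `pool_gmean` is a partitioned signed geometric mean defined for any mix of
#' positive, zero and negative values: with \eqn{P} the positives, \eqn{N}
#' the negatives, \eqn{n} the total count, \eqn{g^+} the geometric mean of
#' \eqn{P} and \eqn{g^-} that of \eqn{|N|} (0 for empty parts), the result is
#' \eqn{(|P| g^+ - |N| g^-)/n}. It reduces to the ordinary geometric mean on
#' all-positive input and is antisymmetric under sign flip. All three return
#' 0 on empty input.
#'
#' @param x Numeric vector of (adjusted) valences.
#' @return A single number.
#' @export
pool_sum <- function(x) if (length(x)) sum(x) else 0

#' @rdname pool_sum
#' @export
pool_mean <- function(x) if (length(x)) mean(x) else 0

#' @rdname pool_sum
#' @export
pool_gmean <- function(x) {
  n <- length(x)
  if (!n) return(0)
  p <- x[x > 0]; ng <- -x[x < 0]
  gp <- if (length(p)) exp(mean(log(p))) else 0
  gn <- if (length(ng)) exp(mean(log(ng))) else 0
  (length(p) * gp - length(ng) * gn) / n
}

#' Score the sentiment polarity of a document
#'
#' Runs the full chain tokenize -> [apply_rules()] -> pool over the adjusted
#' valences of the valence-bearing tokens. Documents with no lexicon hits
#' score exactly 0 under every method. Deterministic for fixed inputs.
#'
#' @param text Character scalar.
#' @param lex A [lexicon()].
#' @param method Pooling operator: `"gmean"` (partitioned signed geometric
#'   mean), `"mean"`, or `"sum"`.
#' @return An object of class `polarity_result`: list with `method`, `value`,
#'   `n_scored`, `n_tokens` and `pooling` (the fully-qualified pooling name).
#' @export
score_document <- function(text, lex, method = c("gmean", "mean", "sum")) {
  method <- match.arg(method)
  scored <- apply_rules(tokenize(text), lex)
  vals <- scored$adjusted_valence[!is.na(scored$adjusted_valence)]
  pool <- switch(method, sum = pool_sum, mean = pool_mean, gmean = pool_gmean)
  structure(
    list(method = method,
         value = pool(vals),
         n_scored = length(vals),
         n_tokens = nrow(scored),
         pooling = if (method == "gmean") "partitioned_signed_gmean" else method),
    class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("Polarity %.4f (%s pooling; %d of %d tokens scored)\n",
              x$value, x$pooling, x$n_scored, x$n_tokens))
  invisible(x)
}

#' Score a vector of statements
#'
#' Vectorised front end to [score_document()].
#'
#' @param texts Character vector.
#' @inheritParams score_document
#' @return Data frame with columns `polarity`, `n_scored`, `n_tokens`.
#' @export
score_statements <- function(texts, lex, method = c("gmean", "mean", "sum")) {
  method <- match.arg(method)
  res <- lapply(texts, score_document, lex = lex, method = method)
  data.frame(polarity = vapply(res, `[[`, numeric(1), "value"),
             n_scored = vapply(res, `[[`, integer(1), "n_scored"),
             n_tokens = vapply(res, `[[`, integer(1), "n_tokens"))
}
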