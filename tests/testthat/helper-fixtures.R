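# Shared fixtures and independent oracles used across test files.

# Minimal Danish-flavoured fixture lexicon for rule-engine tests.
fixture_lexicon <- function() {
  lexicon(valences = c(god = 3, godt = 3, ond = -2, rar = 1, slem = -4),
          modifiers = c(meget = 1.5, lidt = 0.5),
          negators = c("ikke", "aldrig"))
}

# Brute-force O(n^2) Kendall tau-b: explicit pair classification with the
# standard tie terms. Independent of stats::cor.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2))
  n2 <- sum(choose(table(y), 2))
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# Brute-force JT statistic by direct double loop over ordered group pairs.
jt_oracle <- function(x, g) {
  g <- as.integer(factor(g))
  J <- 0
  for (a in seq_along(x)) {
    for (b in seq_along(x)) {
      if (g[a] < g[b]) {
        if (x[a] < x[b]) J <- J + 1
        else if (x[a] == x[b]) J <- J + 0.5
      }
    }
  }
  J
}

# Exhaustive JT permutation p-value by brute-force enumeration of all n!
# index permutations (duplicates included; valid for small n only).
jt_exhaustive_oracle <- function(x, g) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  sizes <- table(factor(g))
  mu <- (n^2 - sum(sizes^2)) / 4
  J_obs <- jt_oracle(x, g)
  Js <- vapply(perms(seq_len(n)), function(p) jt_oracle(x[p], g), numeric(1))
  mean(abs(Js - mu) >= abs(J_obs - mu) - 1e-9)
}

# A small valid cohort with deterministic structure, for instrument and IO
# tests that do not need the full generator.
tiny_cohort <- function(n = 12) {
  young <- rep(c(TRUE, FALSE), length.out = n)
  data.frame(
    id = sprintf("T%02d", seq_len(n)),
    age = ifelse(young, 20, 40),
    sex = rep(c("male", "female"), length.out = n),
    bmi = 30 + seq_len(n),
    age_group = ifelse(young, "young_adult", "adult"),
    motivation_aims = factor(rep(sdt_levels()[2:4], length.out = n),
                             levels = sdt_levels(), ordered = TRUE),
    motivation_online = factor(rep(sdt_levels(), length.out = n),
                               levels = sdt_levels(), ordered = TRUE),
    therapy_aims_text = rep("god dag.", n),
    why_online_text = rep("ikke god.", n),
    sessions_completed = rep(c(3L, 7L, 10L), length.out = n),
    followup_done = rep(c(FALSE, FALSE, TRUE), length.out = n),
    bedq_pre = rep(15L, n), bedq_post = rep(10L, n),
    edeq_pre = rep(3.5, n), edeq_post = rep(2.5, n),
    mdi_pre = rep(23L, n), mdi_post = rep(18L, n),
    vas_pre = rep(50L, n), vas_post = rep(60L, n),
    stringsAsFactors = FALSE)
}
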