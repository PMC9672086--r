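# Seeded synthetic cohorts, lexicons and free-text statements carrying the
# statistical structure the analysis pipeline assumes: ordinal motivation
# labels whose latent polarity rises with the level, pre/post outcomes with a
# treatment effect but (by default) no motivation effect, and an adherence
# link confined to young adults. All patient-level data here are synthetic;
# no real patient material is used or emulated verbatim.

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: a cohort of
#' 148 with 19 young adults and 17 men; therapy-aims motivation counts
#' proportional to 0/50/50/48 (external regulation screened out) and
#' why-online counts to 31/21/81/15; a linear latent-polarity link across
#' the four SDT levels calibrated so the population Kendall tau-b between
#' scored polarity and therapy-aims motivation is about 0.31; pre/post
#' outcomes improving under treatment with a zero motivation-type effect;
#' and a negative polarity-adherence link in young adults only, calibrated
#' to a population tau-b of about -0.31. Completion categories default to
#' proportions 54/56/37.
#'
#' @param n Cohort size.
#' @param young_fraction Fraction of young adults (age below 25).
#' @param p_male Fraction of male patients.
#' @param motivation_probs_aims,motivation_probs_online Probability vectors
#'   over the four SDT levels (external, introjection, identification,
#'   integration); must sum to 1.
#' @param polarity_link Latent mean polarity increment per motivation level
#'   index (0..3).
#' @param polarity_noise_sd Standard deviation of the patient-level latent
#'   polarity noise.
#' @param polarity_baseline Named baseline latent polarity per question.
#' @param tokens_per_statement Content tokens drawn per statement.
#' @param filler_rate Probability that a content slot emits a filler word.
#' @param negation_rate Probability that a valence token is negated.
#' @param token_sd Standard deviation of token valences around the latent
#'   polarity.
#' @param outcome_pre_params Named list per instrument of `c(mean, sd)` for
#'   the truncated-normal pre-treatment draw.
#' @param treatment_effect Named vector of mean pre-to-post shifts (negative
#'   = symptom reduction; VAS positive = improvement).
#' @param outcome_noise_sd Named vector of post-score noise SDs.
#' @param motivation_outcome_effect Additional post shift per therapy-aims
#'   level index; 0 keeps the motivation-outcome null.
#' @param young_adherence_link Strength of the (negative) young-adult link
#'   between why-online latent polarity and adherence propensity.
#' @param completion_probs Target proportions of Low/High/Full completion.
#' @param missing_post_rate Probability that a Low completer has missing
#'   post scores.
#' @param seed Integer seed; every downstream draw is deterministic in it.
#' @return Object of class `generator_config` (a validated list).
#' @export
generator_config <- function(
    n = 148L,
    young_fraction = 19 / 148,
    p_male = 17 / 148,
    motivation_probs_aims = c(0, 50, 50, 48) / 148,
    motivation_probs_online = c(31, 21, 81, 15) / 148,
    polarity_link = 0.615,
    polarity_noise_sd = 1,
    polarity_baseline = c(therapy_aims = 0.6, why_online = 0.1),
    tokens_per_statement = 12L,
    filler_rate = 0.3,
    negation_rate = 0.1,
    token_sd = 1.5,
    outcome_pre_params = list(bedq = c(mean = 16, sd = 3),
                              edeq = c(mean = 3.5, sd = 1),
                              mdi = c(mean = 23, sd = 8),
                              vas = c(mean = 50, sd = 18),
                              bmi = c(mean = 37.5, sd = 6)),
    treatment_effect = c(bedq = -5, edeq = -1, mdi = -4, vas = 10),
    outcome_noise_sd = c(bedq = 3, edeq = 0.8, mdi = 5, vas = 12),
    motivation_outcome_effect = 0,
    young_adherence_link = -0.56,
    completion_probs = c(Low = 54, High = 56, Full = 37) / 147,
    missing_post_rate = 0.25,
    seed = 1L) {
  cfg <- list(n = as.integer(n), young_fraction = young_fraction,
              p_male = p_male,
              motivation_probs_aims = motivation_probs_aims,
              motivation_probs_online = motivation_probs_online,
              polarity_link = polarity_link,
              polarity_noise_sd = polarity_noise_sd,
              polarity_baseline = polarity_baseline,
              tokens_per_statement = as.integer(tokens_per_statement),
              filler_rate = filler_rate, negation_rate = negation_rate,
              token_sd = token_sd,
              outcome_pre_params = outcome_pre_params,
              treatment_effect = treatment_effect,
              outcome_noise_sd = outcome_noise_sd,
              motivation_outcome_effect = motivation_outcome_effect,
              young_adherence_link = young_adherence_link,
              completion_probs = completion_probs,
              missing_post_rate = missing_post_rate,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n < 4L) stop("`n` must be at least 4")
  for (p in c("motivation_probs_aims", "motivation_probs_online",
              "completion_probs"))
    if (abs(sum(cfg[[p]]) - 1) > 1e-9)
      stop(sprintf("`%s` must sum to 1", p))
  if (cfg$polarity_noise_sd <= 0) stop("`polarity_noise_sd` must be > 0")
  if (cfg$young_fraction < 0 || cfg$young_fraction > 1)
    stop("`young_fraction` must lie in [0, 1]")
  for (r in c("filler_rate", "negation_rate", "missing_post_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(sprintf("`%s` must lie in [0, 1]", r))
  if (cfg$tokens_per_statement < 1L)
    stop("`tokens_per_statement` must be positive")
  # eligibility must be satisfiable: pre draws are truncated inside the
  # eligible region, which requires sane instrument parameters
  if (cfg$outcome_pre_params$bedq[["mean"]] > 21 ||
      cfg$outcome_pre_params$bedq[["mean"]] < 0)
    stop("eligibility unsatisfiable: BED-Q pre mean outside the mild-moderate band")
  if (cfg$outcome_pre_params$mdi[["mean"]] > 40)
    stop("eligibility unsatisfiable: MDI pre mean above the exclusion cutoff")
  invisible(cfg)
}

#' Read a generator configuration from JSON
#'
#' The file must contain only [generator_config()] fields; unknown keys are
#' rejected.
#'
#' @param path JSON file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown generator config key(s): ", paste(unknown, collapse = ", "))
  # JSON arrays lose vector names; restore the documented name sets
  renamed <- function(x, nms) {
    x <- unlist(x)
    if (is.null(names(x)) || !all(nzchar(names(x)))) names(x) <- nms
    x
  }
  if (!is.null(raw$outcome_pre_params))
    raw$outcome_pre_params <- lapply(raw$outcome_pre_params, renamed,
                                     nms = c("mean", "sd"))
  name_sets <- list(polarity_baseline = c("therapy_aims", "why_online"),
                    treatment_effect = c("bedq", "edeq", "mdi", "vas"),
                    outcome_noise_sd = c("bedq", "edeq", "mdi", "vas"),
                    completion_probs = c("Low", "High", "Full"))
  for (nm in names(name_sets))
    if (!is.null(raw[[nm]])) raw[[nm]] <- renamed(raw[[nm]], name_sets[[nm]])
  do.call(generator_config, raw)
}

# Pseudo-word vocabulary: all consonant+vowel two-syllable combinations,
# letters only (so the tokenizer keeps them intact), Danish vowels included.
syllable_words <- function() {
  cons <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s", "t", "v")
  vows <- c("a", "e", "i", "o", "u", "y", "æ", "ø", "å")
  syl <- as.vector(outer(cons, vows, paste0))
  as.vector(outer(syl, syl, paste0))
}

# Short function words used as zero-valence fillers; guaranteed disjoint from
# the generated vocabulary (all generated words have at least four letters).
filler_words <- function() {
  c("og", "at", "en", "et", "jeg", "du", "vi", "som", "er", "der", "den", "det")
}

#' Generate a synthetic sentiment lexicon
#'
#' Emits at least 200 valence tokens on an even grid spanning \eqn{[-5, 5]},
#' plus modifiers and negators, built from pseudo-Danish letter-only words.
#' Deterministic per seed; written files are byte-identical across calls.
#'
#' @param seed Integer seed.
#' @param n_valence,n_modifiers,n_negators Vocabulary sizes.
#' @param dir Optional directory; if given the three TSV files are written
#'   there via [write_lexicon()].
#' @return A `bedmot_lexicon`.
#' @export
generate_lexicon <- function(seed = 1L, n_valence = 201L, n_modifiers = 12L,
                             n_negators = 6L, dir = NULL) {
  stopifnot(n_valence >= 2L, n_modifiers >= 1L, n_negators >= 1L)
  lex <- with_seed(seed, {
    words <- sample(syllable_words(), n_valence + n_modifiers + n_negators)
    vals <- seq(-5, 5, length.out = n_valence)
    modifier_factors <- round(runif(n_modifiers, 0.5, 2), 2)
    modifier_factors[modifier_factors == 1] <- 1.1
    lexicon(
      valences = stats::setNames(vals, words[seq_len(n_valence)]),
      modifiers = stats::setNames(modifier_factors,
                                  words[n_valence + seq_len(n_modifiers)]),
      negators = words[n_valence + n_modifiers + seq_len(n_negators)])
  })
  if (!is.null(dir)) write_lexicon(lex, dir)
  lex
}

#' Generate one synthetic motivation statement
#'
#' Draws `tokens_per_statement` content slots: with probability
#' `filler_rate` a filler word; otherwise a valence token whose lexicon
#' value is the nearest grid point to a normal draw centred on the latent
#' polarity. With probability `negation_rate` the valence token is negated:
#' a negator is emitted before it (and the draw is centred on the negated
#' latent, so the realised contribution still tracks the latent), followed
#' by two fillers that exhaust the negation window. Sentences of about six
#' slots end in a full stop, never `?` or `!`. Uses the current RNG state;
#' seed externally for reproducible text.
#'
#' @param latent_polarity Target mean valence of the statement.
#' @param lex Lexicon whose valence tokens are sampled.
#' @param tokens_per_statement,filler_rate,negation_rate,token_sd See
#'   [generator_config()].
#' @return A UTF-8 statement string.
#' @export
generate_statement <- function(latent_polarity, lex, tokens_per_statement = 12L,
                               filler_rate = 0.3, negation_rate = 0.1,
                               token_sd = 1.5) {
  stopifnot(inherits(lex, "bedmot_lexicon"))
  if (!length(lex$valences)) stop("empty lexicon: no valence tokens to sample")
  vtok <- names(lex$valences)
  vval <- unname(lex$valences)
  fillers <- filler_words()
  slots <- list()
  for (i in seq_len(tokens_per_statement)) {
    if (runif(1) < filler_rate) {
      slots[[length(slots) + 1L]] <- sample(fillers, 1L)
      next
    }
    negate <- runif(1) < negation_rate && length(lex$negators) > 0L
    target <- rnorm(1, mean = if (negate) -latent_polarity else latent_polarity,
                    sd = token_sd)
    tok <- vtok[which.min(abs(vval - pmin(pmax(target, -5), 5)))]
    slots[[length(slots) + 1L]] <- if (negate)
      c(sample(lex$negators, 1L), tok, sample(fillers, 2L, replace = TRUE))
    else tok
  }
  n_slots <- length(slots)
  breaks <- seq(1L, n_slots, by = 6L)
  sentences <- vapply(seq_along(breaks), function(b) {
    idx <- breaks[b]:min(breaks[b] + 5L, n_slots)
    paste(unlist(slots[idx]), collapse = " ")
  }, character(1))
  paste0(paste(sentences, collapse = ". "), ".")
}

#' Generate a synthetic patient cohort
#'
#' Draws a full cohort under the configured study conditions, together with
#' the latent ground truth each record was generated from. Demographics,
#' motivation labels, statements, pre/post outcomes (truncated-normal within
#' instrument ranges, all patients eligible by construction) and adherence
#' are all deterministic functions of `config$seed`.
#'
#' @param config A [generator_config()].
#' @param lex Optional lexicon; defaults to
#'   `generate_lexicon(seed = config$seed)`.
#' @return List with `records` (cohort data frame in the canonical column
#'   order), `ground_truth` (per-patient latent polarity, level indices and
#'   adherence propensity), `lexicon`, and `config`.
#' @export
generate_cohort <- function(config = generator_config(), lex = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(lex)) lex <- generate_lexicon(seed = config$seed)
  with_seed(config$seed, {
    n <- config$n
    n_young <- round(n * config$young_fraction)
    young <- c(rep(TRUE, n_young), rep(FALSE, n - n_young))
    age <- ifelse(young, sample(18:24, n, replace = TRUE),
                  sample(25:68, n, replace = TRUE))
    sex <- ifelse(runif(n) < config$p_male, "male", "female")
    bmi <- round(rtruncnorm(n, config$outcome_pre_params$bmi[["mean"]],
                            config$outcome_pre_params$bmi[["sd"]], 21.5, 65), 1)
    lev_aims <- sample(0:3, n, replace = TRUE, prob = config$motivation_probs_aims)
    lev_online <- sample(0:3, n, replace = TRUE, prob = config$motivation_probs_online)
    lat_aims <- config$polarity_baseline[["therapy_aims"]] +
      config$polarity_link * lev_aims + rnorm(n, 0, config$polarity_noise_sd)
    lat_online <- config$polarity_baseline[["why_online"]] +
      config$polarity_link * lev_online + rnorm(n, 0, config$polarity_noise_sd)
    gen_text <- function(lat) generate_statement(
      lat, lex, config$tokens_per_statement, config$filler_rate,
      config$negation_rate, config$token_sd)
    text_aims <- vapply(lat_aims, gen_text, character(1))
    text_online <- vapply(lat_online, gen_text, character(1))

    pp <- config$outcome_pre_params
    bedq_pre <- round(rtruncnorm(n, pp$bedq[["mean"]], pp$bedq[["sd"]], 10, 21))
    edeq_pre <- round(rtruncnorm(n, pp$edeq[["mean"]], pp$edeq[["sd"]], 0, 6), 2)
    mdi_pre <- round(rtruncnorm(n, pp$mdi[["mean"]], pp$mdi[["sd"]], 2, 40))
    vas_pre <- round(rtruncnorm(n, pp$vas[["mean"]], pp$vas[["sd"]], 0, 100))

    post_of <- function(pre, key, lo, hi, digits = 0) {
      m <- pre + config$treatment_effect[[key]] +
        config$motivation_outcome_effect * lev_aims
      round(rtruncnorm(n, m, config$outcome_noise_sd[[key]], lo, hi), digits)
    }
    bedq_post <- post_of(bedq_pre, "bedq", 0, 35)
    edeq_post <- post_of(edeq_pre, "edeq", 0, 6, 2)
    mdi_post <- post_of(mdi_pre, "mdi", 0, 50)
    vas_post <- post_of(vas_pre, "vas", 0, 100)

    # adherence propensity: pure noise for adults; for young adults a
    # (negative) contribution of the standardised why-online latent polarity
    z_lat <- as.numeric(scale(lat_online))
    propensity <- rnorm(n) + ifelse(young, config$young_adherence_link * z_lat, 0)
    u <- pnorm(propensity, mean = 0,
               sd = ifelse(young, sqrt(1 + config$young_adherence_link^2), 1))
    cp <- cumsum(config$completion_probs)
    category <- ifelse(u < cp[["Low"]], "Low",
                       ifelse(u < cp[["High"]], "High", "Full"))
    sessions <- integer(n)
    followup <- logical(n)
    sessions[category == "Low"] <- sample(0:5, sum(category == "Low"), replace = TRUE)
    sessions[category == "High"] <- sample(6:9, sum(category == "High"), replace = TRUE)
    sessions[category == "Full"] <- 10L
    followup[category == "Full"] <- TRUE

    miss <- category == "Low" & runif(n) < config$missing_post_rate
    bedq_post[miss] <- NA; edeq_post[miss] <- NA
    mdi_post[miss] <- NA; vas_post[miss] <- NA

    records <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      age = age,
      sex = sex,
      bmi = bmi,
      age_group = ifelse(young, "young_adult", "adult"),
      motivation_aims = factor(sdt_levels()[lev_aims + 1L],
                               levels = sdt_levels(), ordered = TRUE),
      motivation_online = factor(sdt_levels()[lev_online + 1L],
                                 levels = sdt_levels(), ordered = TRUE),
      therapy_aims_text = text_aims,
      why_online_text = text_online,
      sessions_completed = sessions,
      followup_done = followup,
      bedq_pre = bedq_pre, bedq_post = bedq_post,
      edeq_pre = edeq_pre, edeq_post = edeq_post,
      mdi_pre = mdi_pre, mdi_post = mdi_post,
      vas_pre = vas_pre, vas_post = vas_post,
      stringsAsFactors = FALSE)

    ground_truth <- data.frame(
      id = records$id,
      latent_polarity_aims = lat_aims,
      latent_polarity_online = lat_online,
      level_aims = lev_aims,
      level_online = lev_online,
      adherence_propensity = propensity)
    attr(ground_truth, "note") <-
      "synthetic cohort; dispersion defaults chosen for testability, not fidelity"

    list(records = records, ground_truth = ground_truth,
         lexicon = lex, config = config)
  })
}
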