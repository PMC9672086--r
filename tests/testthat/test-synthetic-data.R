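test_that("generated lexicon is deterministic, in-range, and round-trips", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  lx1 <- generate_lexicon(seed = 5, dir = d1)
  lx2 <- generate_lexicon(seed = 5, dir = d2)
  for (f in c("valences.tsv", "modifiers.tsv", "negators.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_gte(length(lx1$valences), 200)
  expect_gte(length(lx1$modifiers), 10)
  expect_gte(length(lx1$negators), 5)
  expect_true(all(lx1$valences >= -5 & lx1$valences <= 5))
  expect_equal(min(lx1$valences), -5)
  expect_equal(max(lx1$valences), 5)
  back <- load_lexicon(file.path(d1, "valences.tsv"),
                       file.path(d1, "modifiers.tsv"),
                       file.path(d1, "negators.tsv"))
  expect_equal(back$valences, lx1$valences)
  expect_equal(back$modifiers, lx1$modifiers)
  expect_equal(back$negators, lx1$negators)
  # a different seed yields a different vocabulary
  expect_false(identical(names(generate_lexicon(seed = 6)$valences),
                         names(lx1$valences)))
})

test_that("statement generator tracks the latent polarity", {
  lx <- generate_lexicon(seed = 2)
  set.seed(10)
  s1 <- generate_statement(2, lx)
  set.seed(10)
  s2 <- generate_statement(2, lx)
  expect_identical(s1, s2)
  expect_error(generate_statement(0, lexicon()), "empty lexicon")

  # neutral latent: mean-pooled score stays near zero on average
  set.seed(11)
  sc0 <- score_statements(replicate(500, generate_statement(0, lx, negation_rate = 0)),
                          lx, "mean")$polarity
  expect_lte(abs(mean(sc0)), 0.5)

  # strong separation between latent +4 and -4 cohorts
  set.seed(12)
  hi <- score_statements(replicate(100, generate_statement(4, lx)), lx, "mean")$polarity
  lo <- score_statements(replicate(100, generate_statement(-4, lx)), lx, "mean")$polarity
  d <- (mean(hi) - mean(lo)) / sqrt((var(hi) + var(lo)) / 2)
  expect_gt(d, 2)

  # realised polarity correlates with the latent across a wide range
  set.seed(13)
  lat <- runif(1000, -4, 4)
  sc <- score_statements(vapply(lat, generate_statement, character(1), lex = lx),
                         lx, "mean")$polarity
  expect_gte(cor(sc, lat), 0.8)
})

test_that("generated cohorts are valid, eligible, in-range and deterministic", {
  cfg <- generator_config(seed = 3)
  coh <- generate_cohort(cfg)
  rec <- coh$records
  expect_equal(nrow(rec), cfg$n)
  expect_length(validate_cohort(rec), 0)
  # all patients eligible by construction
  elig <- mapply(function(b, m) check_eligibility(b, m)$eligible,
                 rec$bedq_pre, rec$mdi_pre)
  expect_true(all(elig))
  expect_true(all(rec$bedq_pre <= 21))
  expect_true(all(rec$mdi_pre <= 40))
  expect_equal(sum(rec$age_group == "young_adult"), 19)
  expect_true(all(rec$age[rec$age_group == "young_adult"] < 25))
  # every completion category occurs
  cats <- completion_category(rec$sessions_completed, rec$followup_done)
  expect_setequal(as.character(unique(cats)), c("Low", "High", "Full"))
  # determinism and seed sensitivity
  expect_identical(generate_cohort(cfg)$records, rec)
  expect_false(identical(generate_cohort(generator_config(seed = 4))$records, rec))
  # ground truth aligns with records
  expect_equal(coh$ground_truth$id, rec$id)
  expect_equal(sdt_levels()[coh$ground_truth$level_aims + 1L],
               as.character(rec$motivation_aims))
})

test_that("generated cohort CSV re-parses through the cohort reader", {
  coh <- generate_cohort(generator_config(seed = 14))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh$records, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(coh$records))
  expect_length(validate_cohort(back), 0)
  expect_equal(back$therapy_aims_text, coh$records$therapy_aims_text)
})

test_that("therapy-aims labels exclude external regulation; why-online includes it", {
  coh <- generate_cohort(generator_config(seed = 15))
  expect_false("external" %in% as.character(coh$records$motivation_aims))
  expect_true("external" %in% as.character(coh$records$motivation_online))
})

test_that("generator config validation rejects impossible settings", {
  expect_error(generator_config(n = 2), "at least 4")
  expect_error(generator_config(motivation_probs_aims = c(1, 1, 1, 1)), "sum to 1")
  expect_error(generator_config(polarity_noise_sd = 0), "> 0")
  bad_pre <- list(bedq = c(mean = 30, sd = 3), edeq = c(mean = 3.5, sd = 1),
                  mdi = c(mean = 23, sd = 8), vas = c(mean = 50, sd = 18),
                  bmi = c(mean = 37.5, sd = 6))
  expect_error(generator_config(outcome_pre_params = bad_pre), "unsatisfiable")
})

test_that("generator config round-trips through JSON with unknown keys rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- generator_config(n = 40, seed = 9, polarity_link = 0.5)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  back <- read_generator_config(path)
  expect_equal(back$n, 40L)
  expect_equal(back$polarity_link, 0.5)
  expect_equal(back$motivation_probs_aims, cfg$motivation_probs_aims)
  jsonlite::write_json(list(n = 40, bogus_knob = 1), path, auto_unbox = TRUE)
  expect_error(read_generator_config(path), "bogus_knob")
})

test_that("young-adult adherence link has the configured negative sign", {
  # at the default link the young-adult polarity~completion association is
  # negative in the clear majority of cohorts
  negs <- vapply(1:60, function(s) {
    coh <- generate_cohort(generator_config(seed = 3000 + s))
    y <- coh$records$age_group == "young_adult"
    pol <- score_statements(coh$records$why_online_text[y], coh$lexicon,
                            "gmean")$polarity
    code <- as.integer(completion_category(coh$records$sessions_completed[y],
                                           coh$records$followup_done[y])) - 1L
    cor(pol, code, method = "kendall") < 0
  }, logical(1))
  expect_gte(mean(negs), 0.9)
})
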