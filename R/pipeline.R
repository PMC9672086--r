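# End-to-end orchestration: score statements, group by motivation type,
# run the ordinal inference chain per variable/question/stratum, correlate
# polarity with outcomes, fit the pre/post mixed ANOVAs, and serialize the
# result grids.

analysis_variables <- function() {
  c("polarity", "bedq_pre", "edeq_pre", "bmi_pre", "mdi_pre", "vas_pre",
    "completion_rate", "bedq_diff", "edeq_diff")
}

#' Configuration of an analysis run
#'
#' @param pooling Polarity pooling operator (`"gmean"`, `"mean"`, `"sum"`).
#' @param questions Motivation questions to analyse, subset of
#'   `c("therapy_aims", "why_online")`.
#' @param strata Age strata, subset of `c("all", "adult", "young_adult")`.
#' @param variables Variables for the trend grid, subset of
#'   `analysis_variables()`.
#' @param alpha Significance level for p-value based tests.
#' @param rmpe Recommended minimal practical effect size.
#' @param B Bootstrap resamples for tau-b confidence intervals.
#' @param n_perm Monte-Carlo relabellings for the permutation trend test.
#' @param jt_method Trend-test p-value method.
#' @param seed Integer master seed; all per-cell seeds derive from it.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(pooling = c("gmean", "mean", "sum"),
                            questions = c("therapy_aims", "why_online"),
                            strata = c("all", "adult", "young_adult"),
                            variables = analysis_variables(),
                            alpha = 0.05, rmpe = 0.2,
                            B = 2000L, n_perm = 2000L,
                            jt_method = c("normal_approx", "permutation"),
                            seed = 1L) {
  pooling <- match.arg(pooling)
  jt_method <- match.arg(jt_method)
  questions <- match.arg(questions, several.ok = TRUE)
  strata <- match.arg(strata, several.ok = TRUE)
  if (!length(variables) || !all(variables %in% analysis_variables()))
    stop("`variables` must be a nonempty subset of analysis_variables()")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (rmpe <= 0) stop("`rmpe` must be > 0")
  structure(list(pooling = pooling, questions = questions, strata = strata,
                 variables = variables, alpha = alpha, rmpe = rmpe,
                 B = as.integer(B), n_perm = as.integer(n_perm),
                 jt_method = jt_method, seed = as.integer(seed)),
            class = "analysis_config")
}

question_column <- function(q) {
  switch(q, therapy_aims = "therapy_aims_text", why_online = "why_online_text")
}
motivation_column <- function(q) {
  switch(q, therapy_aims = "motivation_aims", why_online = "motivation_online")
}

#' Run the full motivation analysis
#'
#' For every requested question and age stratum: scores each patient's
#' answer, groups variables by motivation type, and runs the inference chain
#' (normality check, Jonckheere-Terpstra trend, Brown-Forsythe, Kendall
#' tau-b of the variable against the 0..3 SDT level code, composite
#' verdict). Separately correlates polarity with baseline severity,
#' completion rate (coded Low=0 < High=1 < Full=2) and the post-minus-pre
#' differentials, and fits the time-by-group mixed ANOVA per outcome and
#' question on the whole cohort. Cells that cannot be computed (empty
#' levels, too-small groups) are reported as degenerate and the run
#' continues. Deterministic for fixed cohort, lexicon and config.
#'
#' @param cohort Cohort data frame or path to a cohort CSV.
#' @param lex A [lexicon()] (or path to a directory of lexicon TSVs).
#' @param config An [analysis_config()].
#' @return Object of class `results_bundle` with elements `trend_grid`,
#'   `correlation_grid`, `anova_grid`, `completion_table`, `descriptives`,
#'   `polarity` (per-patient scores) and `meta` (config echo, seed,
#'   warnings, degenerate-cell log).
#' @export
run_analysis <- function(cohort, lex, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(lex))
    lex <- load_lexicon(file.path(lex, "valences.tsv"),
                        file.path(lex, "modifiers.tsv"),
                        file.path(lex, "negators.tsv"))
  stopifnot(inherits(lex, "bedmot_lexicon"))
  warnings_log <- character()
  degenerate_log <- list()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  # per-patient polarity for both questions
  polarity <- data.frame(id = cohort$id)
  for (q in c("therapy_aims", "why_online")) {
    sc <- score_statements(cohort[[question_column(q)]], lex, config$pooling)
    polarity[[paste0("polarity_", q)]] <- sc$polarity
  }
  completion_code <- as.integer(completion_category(
    cohort$sessions_completed, cohort$followup_done)) - 1L

  extract_variable <- function(sub, v, q) {
    switch(v,
      polarity = sub[[paste0(".polarity_", q)]],
      bedq_pre = sub$bedq_pre,
      edeq_pre = sub$edeq_pre,
      bmi_pre = sub$bmi,
      mdi_pre = sub$mdi_pre,
      vas_pre = sub$vas_pre,
      completion_rate = sub$.completion_code,
      bedq_diff = sub$bedq_post - sub$bedq_pre,
      edeq_diff = sub$edeq_post - sub$edeq_pre)
  }

  aug <- cohort
  aug$.completion_code <- completion_code
  for (q in c("therapy_aims", "why_online"))
    aug[[paste0(".polarity_", q)]] <- polarity[[paste0("polarity_", q)]]

  trend_rows <- list()
  corr_rows <- list()
  cell_i <- 0L
  for (q in config$questions) {
    for (s in config$strata) {
      sub <- switch(s, all = aug, adult = aug[aug$age_group == "adult", ],
                    young_adult = aug[aug$age_group == "young_adult", ])
      lev <- droplevels(factor(sub[[motivation_column(q)]],
                               levels = sdt_levels(), ordered = TRUE))
      lev_code <- as.integer(factor(as.character(lev), levels = sdt_levels())) - 1L
      n_empty <- 4L - nlevels(lev)
      if (n_empty > 0L)
        note(sprintf("%s/%s: %d empty motivation level(s) dropped", q, s, n_empty))
      for (v in config$variables) {
        cell_i <- cell_i + 1L
        vec <- extract_variable(sub, v, q)
        row <- data.frame(variable = v, question = q, age_group = s,
                          T_JT = NA_real_, p_TJT = NA_real_, F_BF = NA_real_,
                          p_FBF = NA_real_, tau_b = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          stars = NA_integer_, overall = NA)
        cell <- tryCatch({
          if (nlevels(lev) < 2L) stop("fewer than two nonempty motivation levels")
          jt <- jonckheere_terpstra(vec, lev, method = config$jt_method,
                                    n_perm = config$n_perm,
                                    seed = derive_seed(config$seed, cell_i))
          bf <- tryCatch(brown_forsythe(vec, lev), error = function(e) NULL)
          if (is.null(bf))
            note(sprintf("%s/%s/%s: Brown-Forsythe unavailable (group too small)",
                         v, q, s))
          tau <- kendall_tau_b(vec, lev_code, B = config$B,
                               seed = derive_seed(config$seed, 100000L + cell_i))
          verdict <- composite_decision(jt, bf, tau, config$alpha, config$rmpe)
          row$T_JT <- jt$z; row$p_TJT <- jt$p.value
          if (!is.null(bf)) { row$F_BF <- bf$F; row$p_FBF <- bf$p.value }
          if (!tau$degenerate) {
            row$tau_b <- tau$tau_b; row$ci_low <- tau$ci_low
            row$ci_high <- tau$ci_high
          }
          row$stars <- verdict$stars; row$overall <- verdict$overall
          row
        }, error = function(e) {
          degenerate_log[[length(degenerate_log) + 1L]] <<- list(
            variable = v, question = q, age_group = s,
            reason = conditionMessage(e))
          note(sprintf("degenerate cell %s/%s/%s: %s", v, q, s,
                       conditionMessage(e)))
          row
        })
        trend_rows[[length(trend_rows) + 1L]] <- cell
      }
      # polarity-vs-outcome correlation grid
      for (v in c("bedq_pre", "edeq_pre", "completion_rate",
                  "bedq_diff", "edeq_diff")) {
        cell_i <- cell_i + 1L
        pol <- sub[[paste0(".polarity_", q)]]
        out_v <- extract_variable(sub, v, q)
        tau <- tryCatch(
          kendall_tau_b(pol, out_v, B = config$B,
                        seed = derive_seed(config$seed, 200000L + cell_i)),
          error = function(e) NULL)
        corr_rows[[length(corr_rows) + 1L]] <- data.frame(
          variable = v, question = q, age_group = s,
          tau_b = if (!is.null(tau) && !tau$degenerate) tau$tau_b else NA_real_,
          ci_low = if (!is.null(tau) && !tau$degenerate) tau$ci_low else NA_real_,
          ci_high = if (!is.null(tau) && !tau$degenerate) tau$ci_high else NA_real_)
        if (is.null(tau) || tau$degenerate)
          note(sprintf("degenerate correlation cell %s/%s/%s", v, q, s))
      }
    }
  }

  anova_rows <- list()
  for (q in config$questions) {
    lev <- droplevels(factor(aug[[motivation_column(q)]],
                             levels = sdt_levels(), ordered = TRUE))
    for (out_v in c("bedq", "edeq", "mdi", "vas")) {
      pre <- aug[[paste0(out_v, "_pre")]]
      post <- aug[[paste0(out_v, "_post")]]
      an <- tryCatch(mixed_anova(pre, post, lev), error = function(e) {
        note(sprintf("degenerate ANOVA cell %s/%s: %s", q, out_v,
                     conditionMessage(e)))
        NULL
      })
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        question = q, outcome = out_v,
        numDF = if (is.null(an)) NA_integer_ else an$numDF,
        denDF = if (is.null(an)) NA_integer_ else an$denDF,
        F = if (is.null(an)) NA_real_ else an$F,
        p = if (is.null(an)) NA_real_ else an$p.value)
      if (!is.null(an) && an$n_dropped > 0L)
        note(sprintf("ANOVA %s/%s: %d incomplete pre/post pair(s) excluded",
                     q, out_v, an$n_dropped))
    }
  }

  structure(list(
    trend_grid = do.call(rbind, trend_rows),
    correlation_grid = do.call(rbind, corr_rows),
    anova_grid = do.call(rbind, anova_rows),
    completion_table = completion_table(cohort),
    descriptives = descriptives(cohort),
    polarity = polarity,
    meta = list(config = unclass(config), seed = config$seed,
                pooling = if (config$pooling == "gmean")
                  "partitioned_signed_gmean" else config$pooling,
                n = nrow(cohort),
                package_version = as.character(utils::packageVersion("bedmot")),
                warnings = warnings_log,
                degenerate_cells = degenerate_log)),
    class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("bedmot results bundle: n =", x$meta$n, "\n")
  cat("  trend grid:", nrow(x$trend_grid), "cells;",
      sum(x$trend_grid$overall, na.rm = TRUE), "overall significant\n")
  cat("  correlation grid:", nrow(x$correlation_grid), "cells\n")
  cat("  anova grid:", nrow(x$anova_grid), "cells\n")
  if (length(x$meta$warnings))
    cat("  warnings:", length(x$meta$warnings), "(see meta$warnings)\n")
  invisible(x)
}

#' Format p-values the way the result tables print them
#'
#' Scientific notation with one decimal below 1e-3 (e.g. `3.0e-07`), two
#' decimals otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 1e-3, formatC(p, format = "e", digits = 1),
                sprintf("%.2f", p)))
}

#' Write a results bundle to disk
#'
#' Emits CSV grids (trend, correlation, anova, completion), a descriptives
#' CSV/JSON mirror, one JSON file with the full bundle at full numeric
#' precision, and a plain-text run log (seed logged first). In the CSV
#' grids, p-value columns use [format_p()].
#'
#' @param bundle A [run_analysis()] result.
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json", "log")`.
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, out_dir, formats = c("csv", "json", "log")) {
  stopifnot(inherits(bundle, "results_bundle"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!nrow(bundle$trend_grid)) stop("empty trend grid; nothing to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("csv" %in% formats) {
    tg <- bundle$trend_grid
    tg$p_TJT <- format_p(tg$p_TJT); tg$p_FBF <- format_p(tg$p_FBF)
    ag <- bundle$anova_grid
    ag$p <- format_p(ag$p)
    grids <- list(trend_grid.csv = tg,
                  correlation_grid.csv = bundle$correlation_grid,
                  anova_grid.csv = ag,
                  completion_table.csv = bundle$completion_table)
    for (nm in names(grids)) {
      p <- file.path(out_dir, nm)
      write.csv(grids[[nm]], p, row.names = FALSE, na = "")
      paths <- c(paths, p)
    }
    p <- file.path(out_dir, "descriptives.csv")
    d <- bundle$descriptives
    write.csv(data.frame(statistic = c("n", "n_male", "pct_male", "age_mean",
                                       "age_min", "age_max", "bmi_mean",
                                       "mdi_mean", "n_young_adults"),
                         value = c(d$n, d$n_male, d$pct_male, d$age$mean,
                                   d$age$min, d$age$max, d$bmi$mean,
                                   d$mdi$mean, d$n_young_adults)),
              p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(out_dir, "bundle.json")
    jsonlite::write_json(unclass(bundle), p, auto_unbox = TRUE, digits = NA,
                         na = "null", force = TRUE)
    paths <- c(paths, p)
  }
  if ("log" %in% formats) {
    p <- file.path(out_dir, "run.log")
    lines <- c(sprintf("seed: %d", bundle$meta$seed),
               sprintf("pooling: %s", bundle$meta$pooling),
               sprintf("n: %d", bundle$meta$n),
               sprintf("package: bedmot %s", bundle$meta$package_version),
               sprintf("warning: %s", bundle$meta$warnings))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
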