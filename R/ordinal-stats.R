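# The inference chain for ordered motivation-type groupings: a signed
# Jonckheere-Terpstra trend test, the Brown-Forsythe homoscedasticity test,
# tie-aware Kendall tau-b with bootstrap confidence intervals, the dual
# minimal-practical-effect-size rule, the composite verdict, and the
# time-by-group mixed ANOVA for pre/post outcomes.

as_ordered_groups <- function(x, g, min_per_group = 1L) {
  if (length(x) != length(g)) stop("`x` and `g` must have equal length")
  g <- if (is.factor(g)) g else factor(g)
  keep <- !is.na(x) & !is.na(g)
  n_drop <- sum(!keep)
  x <- x[keep]; g <- g[keep]
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < min_per_group))
    stop(sprintf("group '%s' has fewer than %d observation(s)",
                 names(sizes)[which(sizes < min_per_group)[1]], min_per_group))
  list(x = x, g = g, sizes = as.integer(sizes), n = length(x), n_dropped = n_drop)
}

# Tie-corrected null variance of the raw JT statistic.
jt_null_moments <- function(x, sizes) {
  n <- sum(sizes)
  tj <- as.integer(table(x))
  mu <- (n^2 - sum(sizes^2)) / 4
  A <- n * (n - 1) * (2 * n + 5) -
    sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  B <- sum(sizes * (sizes - 1) * (sizes - 2)) * sum(tj * (tj - 1) * (tj - 2))
  C <- sum(sizes * (sizes - 1)) * sum(tj * (tj - 1))
  v <- A / 72 +
    (if (n > 2) B / (36 * n * (n - 1) * (n - 2)) else 0) +
    C / (8 * n * (n - 1))
  list(mu = mu, sigma = sqrt(max(v, 0)))
}

# All distinct assignments of n observations to groups of the given sizes,
# as a list of 0-based group-code vectors. Caller guards the count.
enumerate_assignments <- function(n, sizes) {
  res <- list()
  rec <- function(avail, k, codes) {
    if (k == length(sizes)) {
      codes[avail] <- k - 1L
      res[[length(res) + 1L]] <<- codes
      return(invisible())
    }
    for (pick in utils::combn(avail, sizes[k], simplify = FALSE)) {
      codes2 <- codes
      codes2[pick] <- k - 1L
      rec(setdiff(avail, pick), k + 1L, codes2)
    }
  }
  rec(seq_len(n), 1L, integer(n))
  res
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests the null of identical distributions against an ordered alternative
#' over the (ordered factor) grouping. The raw statistic is the sum over
#' group pairs, in the hypothesised ascending order, of Mann-Whitney counts
#' with ties counted 0.5. The sign convention reports ascending trends as
#' positive `z`. P-values are two-sided; the sign is carried separately.
#'
#' With `method = "normal_approx"` the statistic is standardised by its
#' tie-corrected null variance. With `method = "permutation"` observations
#' are relabelled across groups keeping group sizes fixed: exhaustively when
#' the number of distinct arrangements is at most `exhaustive_limit`,
#' otherwise by `n_perm` seeded Monte-Carlo relabellings.
#'
#' @param x Numeric observations.
#' @param g Grouping; coerced to factor, level order = hypothesised ascending
#'   order. Every level must be nonempty.
#' @param method `"normal_approx"` or `"permutation"`.
#' @param n_perm Number of Monte-Carlo relabellings.
#' @param seed Optional integer seed for the Monte-Carlo branch.
#' @param exhaustive_limit Arrangement count up to which the permutation
#'   distribution is enumerated exactly.
#' @return Object of class `jt_test`: `statistic` (raw J), `z`, `p.value`,
#'   `method`, `n_perm`, `seed`, `exhaustive`, `sizes`.
#' @export
jonckheere_terpstra <- function(x, g, method = c("normal_approx", "permutation"),
                                n_perm = 2000L, seed = NULL,
                                exhaustive_limit = 1e5) {
  method <- match.arg(method)
  og <- as_ordered_groups(x, g)
  codes <- as.integer(og$g) - 1L
  J <- jt_statistic_cpp(og$x, codes)
  mom <- jt_null_moments(og$x, og$sizes)
  if (mom$sigma == 0) {
    # all observations identical: no evidence either way
    return(structure(list(statistic = J, z = 0, p.value = 1, method = method,
                          n_perm = NULL, seed = seed, exhaustive = FALSE,
                          sizes = og$sizes, n_dropped = og$n_dropped),
                     class = "jt_test"))
  }
  z <- (J - mom$mu) / mom$sigma
  eps <- 1e-9
  if (method == "normal_approx") {
    p <- 2 * pnorm(-abs(z))
    n_used <- NULL; exhaustive <- FALSE
  } else {
    n_arr <- exp(lgamma(og$n + 1) - sum(lgamma(og$sizes + 1)))
    if (n_arr <= exhaustive_limit) {
      assign_l <- enumerate_assignments(og$n, og$sizes)
      Jstar <- vapply(assign_l, function(cd) jt_statistic_cpp(og$x, cd),
                      numeric(1))
      p <- mean(abs(Jstar - mom$mu) >= abs(J - mom$mu) - eps)
      n_used <- length(assign_l); exhaustive <- TRUE
    } else {
      Jstar <- with_seed(seed, jt_perm_cpp(og$x, codes, as.integer(n_perm)))
      p <- (1 + sum(abs(Jstar - mom$mu) >= abs(J - mom$mu) - eps)) / (n_perm + 1)
      n_used <- as.integer(n_perm); exhaustive <- FALSE
    }
  }
  structure(list(statistic = J, z = z, p.value = min(p, 1), method = method,
                 n_perm = n_used, seed = seed, exhaustive = exhaustive,
                 sizes = og$sizes, n_dropped = og$n_dropped),
            class = "jt_test")
}

#' @export
print.jt_test <- function(x, ...) {
  cat(sprintf("Jonckheere-Terpstra: J = %.1f, z = %.3f, p = %.4g (%s%s)\n",
              x$statistic, x$z, x$p.value, x$method,
              if (isTRUE(x$exhaustive)) ", exhaustive" else ""))
  invisible(x)
}

#' Brown-Forsythe test of homogeneity of variance
#'
#' One-way ANOVA F on the absolute deviations of each observation from its
#' group median. Groups with identical spread yield small F; the
#' homoscedasticity reading used downstream is `p > alpha`.
#'
#' @param x Numeric observations.
#' @param g Grouping factor; every group needs at least two observations.
#' @return Object of class `bf_test`: `F`, `df1`, `df2`, `p.value`.
#' @export
brown_forsythe <- function(x, g) {
  og <- as_ordered_groups(x, g, min_per_group = 2L)
  med <- tapply(og$x, og$g, median)
  z <- abs(og$x - med[as.integer(og$g)])
  k <- length(og$sizes)
  df1 <- k - 1L; df2 <- og$n - k
  if (max(z) - min(z) < .Machine$double.eps^0.5) {
    # all deviations equal (e.g. constant groups): no spread signal at all
    return(structure(list(F = 0, df1 = df1, df2 = df2, p.value = 1),
                     class = "bf_test"))
  }
  tab <- anova(lm(z ~ og$g))
  structure(list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
                 p.value = tab$`Pr(>F)`[1]),
            class = "bf_test")
}

#' @export
print.bf_test <- function(x, ...) {
  cat(sprintf("Brown-Forsythe: F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p.value))
  invisible(x)
}

#' Kendall's tau-b with a seeded bootstrap confidence interval
#'
#' Tie-aware rank correlation \eqn{\tau_B = (C - D) / \sqrt{(n_0 - n_1)(n_0 -
#' n_2)}}, the appropriate effect-size measure for heavily tied ordinal data.
#' The 95% confidence interval is a percentile bootstrap over `(x, y)` pairs
#' (`ci_method = "bootstrap_percentile"`, the default) or the large-sample
#' normal approximation (`"normal_approx"`). If either margin is constant
#' the coefficient is undefined and a degenerate result is returned rather
#' than a number. Bootstrap draws that are themselves degenerate are dropped
#' and counted.
#'
#' @param x,y Numeric vectors of equal length (at least 3 after pairwise
#'   deletion of missing values).
#' @param B Number of bootstrap resamples.
#' @param seed Optional integer seed for the bootstrap.
#' @param ci_method `"bootstrap_percentile"` or `"normal_approx"`.
#' @param conf Confidence level.
#' @return Object of class `tau_result`: `tau_b`, `ci_low`, `ci_high`, `n`,
#'   `ci_method`, `B`, `seed`, `degenerate`, `reason`,
#'   `n_degenerate_draws`, `n_dropped`.
#' @export
kendall_tau_b <- function(x, y, B = 2000L, seed = NULL,
                          ci_method = c("bootstrap_percentile", "normal_approx"),
                          conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  degen <- function(reason)
    structure(list(tau_b = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   n = n, ci_method = ci_method, B = B, seed = seed,
                   degenerate = TRUE, reason = reason,
                   n_degenerate_draws = NA_integer_, n_dropped = n_dropped),
              class = "tau_result")
  if (length(unique(x)) == 1L) return(degen("all x values tied"))
  if (length(unique(y)) == 1L) return(degen("all y values tied"))
  tau <- cor(x, y, method = "kendall")
  alpha <- 1 - conf
  if (ci_method == "normal_approx") {
    se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
    ci <- tau + c(-1, 1) * qnorm(1 - alpha / 2) * se
    n_bad <- 0L
  } else {
    taus <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]; yb <- y[idx]
        if (length(unique(xb)) == 1L || length(unique(yb)) == 1L)
          return(NA_real_)
        cor(xb, yb, method = "kendall")
      }, numeric(1))
    })
    n_bad <- sum(is.na(taus))
    ci <- unname(quantile(taus, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  }
  out <- structure(list(tau_b = tau, ci_low = ci[1], ci_high = ci[2], n = n,
                        ci_method = ci_method, B = if (ci_method == "bootstrap_percentile") as.integer(B) else NULL,
                        seed = seed, degenerate = FALSE, reason = NULL,
                        n_degenerate_draws = n_bad, n_dropped = n_dropped),
                   class = "tau_result")
  if (!is.na(ci[1]) && (ci[1] > tau || ci[2] < tau))
    attr(out, "ci_excludes_estimate") <- TRUE
  out
}

#' @export
print.tau_result <- function(x, ...) {
  if (x$degenerate)
    cat("Kendall tau-b: degenerate (", x$reason, ")\n", sep = "")
  else
    cat(sprintf("Kendall tau-b = %.3f, 95%% CI (%.3f, %.3f), n = %d [%s]\n",
                x$tau_b, x$ci_low, x$ci_high, x$n, x$ci_method))
  invisible(x)
}

#' Dual effect-size rule on a Kendall tau-b result
#'
#' An association counts as a practically significant effect when (a) the
#' point estimate lies outside the recommended minimal practical effect size
#' band \eqn{[-\mathrm{RMPE}, +\mathrm{RMPE}]}, and (b) the 95% confidence
#' interval is not "inversely significant": its lower and upper bounds may
#' not simultaneously reach \eqn{-\mathrm{RMPE}} and \eqn{+\mathrm{RMPE}}.
#' Stars grade \eqn{|\hat\tau|} against the ladder 0.2 (minimal), 0.5
#' (moderate), 0.8 (strong), and are zero whenever the rule fails.
#'
#' @param tau A [kendall_tau_b()] result.
#' @param rmpe Recommended minimal practical effect size (default 0.2).
#' @return List with `effect_ok`, `stars` (0..3) and `reason` (when not ok).
#' @export
effect_size_verdict <- function(tau, rmpe = 0.2) {
  stopifnot(inherits(tau, "tau_result"), rmpe > 0)
  if (tau$degenerate)
    return(list(effect_ok = FALSE, stars = 0L,
                reason = paste("degenerate tau:", tau$reason)))
  inverse_risk <- !is.na(tau$ci_low) && !is.na(tau$ci_high) &&
    tau$ci_low <= -rmpe && tau$ci_high >= rmpe
  ok <- abs(tau$tau_b) > rmpe && !inverse_risk
  list(effect_ok = ok,
       stars = if (ok) sum(abs(tau$tau_b) > c(0.2, 0.5, 0.8)) else 0L,
       reason = if (ok) NULL else if (inverse_risk)
         "confidence interval reaches both significance bounds"
       else "point estimate within the RMPE band")
}

#' Combine trend, variance and effect-size results into one verdict
#'
#' A grouping is flagged overall significant only when both the stochastic
#' dominance test rejects (`p <= alpha`) and the dual effect-size rule
#' passes. Homoscedasticity (`p > alpha` on the Brown-Forsythe test) is
#' reported alongside and, together with a rejecting trend test, licenses
#' extending the ordering statement from mean ranks to group medians.
#'
#' @param trend A [jonckheere_terpstra()] result.
#' @param variance A [brown_forsythe()] result, or `NULL` if unavailable.
#' @param tau A [kendall_tau_b()] result.
#' @param alpha Significance level for the p-value based tests.
#' @param rmpe Minimal practical effect size for [effect_size_verdict()].
#' @return Object of class `significance_verdict` with fields
#'   `stochastic_ok`, `homoscedastic`, `effect_ok`, `stars` (effect-size
#'   ladder), `p_stars` (0.05/0.01/0.001 ladder), `overall`,
#'   `medians_extend`.
#' @export
composite_decision <- function(trend, variance, tau, alpha = 0.05, rmpe = 0.2) {
  stopifnot(inherits(trend, "jt_test"), inherits(tau, "tau_result"))
  stochastic_ok <- trend$p.value <= alpha
  homoscedastic <- if (is.null(variance)) NA else variance$p.value > alpha
  ev <- effect_size_verdict(tau, rmpe)
  structure(list(stochastic_ok = stochastic_ok,
                 homoscedastic = homoscedastic,
                 effect_ok = ev$effect_ok,
                 stars = ev$stars,
                 p_stars = sum(trend$p.value <= c(0.05, 0.01, 0.001)),
                 overall = stochastic_ok && ev$effect_ok,
                 medians_extend = isTRUE(stochastic_ok) && isTRUE(homoscedastic)),
            class = "significance_verdict")
}

#' @export
print.significance_verdict <- function(x, ...) {
  cat(sprintf(
    "Verdict: overall %s (trend %s, effect %s%s; homoscedastic: %s)\n",
    if (x$overall) "SIGNIFICANT" else "not significant",
    if (x$stochastic_ok) "ok" else "ns",
    if (x$effect_ok) "ok" else "ns",
    if (x$stars) paste0(", ", strrep("*", x$stars)) else "",
    x$homoscedastic))
  invisible(x)
}

#' Mixed (split-plot) ANOVA for the time-by-group interaction
#'
#' Two-occasion repeated-measures ANOVA with time as the within-subject
#' factor and group as the between-subject factor, via the classical
#' sums-of-squares decomposition (`aov` with a subject error stratum).
#' Incomplete pre/post pairs are dropped (and counted); every group must
#' retain at least two complete pairs. With two occasions the interaction
#' test is equivalent to a between-group one-way ANOVA on the change scores.
#'
#' @param pre,post Numeric vectors of paired scores per subject.
#' @param group Between-subject grouping factor (at least two groups).
#' @return Object of class `anova_result` for the interaction: `effect`,
#'   `F`, `numDF`, `denDF`, `p.value`, `n`, `n_dropped`.
#' @export
mixed_anova <- function(pre, post, group) {
  if (length(pre) != length(post) || length(pre) != length(group))
    stop("`pre`, `post` and `group` must have equal length")
  g <- if (is.factor(group)) group else factor(group)
  keep <- !is.na(pre) & !is.na(post) & !is.na(g)
  n_dropped <- sum(!keep)
  pre <- pre[keep]; post <- post[keep]; g <- g[keep]
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < 2L))
    stop(sprintf("group '%s' has fewer than 2 complete pre/post pairs",
                 names(sizes)[which(sizes < 2L)[1]]))
  g <- droplevels(g)
  n <- length(pre); k <- length(sizes)
  chg <- post - pre
  if (max(chg) - min(chg) < .Machine$double.eps^0.5 * max(1, max(abs(pre)))) {
    # constant change scores (e.g. identical pre and post): no within-subject
    # variance to partition, so the interaction carries no signal
    return(structure(list(effect = "time:group", F = 0, numDF = k - 1L,
                          denDF = n - k, p.value = 1, n = n,
                          n_dropped = n_dropped),
                     class = "anova_result"))
  }
  d <- data.frame(
    y = c(pre, post),
    time = factor(rep(c("pre", "post"), each = n), levels = c("pre", "post")),
    grp = factor(rep(g, 2L)),
    id = factor(rep(seq_len(n), 2L)))
  fit <- aov(y ~ grp * time + Error(id), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  int_row <- grep("grp:time", rownames(tab))
  res_row <- grep("Residuals", rownames(tab))
  Fv <- tab[int_row, "F value"]
  pv <- tab[int_row, "Pr(>F)"]
  if (!is.finite(Fv)) { Fv <- 0; pv <- 1 }  # zero within-subject variance
  structure(list(effect = "time:group", F = Fv,
                 numDF = tab[int_row, "Df"], denDF = tab[res_row, "Df"],
                 p.value = pv, n = n, n_dropped = n_dropped),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$effect, x$numDF, x$denDF, x$F, x$p.value))
  invisible(x)
}

#' Shapiro-Wilk normality check with detrended QQ deviations
#'
#' @param x Numeric sample, 3 to 5000 observations, non-constant.
#' @return List with `W`, `p.value` and `detrended_qq` (ordered sample minus
#'   fitted normal quantiles).
#' @export
normality_check <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) stop("sample size must lie in 3..5000")
  if (sd(x) == 0) stop("sample is constant; normality check undefined")
  sw <- shapiro.test(x)
  fitted_q <- qnorm(ppoints(n), mean(x), sd(x))
  list(W = unname(sw$statistic), p.value = sw$p.value,
       detrended_qq = sort(x) - fitted_q)
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' Plain covariance-based alpha, provided for synthetic-data checks of
#' multi-item instruments.
#'
#' @param items Numeric matrix or data frame, one column per item.
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2L) stop("need at least two items")
  (k / (k - 1)) * (1 - sum(apply(items, 2, var)) / var(rowSums(items)))
}
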