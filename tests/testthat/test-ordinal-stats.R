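test_that("JT permutation p equals exhaustive enumeration on a small instance", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- factor(rep(1:3, each = 2))
  jt <- jonckheere_terpstra(x, g, method = "permutation", seed = 1)
  expect_true(jt$exhaustive)
  expect_gt(jt$z, 0)
  # independent oracle: enumerate all 6! index permutations
  expect_equal(jt$p.value, jt_exhaustive_oracle(x, g))
  # same with ties present
  xt <- c(1, 2, 2, 3, 3, 4)
  expect_equal(jonckheere_terpstra(xt, g, method = "permutation")$p.value,
               jt_exhaustive_oracle(xt, g))
})

test_that("JT statistic matches the brute-force pair count and sign convention", {
  set.seed(7)
  for (i in 1:25) {
    sizes <- sample(2:6, sample(2:4, 1), replace = TRUE)
    g <- factor(rep(seq_along(sizes), sizes))
    x <- round(rnorm(sum(sizes)), 1)  # rounding forces ties
    jt <- jonckheere_terpstra(x, g)
    expect_equal(jt$statistic, jt_oracle(x, g))
    # reversing the hypothesised order negates z exactly
    rev_g <- factor(g, levels = rev(levels(g)))
    expect_equal(jonckheere_terpstra(x, rev_g)$z, -jt$z)
  }
})

test_that("JT handles degenerate and invalid groupings", {
  g <- factor(rep(1:2, each = 3))
  jt <- jonckheere_terpstra(rep(4, 6), g)
  expect_equal(jt$z, 0)
  expect_equal(jt$p.value, 1)
  expect_error(jonckheere_terpstra(1:3, factor(rep(1, 3))), "two groups")
  empty_lvl <- factor(c(1, 1, 2, 2), levels = 1:3)
  expect_error(jonckheere_terpstra(1:4, empty_lvl), "fewer than")
})

test_that("JT normal approximation tracks the permutation p under the null", {
  set.seed(42)
  diffs <- replicate(25, {
    x <- rnorm(45)
    g <- factor(rep(1:3, each = 15))
    pn <- jonckheere_terpstra(x, g, method = "normal_approx")$p.value
    pp <- jonckheere_terpstra(x, g, method = "permutation", n_perm = 20000,
                              seed = sample.int(1e6, 1))$p.value
    abs(pn - pp)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("Brown-Forsythe agrees with the median-centred Levene cross-check", {
  skip_if_not_installed("car")
  set.seed(11)
  for (i in 1:10) {
    g <- factor(rep(1:3, times = sample(5:15, 3, replace = TRUE)))
    x <- rnorm(length(g), sd = as.integer(g))
    bf <- brown_forsythe(x, g)
    lev <- car::leveneTest(x, g, center = median)
    expect_equal(bf$F, lev$`F value`[1])
    expect_equal(bf$p.value, lev$`Pr(>F)`[1])
    expect_equal(bf$df1, lev$Df[1])
    expect_equal(bf$df2, lev$Df[2])
  }
})

test_that("Brown-Forsythe degenerate and power behaviour", {
  g <- factor(rep(1:2, each = 3))
  bf <- brown_forsythe(c(2, 2, 2, 5, 5, 5), g)
  expect_equal(bf$F, 0)
  expect_equal(bf$p.value, 1)
  expect_error(brown_forsythe(c(1, 2, 3), factor(c(1, 1, 2))), "fewer than 2")
  # a ten-fold spread difference at n = 30 per group is detected
  set.seed(3)
  rejections <- replicate(40, {
    x <- c(rnorm(30), rnorm(30, sd = 10))
    brown_forsythe(x, factor(rep(1:2, each = 30)))$p.value < 0.05
  })
  expect_gte(mean(rejections), 0.95)
})

test_that("Kendall tau-b equals the brute-force pair classifier", {
  expect_equal(kendall_tau_b(1:5, 2 * (1:5), B = 50)$tau_b, 1)
  expect_equal(kendall_tau_b(1:5, -(1:5), B = 50)$tau_b, -1)
  expect_equal(kendall_tau_b(c(1, 1, 2, 3), c(2, 1, 1, 3), B = 50)$tau_b,
               tau_b_oracle(c(1, 1, 2, 3), c(2, 1, 1, 3)))
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    expect_equal(kendall_tau_b(x, y, B = 10)$tau_b, tau_b_oracle(x, y))
  }
})

test_that("tau-b invariances: antisymmetry and monotone transforms", {
  set.seed(5)
  x <- rnorm(30)
  y <- sample(0:3, 30, replace = TRUE)
  t1 <- kendall_tau_b(x, y, B = 10)$tau_b
  expect_equal(kendall_tau_b(x, -y, B = 10)$tau_b, -t1)
  expect_equal(kendall_tau_b(exp(x), y, B = 10)$tau_b, t1)
  expect_equal(kendall_tau_b(x, 2 * y + 1, B = 10)$tau_b, t1)
})

test_that("tau-b bootstrap CI is seeded, ordered, and flags degeneracy", {
  set.seed(2)
  x <- rnorm(40)
  y <- x + rnorm(40)
  a <- kendall_tau_b(x, y, B = 500, seed = 99)
  b <- kendall_tau_b(x, y, B = 500, seed = 99)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$tau_b)
  expect_gte(a$ci_high, a$tau_b)
  d <- kendall_tau_b(rep(1, 10), 1:10, B = 50)
  expect_true(d$degenerate)
  expect_true(is.na(d$tau_b))
  expect_error(kendall_tau_b(1:3, 1:4), "equal length")
})

test_that("dual effect-size rule applies the RMPE threshold and CI guard", {
  mk_tau <- function(tau, lo, hi)
    structure(list(tau_b = tau, ci_low = lo, ci_high = hi, n = 100,
                   degenerate = FALSE, reason = NULL), class = "tau_result")
  v <- effect_size_verdict(mk_tau(0.31, 0.20, 0.42))
  expect_true(v$effect_ok)
  expect_equal(v$stars, 1L)
  expect_false(effect_size_verdict(mk_tau(0.15, -0.1, 0.4))$effect_ok)
  # inverse-significance guard: both CI bounds reach the threshold
  v2 <- effect_size_verdict(mk_tau(0.25, -0.25, 0.55))
  expect_false(v2$effect_ok)
  expect_match(v2$reason, "both")
  # stars ladder is non-decreasing in |tau|
  stars <- vapply(c(0.25, 0.55, 0.85),
                  function(t) effect_size_verdict(mk_tau(t, t - 0.1, t + 0.1))$stars,
                  integer(1))
  expect_equal(stars, 1:3)
  dg <- structure(list(tau_b = NA_real_, degenerate = TRUE, reason = "ties"),
                  class = "tau_result")
  dv <- effect_size_verdict(dg)
  expect_false(dv$effect_ok)
})

test_that("composite verdict is the conjunction of trend and effect", {
  mk_jt <- function(p) structure(list(z = 2, p.value = p), class = "jt_test")
  mk_bf <- function(p) structure(list(F = 1, p.value = p), class = "bf_test")
  mk_tau <- function(tau) structure(list(tau_b = tau, ci_low = tau - 0.1,
                                         ci_high = tau + 0.1, degenerate = FALSE,
                                         reason = NULL), class = "tau_result")
  expect_true(composite_decision(mk_jt(0.001), mk_bf(0.5), mk_tau(0.31))$overall)
  expect_false(composite_decision(mk_jt(0.2), mk_bf(0.5), mk_tau(0.31))$overall)
  expect_false(composite_decision(mk_jt(0.01), mk_bf(0.5), mk_tau(0.1))$overall)
  # homoscedasticity licenses the median extension only with a rejecting trend
  v <- composite_decision(mk_jt(0.001), mk_bf(0.5), mk_tau(0.31))
  expect_true(v$medians_extend)
  expect_false(composite_decision(mk_jt(0.001), mk_bf(0.01), mk_tau(0.31))$medians_extend)
  expect_equal(v$p_stars, 3L)
})

test_that("mixed ANOVA interaction matches the change-score ANOVA cross-check", {
  set.seed(21)
  g <- factor(rep(letters[1:3], each = 20))
  pre <- rnorm(60, 20, 4)
  post <- pre - 5 + rnorm(60, 0, 3) + (g == "c") * 2
  ma <- mixed_anova(pre, post, g)
  # with two occasions the interaction test equals one-way ANOVA on changes
  cs <- anova(lm(I(post - pre) ~ g))
  expect_equal(ma$F, cs$`F value`[1])
  expect_equal(ma$p.value, cs$`Pr(>F)`[1])
  expect_equal(ma$numDF, 2L)
  expect_equal(ma$denDF, 57L)
})

test_that("mixed ANOVA degenerate inputs and missing pairs", {
  g <- factor(rep(1:2, each = 5))
  pre <- c(1:5, 6:10)
  ma <- mixed_anova(pre, pre, g)  # identical pre and post everywhere
  expect_equal(ma$F, 0)
  expect_equal(ma$p.value, 1)
  post <- pre - 1
  post[1] <- NA
  ma2 <- mixed_anova(pre, post, g)
  expect_equal(ma2$n_dropped, 1L)
  expect_equal(ma2$n, 9L)
  expect_error(mixed_anova(1:4, c(1, 2, NA, NA), factor(c(1, 1, 2, 2))),
               "fewer than 2")
})

test_that("normality check separates normal from skewed samples", {
  set.seed(31)
  p_norm <- replicate(40, normality_check(rnorm(100))$p.value)
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- replicate(40, normality_check(rexp(100))$p.value)
  expect_gte(mean(p_exp < 0.05), 0.95)
  nc <- normality_check(rnorm(50))
  expect_length(nc$detrended_qq, 50)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(1:2), "3..5000")
})

test_that("Cronbach's alpha matches its closed form on constructed items", {
  set.seed(8)
  latent <- rnorm(200)
  items <- sapply(1:5, function(i) latent + rnorm(200, sd = 1))
  k <- 5
  expected <- (k / (k - 1)) * (1 - sum(apply(items, 2, var)) / var(rowSums(items)))
  expect_equal(cronbach_alpha(items), expected)
  expect_gt(cronbach_alpha(items), 0.6)
  expect_error(cronbach_alpha(items[, 1, drop = FALSE]), "two items")
})
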