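make_long <- function(n = 6, seed = 1, effect_b = 0) {
  set.seed(seed)
  d <- expand.grid(participant = sprintf("s%02d", seq_len(n)),
                   production = c("MA", "MO"), soa = c(0.8, 1.6, 3.2),
                   KEEP.OUT.ATTRS = FALSE)
  d$value <- rnorm(nrow(d), sd = 0.5) + rep(rnorm(n), 6) +
    effect_b * as.numeric(factor(d$soa))
  d
}

test_that("repeated-measures ANOVA matches the aov error-strata oracle", {
  for (seed in 1:3) {
    d <- make_long(n = 5, seed = seed, effect_b = 0.3)
    mine <- rm_anova_2x3(d)
    ref <- aov_oracle(d)
    for (nm in c("A", "B", "AB")) {
      expect_equal(mine[[nm]]$ss_effect, ref[[nm]]$ss, tolerance = 1e-8)
      expect_equal(mine[[nm]]$ss_error, ref[[nm]]$ss_err, tolerance = 1e-8)
      expect_equal(mine[[nm]]$F, ref[[nm]]$F, tolerance = 1e-8)
      expect_equal(mine[[nm]]$p, ref[[nm]]$p, tolerance = 1e-8)
    }
  }
})

test_that("ANOVA sums of squares are conserved", {
  d <- make_long(n = 7, seed = 11)
  a <- rm_anova_2x3(d)
  expect_equal(sum(a$strata$ss_all), a$strata$ss_total, tolerance = 1e-8)
})

test_that("a 2-level within factor reduces to the squared paired t", {
  d <- make_long(n = 8, seed = 4)
  a <- rm_anova_2x3(d)
  agg <- stats::aggregate(value ~ participant + production, d, mean)
  ma <- agg$value[agg$production == "MA"]
  mo <- agg$value[agg$production == "MO"]
  tt <- paired_contrast(ma, mo)
  expect_equal(a$A$F, tt$t^2, tolerance = 1e-10)
  expect_equal(a$A$p, tt$p, tolerance = 1e-10)
})

test_that("a pure additive subject + effect model gives partial eta squared of 1", {
  d <- expand.grid(participant = sprintf("s%d", 1:4),
                   production = c("MA", "MO"), soa = c(0.8, 1.6, 3.2))
  d$value <- rep(c(1, 2, 4, 8), 6) + (d$production == "MA") * 3
  a <- rm_anova_2x3(d)
  expect_equal(a$A$partial_eta_sq, 1)
})

test_that("ANOVA validates completeness of the design", {
  d <- make_long(n = 4, seed = 2)
  expect_error(rm_anova_2x3(d[-1, ]), "complete and balanced")
  expect_error(rm_anova_2x3(make_long(n = 2)), ">= 3 participants")
})

test_that("Greenhouse-Geisser epsilon spans its theoretical range", {
  # compound symmetry: sphericity holds, epsilon = 1
  cs <- diag(3) * 2 + 1
  expect_equal(gg_epsilon(cs), 1)
  expect_identical(gg_epsilon(diag(2)), 1)   # k = 2 is trivially spherical
  # all contrast variance in one direction: the 1/(k-1) lower bound
  v <- c(1, 0, -1)
  degenerate <- outer(v, v) + diag(3) * 1e-12
  expect_equal(gg_epsilon(degenerate), 0.5, tolerance = 1e-6)
})

test_that("Mauchly's test matches the stats::mauchly.test oracle", {
  set.seed(19)
  for (i in 1:3) {
    y <- matrix(rnorm(21 * 3), 21, 3) %*% matrix(rnorm(9), 3, 3)
    mine <- mauchly_sphericity(y)
    ref <- stats::mauchly.test(stats::lm(y ~ 1), X = ~1)
    expect_equal(mine$W, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired contrasts match hand-worked arithmetic and are antisymmetric", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.9)
  y <- c(4.9, 4.1, 5.2, 5.6, 5.0)
  d <- x - y
  r <- paired_contrast(x, y)
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$d, mean(d) / sd(d), tolerance = 1e-12)
  expect_identical(r$df, 4L)
  expect_equal(r$p, stats::t.test(x, y, paired = TRUE)$p.value, tolerance = 1e-12)
  flipped <- paired_contrast(y, x)
  expect_equal(flipped$t, -r$t)
  expect_equal(flipped$d, -r$d)
  same <- paired_contrast(x, x + c(1, -1, 1, -1, 1))
  expect_equal(2 * stats::pt(abs(same$t), 4, lower.tail = FALSE), same$p)
  expect_error(paired_contrast(x, x), "zero difference variance")
})

test_that("paired contrast holds its nominal type-I error under the null", {
  set.seed(123)
  rejections <- mean(vapply(seq_len(2000), function(i) {
    d <- rnorm(21)
    paired_contrast(d, rep(0, 21))$p < 0.05
  }, TRUE))
  expect_lt(abs(rejections - 0.05), 0.01)
})

test_that("BH adjustment reproduces worked three-contrast families", {
  # reported as 0.014 / 0.041 at two-decimal-of-a-percent precision
  expect_equal(bh_adjust(c(0.473, 0.009, 0.005)),
               c(0.473, 0.0135, 0.0135), tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.027, 0.025, 0.701)),
               c(0.0405, 0.0405, 0.701), tolerance = 1e-12)
  expect_identical(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment is monotone and order-preserving", {
  set.seed(8)
  p <- runif(12)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # a family of identical p values is a fixed point
  expect_identical(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
})

test_that("the random-intercept LMM collapses to OLS when groups carry no signal", {
  # residuals constructed with zero mean inside every group: the intercept
  # variance is estimated at the boundary and the fit is exactly OLS
  set.seed(31)
  x <- rnorm(60)
  y <- 2 + 1.5 * x + rep(c(-0.1, 0, 0.1), 20)
  g <- rep(1:20, each = 3)
  fit <- fit_random_intercept_lmm(y, data.frame(x = x), g)
  ols <- stats::lm(y ~ x)
  expect_true(fit$boundary)
  expect_lt(fit$icc, 1e-8)
  expect_equal(fit$fixed$estimate, unname(stats::coef(ols)), tolerance = 1e-6)
  expect_equal(fit$fixed$se,
               unname(sqrt(diag(stats::vcov(ols))) * sqrt(58 / 60)),
               tolerance = 1e-3)
})

test_that("the LMM recovers simulated fixed and variance components at design scale", {
  # 21 groups x 3 observations, b = -5.7, var_u = 2.0, var_e = 2.9
  set.seed(77)
  n_rep <- 200
  covered <- logical(n_rep)
  est <- numeric(n_rep)
  vu <- numeric(n_rep)
  ve <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    g <- rep(1:21, each = 3)
    x <- rnorm(63)
    y <- 1 - 5.7 * x + rnorm(21, 0, sqrt(2))[g] + rnorm(63, 0, sqrt(2.9))
    f <- fit_random_intercept_lmm(y, data.frame(x = x), g)
    row <- f$fixed[f$fixed$term == "x", ]
    est[i] <- row$estimate
    covered[i] <- row$ci_lower <= -5.7 && -5.7 <= row$ci_upper
    vu[i] <- f$var_intercept
    ve[i] <- f$var_residual
  }
  expect_lt(abs(mean(est) + 5.7), 3 * sd(est) / sqrt(n_rep))
  expect_equal(mean(vu), 2.0, tolerance = 0.2)
  expect_equal(mean(ve), 2.9, tolerance = 0.15)
  # Wald coverage at this scale is approximately nominal
  expect_gt(mean(covered), 0.88)
})

test_that("the fitted LMM likelihood is a local optimum", {
  set.seed(5)
  g <- rep(1:21, each = 3)
  x <- rnorm(63)
  y <- 1 + 0.5 * x + rnorm(21, 0, 1)[g] + rnorm(63)
  f <- fit_random_intercept_lmm(y, data.frame(x = x), g)
  # perturb the variance ratio around the optimum through the deviance function
  devf <- lme4::lmer(.y ~ x + (1 | .g), REML = FALSE, devFunOnly = TRUE,
                     data = data.frame(.y = y, x = x, .g = factor(g)))
  opt_theta <- lme4::getME(f$model, "theta")
  d0 <- devf(opt_theta)
  set.seed(6)
  worse <- vapply(seq_len(100), function(i) {
    devf(abs(opt_theta + rnorm(1, 0, 0.3))) >= d0 - 1e-6
  }, TRUE)
  expect_true(all(worse))
})

test_that("ICC and the BIC Bayes factor follow their closed forms", {
  expect_identical(icc(0, 4), 0)
  expect_identical(icc(3, 3), 0.5)
  expect_equal(icc(2.01, 2.89), 0.410, tolerance = 5e-4)
  expect_error(icc(0, 0), "undefined")
  expect_equal(bic_bayes_factor(290.99, 290.89), exp(0.05), tolerance = 1e-12)
  expect_identical(bic_bayes_factor(100, 100), 1)
  expect_equal(bic_bayes_factor(102, 100), exp(1), tolerance = 1e-12)
})
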