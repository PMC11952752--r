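test_that("fit_exponential recovers exact log-linear data", {
  d <- c(0, 2, 4, 6, 8)
  f <- fit_exponential(d, 100 * exp(0.3 * d))
  expect_equal(f$rate, 0.3, tolerance = 1e-12)
  expect_equal(f$intercept, log(100), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(f$n_points_used, 5L)
  expect_equal(coef(f), c(intercept = log(100), rate = 0.3),
               tolerance = 1e-12)
  expect_equal(predict(f, d), 100 * exp(0.3 * d), tolerance = 1e-9)
})

test_that("constant areas fit a zero rate with undefined r-squared", {
  f <- fit_exponential(c(0, 2, 4), c(500, 500, 500))
  expect_equal(f$rate, 0)
  expect_true(is.na(f$r_squared))
})

test_that("non-positive areas are dropped before fitting", {
  # hand slope on the two surviving points: (1.2 - 0) / (4 - 0) = 0.3
  f <- fit_exponential(c(0, 2, 4), c(100, 0, 100 * exp(1.2)))
  expect_equal(f$rate, 0.3, tolerance = 1e-12)
  expect_equal(f$n_points_used, 2L)
  expect_error(fit_exponential(c(0, 2), c(0, 10)), "fewer than 2")
})

test_that("outlier removal applies the single-pass 3 SD rule per group", {
  vals <- c(rep(10, 30), 25)
  df <- data.frame(genotype = "g1", condition_mM = 0, y = vals)
  res <- remove_outliers(df, "y")
  # independent computation of the criterion, outlier included
  mu <- mean(vals)
  sdev <- sqrt(mean((vals - mu)^2))
  expect_true(abs(25 - mu) > 3 * sdev)
  expect_true(all(abs(10 - mu) <= 3 * sdev))
  expect_equal(nrow(res$data), 30L)
  expect_equal(res$removed$y, 25)

  # zero-SD group removes nothing
  df2 <- data.frame(genotype = "g", condition_mM = 0, y = c(10, 10, 10))
  expect_equal(nrow(remove_outliers(df2, "y")$data), 3L)

  # groups of size <= 2 are never filtered
  df3 <- data.frame(genotype = c("a", "b", "b"), condition_mM = 0,
                    y = c(5, 1, 100))
  expect_equal(nrow(remove_outliers(df3, "y")$data), 3L)
})

test_that("outlier filter is inert when all values sit within 3 SD", {
  set.seed(21)
  for (i in 1:20) {
    y <- rnorm(sample(5:30, 1))
    mu <- mean(y); sdev <- sqrt(mean((y - mu)^2))
    df <- data.frame(genotype = "g", condition_mM = 0, y = y)
    res <- remove_outliers(df, "y")
    expect_equal(nrow(res$removed), sum(abs(y - mu) > 3 * sdev))
  }
})

test_that("genotype means, STI and rate ratios follow their definitions", {
  df <- data.frame(genotype = c("a", "a", "a", "b"),
                   condition_mM = c(0, 0, 0, 0),
                   y = c(1, 2, 3, 7))
  m <- genotype_condition_means(df, "y")
  expect_equal(m$mean[m$genotype == "a"], 2)
  expect_equal(m$n[m$genotype == "b"], 1L)

  expect_equal(compute_sti(0.5, 1.0), 0.5)
  expect_equal(compute_sti(0.8, 0.8), 1.0)
  expect_true(is.na(compute_sti(0.5, 0)))
  # STI of a genotype against itself is 1
  expect_equal(compute_sti(c(0.3, 1.7), c(0.3, 1.7)), c(1, 1))

  expect_equal(rate_ratio(0.2, 0.4), 0.5)
  expect_equal(rate_ratio(0.3, 0.3), 1.0)
  expect_true(is.na(rate_ratio(0.3, 0)))
  f1 <- fit_exponential(0:3, 10 * exp(0.2 * 0:3))
  f2 <- fit_exponential(0:3, 10 * exp(0.4 * 0:3))
  expect_equal(rate_ratio(f1, f2), 0.5, tolerance = 1e-9)
})

test_that("coordination test detects variance expansion (Brown-Forsythe)", {
  # degenerate: two identical constant groups -> statistic 0
  r0 <- c(rep(1, 5), rep(1, 5))
  tr <- rep(c("0", "75"), each = 5)
  cs <- coordination_test(r0, tr, control_label = "0")
  expect_equal(cs$tests$statistic, 0)
  expect_equal(cs$tests$p_value, 1)
  expect_true(all(cs$groups$variance >= 0))

  # SD 1 vs SD 3, n = 100 each: variance expansion must be detected
  set.seed(11)
  ctrl <- rnorm(100, 1, 1)
  salt <- rnorm(100, 1, 3)
  cs2 <- coordination_test(c(ctrl, salt),
                           rep(c("0", "125"), each = 100),
                           control_label = "0")
  expect_lt(cs2$tests$p_value, 0.05)
  # cross-check statistic and p against the linear-model ANOVA route
  orc <- oracle_brown_forsythe(salt, ctrl)
  expect_equal(cs2$tests$statistic, orc$statistic, tolerance = 1e-9)
  expect_equal(cs2$tests$p_value, orc$p_value, tolerance = 1e-9)

  # groups with n < 3 are excluded with a warning
  expect_warning(
    coordination_test(c(ctrl, salt, 1, 2),
                      c(rep(c("0", "125"), each = 100), "75", "75"),
                      control_label = "0"),
    "n < 3")
})

test_that("heritability matches its limit cases and stays in [0, 1]", {
  # distinct genotypes, zero residual -> H^2 = 1
  h <- heritability(rep(c(1, 2, 3), each = 4), rep(c("a", "b", "c"), each = 4))
  expect_equal(h$h2, 1)
  # identical genotype means -> truncated to 0
  h0 <- heritability(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(h0$sigma2_g, 0)
  expect_equal(h0$h2, 0)
  expect_error(heritability(1:4, rep("a", 4)), ">= 2 genotypes")

  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:10, 1)
    g <- rep(seq_len(k), each = sample(2:5, 1))
    v <- rnorm(length(g), mean = rnorm(k, sd = runif(1, 0, 3))[g])
    hh <- heritability(v, g)
    expect_gte(hh$h2, 0)
    expect_lte(hh$h2, 1)
  }
})

test_that("balanced-design heritability equals the mixed-model ICC", {
  set.seed(8)
  k <- 40; n <- 5
  g <- factor(rep(seq_len(k), each = n))
  v <- rnorm(k, sd = 1.5)[g] + rnorm(k * n)
  ours <- heritability(v, g)
  fit <- lme4::lmer(v ~ 1 + (1 | g))
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc <- vc$vcov[1] / sum(vc$vcov)
  expect_equal(ours$h2, icc, tolerance = 1e-4)
})

test_that("correlate_series computes guarded Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate_series(x, 2 * x + 1), 1)
  expect_equal(correlate_series(x, -x), -1)
  # hand computation: x = (1,2,3), y = (1,3,2) -> r = 0.5
  expect_equal(correlate_series(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_warning(r <- correlate_series(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(r))
  expect_error(correlate_series(c(1, 2), c(1, 2)), ">= 3")
})

test_that("relative growth fractions label both population definitions", {
  df <- data.frame(genotype = rep(c("a", "b"), 2),
                   condition_mM = rep(c("0", "75"), each = 2),
                   rate = c(1, 3, 0.5, 1.5))
  fr <- relative_growth_fractions(df)
  # ratio of means: (0.5 + 1.5)/2 over (1 + 3)/2 = 0.5
  expect_equal(fr$ratio_of_means, 0.5)
  # mean of ratios: mean(0.5/1, 1.5/3) = 0.5
  expect_equal(fr$mean_of_ratios, 0.5)
  expect_equal(fr$n_genotypes, 2L)
})
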