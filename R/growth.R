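#' Fit an exponential growth rate to an area time series
#'
#' Growth is modelled as \eqn{A(t) = A_0 e^{rt}}; the rate `r` (per day) is
#' the slope of an ordinary least-squares fit of `ln(area)` on the
#' untransformed day. Non-positive areas are dropped before fitting (the
#' log is undefined there, and zero-pixel observations on early days are
#' segmentation dropouts rather than biology).
#'
#' @param day numeric vector of days (days after transfer to treatment).
#' @param area numeric vector of projected areas (pixels), same length.
#' @return A `growth_fit` object: `rate` (per day), `intercept`
#'   (`ln` area at day 0), `r_squared` (`NA` when the response is
#'   constant), `n_points_used`.
#' @examples
#' f <- fit_exponential(c(0, 2, 4, 6, 8), 100 * exp(0.3 * c(0, 2, 4, 6, 8)))
#' coef(f)
#' @export
fit_exponential <- function(day, area) {
  stopifnot(length(day) == length(area))
  keep <- is.finite(day) & is.finite(area) & area > 0
  d <- day[keep]; a <- area[keep]
  if (length(d) < 2L)
    stop("fit_exponential: fewer than 2 positive observations", call. = FALSE)
  if (length(unique(d)) < 2L)
    stop("fit_exponential: all observations on one day", call. = FALSE)
  y <- log(a)
  fit <- lm(y ~ d)
  sst <- sum((y - mean(y))^2)
  ssr <- sum(fit$residuals^2)
  structure(list(rate = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
                 n_points_used = length(d)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> rate %.4f / day, A0 = %.1f px, r^2 = %s, n = %d\n",
    x$rate, exp(x$intercept),
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
    x$n_points_used))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(intercept = object$intercept, rate = object$rate)
}

#' @export
predict.growth_fit <- function(object, day, ...) {
  exp(object$intercept + object$rate * day)
}

#' Remove outliers beyond k standard deviations within groups
#'
#' Within each genotype-by-condition group, observations farther than
#' `k` population standard deviations (n denominator) from the group mean
#' are removed in a single pass. Groups of size <= 2 are never filtered:
#' the SD estimate is unstable and any point would trivially sit at 1 SD.
#'
#' @param data `data.frame` of replicate-level records.
#' @param value_col name of the numeric trait column.
#' @param group_cols character vector of grouping columns.
#' @param k SD multiple (default 3).
#' @return list with `data` (retained rows) and `removed` (dropped rows).
#' @export
remove_outliers <- function(data, value_col,
                            group_cols = c("genotype", "condition_mM"),
                            k = 3) {
  stopifnot(is.data.frame(data), value_col %in% names(data),
            all(group_cols %in% names(data)), k > 0)
  key <- interaction(data[group_cols], drop = TRUE)
  x <- data[[value_col]]
  drop <- logical(nrow(data))
  for (g in levels(key)) {
    sel <- which(key == g & !is.na(x))
    if (length(sel) <= 2L) next
    mu <- mean(x[sel])
    sdev <- sqrt(mean((x[sel] - mu)^2))          # population SD
    if (sdev == 0) next
    drop[sel] <- abs(x[sel] - mu) > k * sdev
  }
  list(data = data[!drop, , drop = FALSE],
       removed = data[drop, , drop = FALSE])
}

#' Genotype-by-condition trait means
#'
#' @inheritParams remove_outliers
#' @return `data.frame` with the grouping columns, `mean` and `n`
#'   (non-missing replicates). Empty groups report `NA` mean, n = 0.
#' @export
genotype_condition_means <- function(data, value_col,
                                     group_cols = c("genotype",
                                                    "condition_mM")) {
  stopifnot(is.data.frame(data), value_col %in% names(data))
  key <- interaction(data[group_cols], drop = TRUE)
  x <- data[[value_col]]
  out <- do.call(rbind, lapply(levels(key), function(g) {
    sel <- key == g
    v <- x[sel & !is.na(x)]
    cbind(data[which(sel)[1], group_cols, drop = FALSE],
          data.frame(mean = if (length(v)) mean(v) else NA_real_,
                     n = length(v)))
  }))
  rownames(out) <- NULL
  out
}

#' Salt tolerance index
#'
#' STI is the genotype-specific mean trait value under salt divided by the
#' mean under control. Undefined (NA) when the control mean is not positive.
#'
#' @param mean_salt,mean_control numeric vectors (recycled to equal length).
#' @return numeric vector of STI values.
#' @export
compute_sti <- function(mean_salt, mean_control) {
  out <- mean_salt / mean_control
  out[!is.na(mean_control) & mean_control <= 0] <- NA_real_
  out
}

#' Root:shoot growth-rate ratio
#'
#' @param root,shoot `growth_fit` objects or numeric rates.
#' @return numeric ratio; `NA` when the shoot rate is not positive.
#' @export
rate_ratio <- function(root, shoot) {
  r <- if (inherits(root, "growth_fit")) root$rate else root
  s <- if (inherits(shoot, "growth_fit")) shoot$rate else shoot
  out <- r / s
  out[!is.na(s) & s <= 0] <- NA_real_
  out
}

#' Test for salt-induced expansion of root:shoot ratio variance
#'
#' Summarizes the root:shoot growth-rate ratio per treatment and tests each
#' salt group against the control for unequal spread with the
#' Brown-Forsythe test (one-way ANOVA on absolute deviations from the group
#' medians) — robust to the non-normality of ratio traits. Groups with
#' fewer than 3 members are excluded with a warning.
#'
#' @param ratio numeric vector of ratios.
#' @param treatment treatment label per observation (coerced to character).
#' @param control_label label of the control group.
#' @return A `coordination_summary`: list with `groups` (treatment, n,
#'   mean, se, variance) and `tests` (treatment, statistic, df1, df2,
#'   p_value) for each non-control group vs control.
#' @export
coordination_test <- function(ratio, treatment, control_label = "0") {
  stopifnot(length(ratio) == length(treatment))
  treatment <- as.character(treatment)
  keep <- !is.na(ratio) & !is.na(treatment)
  ratio <- ratio[keep]; treatment <- treatment[keep]
  counts <- table(treatment)
  small <- names(counts)[counts < 3L]
  if (length(small)) {
    warning("excluding groups with n < 3: ", paste(small, collapse = ", "),
            call. = FALSE)
    keep <- !treatment %in% small
    ratio <- ratio[keep]; treatment <- treatment[keep]
  }
  groups <- sort(unique(treatment))
  if (length(groups) < 2L || !control_label %in% groups)
    stop("need a control group and at least one other group", call. = FALSE)
  gstats <- do.call(rbind, lapply(groups, function(g) {
    x <- ratio[treatment == g]
    data.frame(treatment = g, n = length(x), mean = mean(x),
               se = sd(x) / sqrt(length(x)), variance = var(x),
               stringsAsFactors = FALSE)
  }))
  ctrl <- ratio[treatment == control_label]
  tests <- do.call(rbind, lapply(setdiff(groups, control_label), function(g) {
    bf <- brown_forsythe(ratio[treatment == g], ctrl)
    data.frame(treatment = g, statistic = bf$statistic, df1 = bf$df1,
               df2 = bf$df2, p_value = bf$p_value, stringsAsFactors = FALSE)
  }))
  structure(list(groups = gstats, tests = tests,
                 control_label = control_label),
            class = "coordination_summary")
}

# Two-sample Brown-Forsythe (median-centered Levene) test.
brown_forsythe <- function(x, y) {
  zx <- abs(x - median(x))
  zy <- abs(y - median(y))
  z <- c(zx, zy)
  g <- rep(1:2, c(length(zx), length(zy)))
  n <- length(z); k <- 2L
  mz <- mean(z)
  ssb <- sum(tapply(z, g, function(v) length(v) * (mean(v) - mz)^2))
  ssw <- sum((z - ave(z, g))^2)
  df1 <- k - 1L; df2 <- n - k
  if (ssw == 0 && ssb == 0)
    return(list(statistic = 0, df1 = df1, df2 = df2, p_value = 1))
  stat <- (ssb / df1) / (ssw / df2)
  list(statistic = stat, df1 = df1, df2 = df2,
       p_value = pf(stat, df1, df2, lower.tail = FALSE))
}

#' @export
print.coordination_summary <- function(x, ...) {
  cat("Root:shoot ratio coordination summary\n")
  print(x$groups, row.names = FALSE)
  cat("\nBrown-Forsythe tests vs control (", x$control_label, " mM):\n",
      sep = "")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Broad-sense heritability from one-way variance components
#'
#' Estimates \eqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)} from a
#' one-way random-effects ANOVA over genotypes within one condition.
#' \eqn{\sigma^2_g = \max(0, (MS_{between} - MS_{within}) / \bar n)} with
#' the unbalanced-design effective replicate number
#' \eqn{\bar n = (N - \sum n_i^2 / N) / (k - 1)}; \eqn{\sigma^2_e} is
#' \eqn{MS_{within}}.
#'
#' @param value numeric replicate-level trait values.
#' @param genotype genotype label per value.
#' @return A `heritability_estimate`: `sigma2_g`, `sigma2_e`, `h2`,
#'   `n_genotypes`, `n_total`, `n_eff`.
#' @export
heritability <- function(value, genotype) {
  keep <- !is.na(value) & !is.na(genotype)
  value <- value[keep]; genotype <- as.character(genotype[keep])
  ni <- table(genotype)
  k <- length(ni); n <- length(value)
  if (k < 2L) stop("heritability needs >= 2 genotypes", call. = FALSE)
  if (n - k < 1L)
    stop("heritability needs replication within genotypes", call. = FALSE)
  gm <- tapply(value, genotype, mean)
  grand <- mean(value)
  ssb <- sum(as.numeric(ni) * (gm - grand)^2)
  ssw <- sum((value - ave(value, genotype))^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  n_eff <- (n - sum(as.numeric(ni)^2) / n) / (k - 1)
  sigma2_g <- max(0, (msb - msw) / n_eff)
  h2 <- if (sigma2_g + msw > 0) sigma2_g / (sigma2_g + msw) else 0
  structure(list(sigma2_g = sigma2_g, sigma2_e = msw, h2 = h2,
                 n_genotypes = k, n_total = n, n_eff = n_eff),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf(
    "<heritability> H^2 = %.3f (sigma2_g %.3f, sigma2_e %.3f; %d genotypes, %d obs)\n",
    x$h2, x$sigma2_g, x$sigma2_e, x$n_genotypes, x$n_total))
  invisible(x)
}

#' Pearson correlation with degenerate-input guard
#'
#' Used for validating projected areas against fresh-weight measurements.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return Pearson r, or `NA` (with a warning) when either input has zero
#'   variance.
#' @export
correlate_series <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("correlate_series needs >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Population-wide relative growth-rate fractions
#'
#' The fraction of control growth retained under each salt treatment,
#' reported both as the ratio of population means and as the population
#' mean of per-genotype salt/control ratios (the two differ under
#' genotype-by-treatment interaction; both are labelled explicitly).
#'
#' @param data `data.frame` of genotype-level rates.
#' @param rate_col name of the rate column.
#' @param condition_col name of the treatment column.
#' @param genotype_col name of the genotype column.
#' @param control_label control treatment label.
#' @return `data.frame` with condition, `ratio_of_means`,
#'   `mean_of_ratios`, and genotype counts.
#' @export
relative_growth_fractions <- function(data, rate_col = "rate",
                                      condition_col = "condition_mM",
                                      genotype_col = "genotype",
                                      control_label = "0") {
  stopifnot(all(c(rate_col, condition_col, genotype_col) %in% names(data)))
  cond <- as.character(data[[condition_col]])
  rate <- data[[rate_col]]
  geno <- as.character(data[[genotype_col]])
  ctrl <- cond == control_label
  ctrl_mean <- mean(rate[ctrl], na.rm = TRUE)
  ctrl_by_geno <- tapply(rate[ctrl], geno[ctrl], mean, na.rm = TRUE)
  out <- lapply(setdiff(sort(unique(cond)), control_label), function(cc) {
    sel <- cond == cc
    rom <- mean(rate[sel], na.rm = TRUE) / ctrl_mean
    salt_by_geno <- tapply(rate[sel], geno[sel], mean, na.rm = TRUE)
    common <- intersect(names(salt_by_geno), names(ctrl_by_geno))
    ratios <- salt_by_geno[common] / ctrl_by_geno[common]
    ratios <- ratios[is.finite(ratios)]
    data.frame(condition = cc, ratio_of_means = rom,
               mean_of_ratios = mean(ratios), n_genotypes = length(ratios),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
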