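# Validation machinery: correlation criterion, amount-effect and
# spatial-effect F tests, variance components of replicate estimates,
# and the replicate power analysis.

effect_test_result <- function(effect_name, p_value, f_statistic, df) {
  structure(
    list(effect_name = effect_name, p_value = p_value,
         f_statistic = f_statistic, df = df),
    class = "effect_test_result")
}

#' @export
print.effect_test_result <- function(x, ...) {
  cat(sprintf("%s effect: F(%d, %d) = %.3f, p = %.4g\n",
              x$effect_name, x$df[1L], x$df[2L], x$f_statistic, x$p_value))
  invisible(x)
}

#' Correlation between estimated and true expression levels
#'
#' Pearson correlation between estimated relative log-expression levels
#' and the true log-concentrations, matched by name. Since estimates
#' are only defined up to an additive constant, the correlation is the
#' natural scale-free agreement measure.
#'
#' @param x_hat Named numeric vector of estimates.
#' @param truth Named numeric vector of true log-concentrations.
#' @return The correlation, or `NA` (with a warning) when either vector
#'   is constant.
#' @export
correlation_criterion <- function(x_hat, truth) {
  common <- intersect(names(x_hat), names(truth))
  x <- x_hat[common]; t <- truth[common]
  keep <- is.finite(x) & is.finite(t)
  x <- x[keep]; t <- t[keep]
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(t) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, t)
}

#' Test for a residual starting-amount effect
#'
#' Fits `yNorm ~ dilution + amount + dilution:amount` with dilution
#' step and deposited amount as factors, and tests the amount main
#' effect by a type-II F test (amount after dilution). A significant
#' amount effect on normalized intensities means the normalization
#' failed to absorb variation in the total deposited protein.
#'
#' @param y_norm Normalized (or raw) spot intensities of one sample
#'   deposited at several starting amounts.
#' @param amount Per-spot deposited amount (mg/ml); treated as a factor.
#' @param dilution Per-spot dilution step; treated as a factor.
#' @return An `effect_test_result` for the amount main effect.
#' @export
test_amount_effect <- function(y_norm, amount, dilution) {
  keep <- is.finite(y_norm)
  y_norm <- y_norm[keep]
  af <- factor(amount[keep])
  df_ <- factor(dilution[keep])
  if (nlevels(af) < 2L) {
    stop("amount effect untestable: a single amount level", call. = FALSE)
  }
  fit <- stats::lm(y_norm ~ df_ * af)
  an <- car::Anova(fit, type = 2)
  row <- an["af", ]
  effect_test_result(
    "amount",
    p_value = row[["Pr(>F)"]],
    f_statistic = row[["F value"]],
    df = c(row[["Df"]], an["Residuals", "Df"]))
}

#' Test for linear row/column spatial effects
#'
#' Fits `value ~ sample + R + C` with the within-block row and column
#' indices as numeric linear covariates and the sample as a factor, and
#' returns the F test (type II) for each spatial covariate. Applied to
#' raw intensities this detects spatial bias; applied to model
#' residuals it checks whether a fitted model removed it.
#'
#' @param values Per-spot raw intensities or residuals.
#' @param layout Data frame with per-spot columns `row`, `col` and
#'   `sample_id` (a spot table works directly).
#' @return A list with `effect_test_result`s `row` and `col`.
#' @export
test_spatial_effect <- function(values, layout) {
  stopifnot(all(c("row", "col", "sample_id") %in% names(layout)))
  keep <- is.finite(values)
  dat <- data.frame(value = values[keep],
                    R = as.numeric(layout$row[keep]),
                    C = as.numeric(layout$col[keep]),
                    sample_f = factor(layout$sample_id[keep]))
  if (nrow(dat) < 4L) stop("too few spots to test spatial effects", call. = FALSE)
  if (length(unique(dat$R)) < 2L || length(unique(dat$C)) < 2L) {
    stop("need at least two distinct rows and columns", call. = FALSE)
  }
  form <- if (nlevels(dat$sample_f) > 1L) value ~ sample_f + R + C else value ~ R + C
  fit <- stats::lm(form, data = dat)
  an <- car::Anova(fit, type = 2)
  res_df <- an["Residuals", "Df"]
  list(
    row = effect_test_result("row", an["R", "Pr(>F)"], an["R", "F value"],
                             c(an["R", "Df"], res_df)),
    col = effect_test_result("col", an["C", "Pr(>F)"], an["C", "F value"],
                             c(an["C", "Df"], res_df)))
}

#' Variance components of replicate expression estimates
#'
#' Decomposes per-(sample, array) relative expression estimates into
#' sample fixed effects, an array random intercept (inter-array
#' variability) and a residual (intra-array variability), by a REML
#' linear mixed model. The residual variance feeds the replicate power
#' analysis.
#'
#' @param estimates Data frame with columns `x_hat`, `sample_id` and
#'   `array_id`; one row per replicate estimate.
#' @return A list of class `variance_components` with `sigma2_array`,
#'   `sigma2_resid` and the named vector `sample_effects`.
#' @export
estimate_variance_components <- function(estimates) {
  stopifnot(all(c("x_hat", "sample_id", "array_id") %in% names(estimates)))
  dat <- estimates[is.finite(estimates$x_hat), , drop = FALSE]
  dat$sample_id <- factor(dat$sample_id)
  dat$array_id <- factor(dat$array_id)
  if (nlevels(dat$sample_id) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (nlevels(dat$array_id) < 2L) {
    fit <- stats::lm(x_hat ~ 0 + sample_id, data = dat)
    out <- list(sigma2_array = NA_real_,
                sigma2_resid = summary(fit)$sigma^2,
                sample_effects = stats::setNames(stats::coef(fit),
                                                 levels(dat$sample_id)))
  } else {
    fit <- lme4::lmer(x_hat ~ 0 + sample_id + (1 | array_id), data = dat,
                      REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    out <- list(
      sigma2_array = vc$vcov[vc$grp == "array_id"][1L],
      sigma2_resid = vc$vcov[vc$grp == "Residual"][1L],
      sample_effects = stats::setNames(lme4::fixef(fit),
                                       levels(dat$sample_id)))
  }
  structure(out, class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components: inter-array %.4g, intra-array %.4g (%d samples)\n",
              x$sigma2_array, x$sigma2_resid, length(x$sample_effects)))
  invisible(x)
}

#' Power of the two-sample comparison of replicate estimates
#'
#' Analytic power of the two-sided, two-sample pooled-variance t test
#' for a difference `delta` in mean relative expression between two
#' samples measured with `n_replicates` technical replicates each,
#' computed from the noncentral t distribution. At `delta = 0` the
#' power equals the significance level exactly.
#'
#' @param sigma_resid Residual (intra-array) standard deviation of a
#'   single replicate estimate, log-dilution units.
#' @param n_replicates Replicates per sample (per group), at least 2.
#' @param deltas Differences in mean expression to evaluate.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `power_curve` with fields `n_replicates`,
#'   `deltas`, `power` and `alpha`.
#' @export
power_curve <- function(sigma_resid, n_replicates, deltas, alpha = 0.05) {
  if (n_replicates < 2L) stop("need at least 2 replicates", call. = FALSE)
  stopifnot(sigma_resid > 0, alpha > 0, alpha < 1)
  df <- 2L * n_replicates - 2L
  ncp <- deltas / (sigma_resid * sqrt(2 / n_replicates))
  crit <- stats::qt(1 - alpha / 2, df)
  power <- stats::pt(-crit, df, ncp) + stats::pt(crit, df, ncp, lower.tail = FALSE)
  structure(
    list(n_replicates = n_replicates, deltas = deltas,
         power = power, alpha = alpha),
    class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Power curve (n = %d, alpha = %.3g):\n", x$n_replicates, x$alpha))
  print(data.frame(delta = x$deltas, power = round(x$power, 4)), row.names = FALSE)
  invisible(x)
}
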