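# Initial SuperCurve quantification: joint logistic initialization,
# monotone curve fit, series-wise concentration estimation, the curve
# and concentration steps iterated twice.

logistic_mean <- function(alpha, beta, gamma, u) {
  alpha + beta * stats::plogis(gamma * u)
}

# Robust noise scale of an array: MAD of replicate deviations within
# (sample, dilution) cells; falls back to the MAD of all intensities
# when no cell has replicates.
replicate_noise_scale <- function(spots) {
  cell <- paste(spots$sample_id, spots$dilution_step, sep = "\r")
  dev <- unlist(tapply(spots$intensity, cell, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NULL)
    v - stats::median(v)
  }), use.names = FALSE)
  if (length(dev) >= 4L && stats::mad(dev) > 0) return(stats::mad(dev))
  # no usable replicate scatter (single deposits, or noise-free data):
  # fall back to a small fraction of the dynamic range, so only truly
  # constant series are screened out
  1e-3 * diff(range(spots$intensity, na.rm = TRUE))
}

#' Joint logistic initialization of relative expression levels
#'
#' Step 1 of the SuperCurve algorithm: fits a four-parameter logistic
#' response shared across all samples of the array,
#' `y = alpha + beta * plogis(gamma * (x_i + d_j))`, with a common
#' `(alpha, beta, gamma)` and one horizontal shift `x_i` per sample, by
#' alternating nonlinear least squares. The shifts initialize the
#' non-parametric fits and are centered to median 0.
#'
#' @param arrays An [align_array_set()] result (only the antibody
#'   channel is used) or a spot table.
#' @param design A [dilution_design()].
#' @param max_rounds,tol Alternation control: stop when the relative
#'   change in the summed squared error drops below `tol` (default
#'   `1e-8`) or after `max_rounds` (default 50) rounds.
#' @return An object of class `logistic_params`: `alpha`, `beta`,
#'   `gamma`, named vector `shifts` (NA for flat series) and a named
#'   character vector `flags` (`"ok"` or `"flat_series"`).
#' @export
fit_joint_logistic <- function(arrays, design, max_rounds = 50L, tol = 1e-8) {
  spots <- if (inherits(arrays, "array_set")) arrays$antibody else validate_spot_table(arrays)
  spots <- spots[canonical_spot_order(spots), , drop = FALSE]
  d_all <- center_dilution_covariates(design)
  keep <- is.finite(spots$intensity)
  spots <- spots[keep, , drop = FALSE]
  if (max(spots$dilution_step) > length(d_all)) {
    stop("spot table contains dilution steps beyond the design", call. = FALSE)
  }
  d <- d_all[spots$dilution_step]
  y <- spots$intensity
  sample <- spots$sample_id
  samples <- sort(unique(sample))

  if (diff(range(y)) == 0) {
    stop("all intensities constant: model unidentifiable", call. = FALSE)
  }

  # flat-series screen: dynamic range below twice the replicate noise scale
  noise <- replicate_noise_scale(spots)
  series <- series_ids(spots)
  series_range <- tapply(y, series, function(v) diff(range(v)))
  series_sample <- tapply(sample, series, `[`, 1L)
  flat_series <- names(series_range)[series_range < 2 * noise]
  # a sample is flat when all of its series are flat
  flags <- stats::setNames(rep("ok", length(samples)), samples)
  for (s in samples) {
    ser <- unique(series[sample == s])
    if (length(ser) && all(ser %in% flat_series)) flags[s] <- "flat_series"
  }
  active <- names(flags)[flags == "ok"]
  if (!length(active)) stop("every series is flat: model unidentifiable", call. = FALSE)
  use <- sample %in% active

  # initialization
  q <- stats::quantile(y[use], c(0.05, 0.95), names = FALSE)
  alpha <- q[1L]; beta <- max(q[2L] - q[1L], 1e-8); gamma <- 1
  x <- stats::setNames(rep(0, length(active)), active)

  sse_of <- function(alpha, beta, gamma, x) {
    mu <- logistic_mean(alpha, beta, gamma, x[sample[use]] + d[use])
    sum((y[use] - mu)^2)
  }
  sse_old <- sse_of(alpha, beta, gamma, x)
  for (round in seq_len(max_rounds)) {
    # shared parameters given shifts
    u <- x[sample[use]] + d[use]
    yy <- y[use]
    opt <- stats::optim(
      c(alpha, beta, gamma),
      function(p) sum((yy - logistic_mean(p[1L], p[2L], p[3L], u))^2),
      method = "BFGS", control = list(maxit = 200L, reltol = 1e-12))
    alpha <- opt$par[1L]; beta <- opt$par[2L]; gamma <- opt$par[3L]
    # shifts given shared parameters, one bounded 1-D problem per sample
    span <- diff(range(d)) + 2
    for (s in active) {
      sel <- use & sample == s
      ys <- y[sel]; ds <- d[sel]
      x[s] <- stats::optimize(
        function(xi) sum((ys - logistic_mean(alpha, beta, gamma, xi + ds))^2),
        interval = c(-span, span), tol = 1e-7)$minimum
    }
    sse_new <- sse_of(alpha, beta, gamma, x)
    if (abs(sse_old - sse_new) <= tol * max(sse_old, 1e-12)) break
    sse_old <- sse_new
  }

  # fix orientation so beta >= 0 (rising curve convention)
  if (beta < 0) {
    alpha <- alpha + beta
    beta <- -beta
    gamma <- -gamma
  }
  x <- x - stats::median(x)
  shifts <- stats::setNames(rep(NA_real_, length(samples)), samples)
  shifts[active] <- x[active]
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         shifts = shifts, flags = flags),
    class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("Joint logistic: alpha=%.4g beta=%.4g gamma=%.4g; %d sample(s), %d flat\n",
              x$alpha, x$beta, x$gamma, length(x$shifts),
              sum(x$flags == "flat_series")))
  invisible(x)
}

#' Estimate the relative concentration of one dilution series
#'
#' Step 3 of the SuperCurve algorithm: given the fitted response curve,
#' finds the horizontal shift `x` minimizing
#' `sum_j (y_j - offset_j - f(x + d_j))^2` for one series, by a dense
#' coarse grid followed by bounded golden-section refinement over the
#' curve domain extended by one dilution step on each side.
#'
#' @param curve A fitted curve ([fit_monotone_curve()] result, an
#'   `additive_curve`, or a plain function of `u`; for a function,
#'   `bounds` must be supplied).
#' @param series_y Intensities of the series' spots.
#' @param d Centered dilution covariates of those spots.
#' @param offsets Per-spot covariate contributions to subtract (zero for
#'   the base model).
#' @param bounds Optional search interval for `u = x + d`; defaults to
#'   the curve domain.
#' @param n_grid Coarse-grid size (default 200).
#' @return List with `x_hat` (the estimate) and `flag` (`"ok"` or
#'   `"boundary"` when the optimum sits at a search bound).
#' @export
estimate_series_concentration <- function(curve, series_y, d,
                                          offsets = NULL,
                                          bounds = NULL, n_grid = 200L) {
  if (!length(series_y)) stop("empty series", call. = FALSE)
  if (is.null(offsets)) offsets <- rep(0, length(series_y))
  stopifnot(length(series_y) == length(d), length(offsets) == length(series_y))
  keep <- is.finite(series_y) & is.finite(d) & is.finite(offsets)
  series_y <- series_y[keep]; d <- d[keep]; offsets <- offsets[keep]
  if (!length(series_y)) stop("empty series after removing missing spots", call. = FALSE)
  dom <- if (is.null(bounds)) curve_domain(curve) else bounds
  step <- if (length(unique(d)) > 1L) stats::median(diff(sort(unique(d)))) else 1
  lo <- (dom[1L] - step) - max(d)
  hi <- (dom[2L] + step) - min(d)
  target <- series_y - offsets
  obj <- function(x) sum((target - eval_curve(curve, x + d))^2)
  grid <- seq(lo, hi, length.out = n_grid)
  # one vectorized curve evaluation over the whole grid x series outer sum
  U <- outer(grid, d, `+`)
  fu <- matrix(eval_curve(curve, as.vector(U)), nrow = n_grid)
  vals <- rowSums((matrix(target, n_grid, length(d), byrow = TRUE) - fu)^2)
  i <- which.min(vals)
  cell <- c(grid[max(1L, i - 1L)], grid[min(n_grid, i + 1L)])
  opt <- stats::optimize(obj, interval = cell, tol = 1e-6)
  x_hat <- opt$minimum
  f_opt <- opt$objective
  # a bound matching the interior optimum (flat objective, e.g. a
  # series stuck on a plateau) means the concentration is outside the
  # observable range: report the bound and flag it
  tol_obj <- 1e-9 * max(f_opt, 1) + 1e-12
  flag <- "ok"
  for (b in c(lo, hi)) {
    if (obj(b) <= f_opt + tol_obj) {
      x_hat <- b
      flag <- "boundary"
      break
    }
  }
  edge_tol <- 1e-3 * (hi - lo)
  if (x_hat - lo < edge_tol || hi - x_hat < edge_tol) flag <- "boundary"
  list(x_hat = x_hat, flag = flag)
}

#' Quantify an array with the initial SuperCurve algorithm
#'
#' Runs the complete initial SuperCurve procedure on one array: joint
#' logistic initialization, then exactly two iterations of (monotone
#' curve refit, series-by-series concentration re-estimation).
#' Estimates are median-centered per array. The result is deterministic
#' and invariant to the ordering of the input spots.
#'
#' @param arrays An [align_array_set()] result or antibody spot table.
#' @param design A [dilution_design()].
#' @param n_iter Number of curve/concentration iterations after
#'   initialization (default 2).
#' @return A list of class `supercurve_fit` with `curve` (the final
#'   [fit_monotone_curve()]), `quant` (data frame `series_id, sample_id,
#'   x_hat, flag`), `init` (the `logistic_params`), per-spot `fitted`
#'   and `residuals` aligned to the antibody table, and `n_refits`, the
#'   number of curve refits performed after initialization.
#' @export
fit_supercurve <- function(arrays, design, n_iter = 2L) {
  spots <- if (inherits(arrays, "array_set")) arrays$antibody else validate_spot_table(arrays)
  # canonical processing order: results must not depend on input order
  ord <- canonical_spot_order(spots)
  spots <- spots[ord, , drop = FALSE]
  unorder <- order(ord)
  init <- fit_joint_logistic(spots, design)
  d_all <- center_dilution_covariates(design)
  d <- d_all[spots$dilution_step]
  series <- series_ids(spots)
  ser_levels <- sort(unique(series))
  ser_sample <- vapply(ser_levels, function(s) spots$sample_id[series == s][1L], character(1L))
  obs <- is.finite(spots$intensity)

  x_series <- init$shifts[ser_sample]          # NA for flat samples
  names(x_series) <- ser_levels
  flags <- stats::setNames(
    ifelse(init$flags[ser_sample] == "flat_series", "flat_series", "ok"),
    ser_levels)
  active <- ser_levels[flags != "flat_series"]
  if (!length(active)) stop("no usable series", call. = FALSE)

  curve <- NULL
  n_refits <- 0L
  for (iter in seq_len(n_iter)) {
    sel <- obs & series %in% active
    u <- x_series[series[sel]] + d[sel]
    curve <- fit_monotone_curve(u, spots$intensity[sel])
    n_refits <- n_refits + 1L
    for (s in active) {
      sel_s <- obs & series == s
      est <- estimate_series_concentration(curve, spots$intensity[sel_s], d[sel_s])
      x_series[s] <- est$x_hat
      flags[s] <- est$flag
    }
    x_series[active] <- x_series[active] - stats::median(x_series[active])
  }

  fitted <- rep(NA_real_, nrow(spots))
  sel <- series %in% active
  fitted[sel] <- eval_curve(curve, x_series[series[sel]] + d[sel])
  quant <- data.frame(
    series_id = ser_levels,
    sample_id = unname(ser_sample),
    x_hat = unname(x_series[ser_levels]),
    flag = unname(flags[ser_levels]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(curve = curve, quant = quant, init = init,
         fitted = fitted[unorder],
         residuals = (spots$intensity - fitted)[unorder],
         n_refits = n_refits),
    class = "supercurve_fit")
}

#' @export
print.supercurve_fit <- function(x, ...) {
  cat(sprintf("SuperCurve fit: %d series, %d curve refit(s)\n",
              nrow(x$quant), x$n_refits))
  invisible(x)
}

# Internal: canonical spot ordering, so floating-point accumulation
# order (and hence every estimate) is independent of input row order.
canonical_spot_order <- function(spots) {
  order(spots$sample_id, spots$replicate_id, spots$dilution_step,
        spots$block, spots$row, spots$col)
}

# Internal: per-sample median of per-series estimates (convenience for
# comparing against per-sample truth).
sample_estimates <- function(quant) {
  ok <- quant$flag != "flat_series" & is.finite(quant$x_hat)
  tapply(quant$x_hat[ok], quant$sample_id[ok], stats::median)
}
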