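# Extended SuperCurve: the monotone curve fit of step 2 is replaced by
# a penalized additive model (mgcv, REML-selected smoothing) in which
# the response curve s(u), optional centered smooths of the ctrl and
# sypro channel intensities, optional linear row/column covariates, and
# an optional per-series random effect enter additively. Concentration
# re-estimation (step 3) then reads each series off the covariate-
# adjusted curve by subtracting every non-curve term as an offset.

#' Specify an extended SuperCurve model
#'
#' Four orthogonal switches select which covariates enter the additive
#' model: linear within-block row/column terms (`spatial`), a per-series
#' random intercept (`replicate_effect`), and centered smooths of the
#' negative-control (`use_ctrl`) and total-protein-stain (`use_sypro`)
#' channels. The model with spatial terms and both control-channel
#' smooths — `model_spec("sc3", covariates = "cs")` — is NormaCurve.
#'
#' @param model One of `"sc1"` (base), `"sc3"` (base + spatial),
#'   `"sc4"` (base + replicate random effect) or `"custom"`.
#' @param covariates Which control channels to include: `"none"`,
#'   `"c"`, `"s"` or `"cs"`.
#' @param spatial,replicate_effect Logical overrides used when
#'   `model = "custom"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = c("sc1", "sc3", "sc4", "custom"),
                       covariates = c("none", "c", "s", "cs"),
                       spatial = FALSE, replicate_effect = FALSE) {
  model <- match.arg(model)
  covariates <- match.arg(covariates)
  if (model != "custom") {
    spatial <- model == "sc3"
    replicate_effect <- model == "sc4"
  }
  structure(
    list(spatial = spatial,
         replicate_effect = replicate_effect,
         use_ctrl = covariates %in% c("c", "cs"),
         use_sypro = covariates %in% c("s", "cs"),
         family_label = toupper(model),
         covariates = covariates),
    class = "model_spec")
}

#' The NormaCurve model specification
#'
#' Shorthand for `model_spec("sc3", "cs")`: spatial row/column terms
#' plus both the ctrl and sypro smooths.
#' @return A `model_spec`.
#' @export
normacurve_spec <- function() model_spec("sc3", "cs")

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model%s-%s: spatial=%s, replicate RE=%s, ctrl=%s, sypro=%s\n",
              x$family_label, x$covariates, x$spatial, x$replicate_effect,
              x$use_ctrl, x$use_sypro))
  invisible(x)
}

# Internal: assemble the per-spot model frame for the additive fit.
additive_model_frame <- function(arrays, x_current, design) {
  spots <- arrays$antibody
  d_all <- center_dilution_covariates(design)
  series <- series_ids(spots)
  df <- data.frame(
    y = spots$intensity,
    u = unname(x_current[series]) + d_all[spots$dilution_step],
    Rc = spots$row - mean(spots$row),
    Cc = spots$col - mean(spots$col),
    series_f = factor(series),
    stringsAsFactors = FALSE)
  df$ctrl <- if (is.null(arrays$ctrl)) NA_real_ else arrays$ctrl
  df$sypro <- if (is.null(arrays$sypro)) NA_real_ else arrays$sypro
  df$series <- series
  df
}

#' Fit the penalized additive intensity model
#'
#' The modified step 2 of the extended SuperCurve: given current
#' concentration estimates `x_current`, fits
#' `y = intercept + s(u) [+ s(ctrl)] [+ s(sypro)] [+ a_R*R + a_C*C]
#' [+ series random effect] + e` with `u = x + d`, each smooth a
#' penalized thin-plate spline with its smoothing parameter selected by
#' REML (no monotonicity constraint). Smooths are centered
#' (sum-to-zero over the data). A degenerate covariate (fewer than four
#' distinct values) is dropped with a warning rather than an error.
#'
#' @param arrays An [align_array_set()] result.
#' @param x_current Named vector of current per-series concentration
#'   estimates (`NA` entries and their spots are excluded).
#' @param design A [dilution_design()].
#' @param spec A [model_spec()].
#' @param k_u,k_cov Basis dimensions for the curve and covariate
#'   smooths (defaults 10).
#' @return An object of class `additive_fit`: the mgcv fit in `$gam`,
#'   `reml_score`, `spatial_coefs`, `replicate_variance`, per-spot
#'   `offsets` (sum of all non-curve terms, `NA` for excluded spots),
#'   the covariate-adjusted response curve in `$curve` (class
#'   `additive_curve`), `residuals`, and `dropped` (names of dropped
#'   terms).
#' @export
fit_additive_model <- function(arrays, x_current, design, spec,
                               k_u = 10L, k_cov = 10L) {
  stopifnot(inherits(arrays, "array_set"), inherits(spec, "model_spec"))
  if (spec$use_ctrl && is.null(arrays$ctrl)) {
    stop("model requires the ctrl channel but the array set has none", call. = FALSE)
  }
  if (spec$use_sypro && is.null(arrays$sypro)) {
    stop("model requires the sypro channel but the array set has none", call. = FALSE)
  }
  df <- additive_model_frame(arrays, x_current, design)
  keep <- is.finite(df$y) & is.finite(df$u)
  dat <- droplevels(df[keep, , drop = FALSE])
  if (nrow(dat) < 10L) stop("too few usable spots for the additive fit", call. = FALSE)

  usable <- function(v) length(unique(v[is.finite(v)])) >= 4L
  dropped <- character(0L)
  terms <- sprintf("s(u, k = %d)", min(k_u, length(unique(dat$u)) - 1L))
  if (spec$use_ctrl) {
    if (usable(dat$ctrl)) {
      terms <- c(terms, sprintf("s(ctrl, k = %d)",
                                min(k_cov, length(unique(dat$ctrl)) - 1L)))
    } else {
      warning("ctrl covariate is degenerate; its smooth was dropped")
      dropped <- c(dropped, "s(ctrl)")
    }
  }
  if (spec$use_sypro) {
    if (usable(dat$sypro)) {
      terms <- c(terms, sprintf("s(sypro, k = %d)",
                                min(k_cov, length(unique(dat$sypro)) - 1L)))
    } else {
      warning("sypro covariate is degenerate; its smooth was dropped")
      dropped <- c(dropped, "s(sypro)")
    }
  }
  if (spec$spatial) {
    for (v in c("Rc", "Cc")) {
      if (length(unique(dat[[v]])) >= 2L) {
        terms <- c(terms, v)
      } else {
        warning(v, " covariate is constant; dropped")
        dropped <- c(dropped, v)
      }
    }
  }
  if (spec$replicate_effect) terms <- c(terms, 's(series_f, bs = "re")')
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = dat, method = "REML")

  # decompose fitted values: curve part = intercept + s(u); everything
  # else (covariate smooths, spatial terms, random effects) is the
  # per-spot offset subtracted during concentration re-estimation.
  tm <- stats::predict(fit, type = "terms")
  su_col <- grep("^s\\(u", colnames(tm))
  intercept <- unname(stats::coef(fit)[1L])
  curve_part <- intercept + if (length(su_col)) tm[, su_col] else 0
  offsets_kept <- stats::fitted(fit) - curve_part
  offsets <- rep(NA_real_, nrow(df))
  offsets[keep] <- offsets_kept

  su_idx <- which(vapply(fit$smooth, function(s) s$term[1L] == "u", logical(1L)))
  curve <- structure(
    list(fit = fit, smooth_index = su_idx, intercept = intercept,
         domain = range(dat$u)),
    class = "additive_curve")
  # dense evaluation cache: repeated grid searches over the curve then
  # cost one basis construction instead of one per series
  grid_u <- seq(curve$domain[1L], curve$domain[2L], length.out = 2001L)
  curve$grid_u <- grid_u
  curve$grid_f <- predict_additive_curve(curve, grid_u)

  spatial_coefs <- if (spec$spatial) {
    cf <- stats::coef(fit)
    c(row = unname(cf["Rc"]), col = unname(cf["Cc"]))
  } else NULL
  replicate_variance <- if (spec$replicate_effect) {
    vc <- mgcv::gam.vcomp(fit, rescale = TRUE)
    re_row <- grep("series_f", rownames(vc))
    if (length(re_row)) unname(vc[re_row[1L], "std.dev"]^2) else NA_real_
  } else NULL

  resid_full <- rep(NA_real_, nrow(df))
  resid_full[keep] <- dat$y - stats::fitted(fit)
  structure(
    list(gam = fit, spec = spec,
         centers = c(row = mean(arrays$antibody$row),
                     col = mean(arrays$antibody$col)),
         reml_score = as.numeric(fit$gcv.ubre),
         intercept = intercept, spatial_coefs = spatial_coefs,
         replicate_variance = replicate_variance,
         offsets = offsets, curve = curve,
         residuals = resid_full,
         kept = keep, frame = df, dropped = dropped),
    class = "additive_fit")
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(sprintf("Additive RPPA model (%s-%s): REML = %.4f, %d spots\n",
              x$spec$family_label, x$spec$covariates, x$reml_score,
              sum(x$kept)))
  invisible(x)
}

# Evaluate intercept + s(u) of an additive fit at new u, clamped to the
# training domain (the curve is not extrapolated). Uses the dense
# interpolation cache when available.
predict_additive_curve <- function(curve, u) {
  u <- pmin(pmax(u, curve$domain[1L]), curve$domain[2L])
  if (!is.null(curve$grid_f)) {
    return(stats::approx(curve$grid_u, curve$grid_f, xout = u, rule = 2)$y)
  }
  if (!length(curve$smooth_index)) {
    return(rep(curve$intercept, length(u)))
  }
  sm <- curve$fit$smooth[[curve$smooth_index]]
  X <- mgcv::PredictMat(sm, data.frame(u = u))
  beta <- stats::coef(curve$fit)[sm$first.para:sm$last.para]
  curve$intercept + as.vector(X %*% beta)
}

# Evaluate one covariate smooth of an additive fit at new values.
predict_covariate_smooth <- function(model, term, values) {
  idx <- which(vapply(model$gam$smooth, function(s) s$term[1L] == term, logical(1L)))
  if (!length(idx)) {
    stop("model contains no smooth of '", term, "'", call. = FALSE)
  }
  sm <- model$gam$smooth[[idx]]
  X <- mgcv::PredictMat(sm, stats::setNames(data.frame(v = values), term))
  beta <- stats::coef(model$gam)[sm$first.para:sm$last.para]
  as.vector(X %*% beta)
}

#' Quantify and normalize an array with an extended SuperCurve model
#'
#' The full extended algorithm: joint logistic initialization, then
#' `n_iter` iterations in which the penalized additive model is refit
#' at the current concentrations and each series' concentration is
#' re-estimated from the covariate-adjusted curve (all non-curve terms
#' subtracted as offsets). With `replicate_effect = TRUE` the
#' concentrations are estimated per sample, pooling the squared error
#' over all of the sample's series. Estimates are median-centered.
#'
#' @inheritParams fit_additive_model
#' @param n_iter Number of model/concentration iterations after
#'   initialization (default 2).
#' @return A list of class `normacurve_fit`: `model` (the final
#'   [fit_additive_model()]), `quant` (data frame `series_id, sample_id,
#'   x_hat, flag`; one row per series, or per sample when the replicate
#'   random effect pools series), `init`, per-spot `fitted` and
#'   `residuals`, and `n_refits`.
#' @export
fit_normacurve <- function(arrays, design, spec = normacurve_spec(),
                           n_iter = 2L, k_u = 10L, k_cov = 10L) {
  stopifnot(inherits(arrays, "array_set"))
  # canonical processing order: results must not depend on input order
  ord <- canonical_spot_order(arrays$antibody)
  unorder <- order(ord)
  arrays <- structure(
    list(antibody = arrays$antibody[ord, , drop = FALSE],
         ctrl = if (is.null(arrays$ctrl)) NULL else arrays$ctrl[ord],
         sypro = if (is.null(arrays$sypro)) NULL else arrays$sypro[ord]),
    class = "array_set")
  spots <- arrays$antibody
  init <- fit_joint_logistic(spots, design)
  d_all <- center_dilution_covariates(design)
  d <- d_all[spots$dilution_step]
  series <- series_ids(spots)
  ser_levels <- sort(unique(series))
  ser_sample <- vapply(ser_levels, function(s) spots$sample_id[series == s][1L], character(1L))
  obs <- is.finite(spots$intensity)

  x_series <- init$shifts[ser_sample]
  names(x_series) <- ser_levels
  flags <- stats::setNames(
    ifelse(init$flags[ser_sample] == "flat_series", "flat_series", "ok"),
    ser_levels)
  active <- ser_levels[flags != "flat_series"]
  if (!length(active)) stop("no usable series", call. = FALSE)

  model <- NULL
  n_refits <- 0L
  for (iter in seq_len(n_iter)) {
    model <- fit_additive_model(arrays, x_series, design, spec,
                                k_u = k_u, k_cov = k_cov)
    n_refits <- n_refits + 1L
    off <- model$offsets
    if (spec$replicate_effect) {
      for (smp in unique(ser_sample[active])) {
        sel <- obs & spots$sample_id == smp & series %in% active & is.finite(off)
        if (!any(sel)) next
        est <- estimate_series_concentration(
          model$curve, spots$intensity[sel], d[sel], off[sel])
        hit <- active[ser_sample[active] == smp]
        x_series[hit] <- est$x_hat
        flags[hit] <- est$flag
      }
    } else {
      for (s in active) {
        sel <- obs & series == s & is.finite(off)
        if (!any(sel)) next
        est <- estimate_series_concentration(
          model$curve, spots$intensity[sel], d[sel], off[sel])
        x_series[s] <- est$x_hat
        flags[s] <- est$flag
      }
    }
    x_series[active] <- x_series[active] - stats::median(x_series[active])
  }

  fitted <- rep(NA_real_, nrow(spots))
  sel <- series %in% active & is.finite(model$offsets)
  fitted[sel] <- predict_additive_curve(model$curve, x_series[series[sel]] + d[sel]) +
    model$offsets[sel]

  if (spec$replicate_effect) {
    smp_levels <- sort(unique(ser_sample))
    quant <- data.frame(
      series_id = smp_levels,
      sample_id = smp_levels,
      x_hat = unname(x_series[match(smp_levels, ser_sample)]),
      flag = unname(flags[match(smp_levels, ser_sample)]),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    quant <- data.frame(
      series_id = ser_levels,
      sample_id = unname(ser_sample),
      x_hat = unname(x_series[ser_levels]),
      flag = unname(flags[ser_levels]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(
    list(model = model, quant = quant, init = init,
         fitted = fitted[unorder],
         residuals = (spots$intensity - fitted)[unorder],
         x_series = x_series, n_refits = n_refits, spec = spec),
    class = "normacurve_fit")
}

#' @export
print.normacurve_fit <- function(x, ...) {
  cat(sprintf("NormaCurve fit (%s-%s): %d estimate(s), %d model refit(s), REML = %.4f\n",
              x$spec$family_label, x$spec$covariates, nrow(x$quant),
              x$n_refits, x$model$reml_score))
  invisible(x)
}

#' Normalize spot intensities by the fitted control-channel smooths
#'
#' Subtracts from each observed intensity the fitted smooth of the
#' negative-control channel and/or of the total-protein-stain channel,
#' according to the requested case: `"none"` leaves intensities
#' untouched, `"c"` subtracts the ctrl smooth, `"s"` the sypro smooth,
#' `"cs"` both (the two corrections are additive, so their order is
#' immaterial).
#'
#' @param arrays The [align_array_set()] the model was fitted to.
#' @param model An [fit_additive_model()] result (or `normacurve_fit`)
#'   containing the requested smooths.
#' @param covariates Which corrections to apply: `"none"`, `"c"`,
#'   `"s"` or `"cs"`. Defaults to the model's own covariate case.
#' @return Numeric vector of normalized intensities, aligned to the
#'   antibody spot table.
#' @export
normalize_intensities <- function(arrays, model, covariates = NULL) {
  if (inherits(model, "normacurve_fit")) model <- model$model
  stopifnot(inherits(model, "additive_fit"))
  if (is.null(covariates)) covariates <- model$spec$covariates
  covariates <- match.arg(covariates, c("none", "c", "s", "cs"))
  y <- arrays$antibody$intensity
  if (covariates %in% c("c", "cs")) {
    if (is.null(arrays$ctrl)) stop("array set has no ctrl channel", call. = FALSE)
    if ("s(ctrl)" %in% model$dropped) {
      # degenerate ctrl smooth was dropped: correction is identically 0
    } else {
      y <- y - predict_covariate_smooth(model, "ctrl", arrays$ctrl)
    }
  }
  if (covariates %in% c("s", "cs")) {
    if (is.null(arrays$sypro)) stop("array set has no sypro channel", call. = FALSE)
    if (!("s(sypro)" %in% model$dropped)) {
      y <- y - predict_covariate_smooth(model, "sypro", arrays$sypro)
    }
  }
  y
}
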