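# Cross-validation of the quantification/normalization models against
# known spike-in concentrations, and the dilution-subsampling design
# study.

# Internal: restrict an array set to a subset of its spots.
subset_array_set <- function(arrays, idx) {
  structure(
    list(antibody = arrays$antibody[idx, , drop = FALSE],
         ctrl = if (is.null(arrays$ctrl)) NULL else arrays$ctrl[idx],
         sypro = if (is.null(arrays$sypro)) NULL else arrays$sypro[idx]),
    class = "array_set")
}

# Internal: covariate offsets (ctrl/sypro smooths + spatial terms) of a
# fitted additive model evaluated at arbitrary spots; the per-series
# random effect is excluded, so the offsets apply to unseen series.
additive_offsets_at <- function(model, arrays, idx = NULL) {
  spots <- arrays$antibody
  if (is.null(idx)) idx <- seq_len(nrow(spots))
  off <- rep(0, length(idx))
  sm_terms <- vapply(model$gam$smooth, function(s) s$term[1L], character(1L))
  if ("ctrl" %in% sm_terms) {
    off <- off + predict_covariate_smooth(model, "ctrl", arrays$ctrl[idx])
  }
  if ("sypro" %in% sm_terms) {
    off <- off + predict_covariate_smooth(model, "sypro", arrays$sypro[idx])
  }
  if (!is.null(model$spatial_coefs)) {
    off <- off +
      model$spatial_coefs[["row"]] * (spots$row[idx] - model$centers[["row"]]) +
      model$spatial_coefs[["col"]] * (spots$col[idx] - model$centers[["col"]])
  }
  off
}

#' Cross-validate a model against known concentrations
#'
#' Repeated 5-fold cross-validation of an extended SuperCurve model on
#' an array whose true relative concentrations are known (up to an
#' additive constant), as in a spike-in experiment. Dilution series —
#' not individual spots — are partitioned into folds, so every held-out
#' series is genuinely out-of-sample. Per fold, the model is fitted on
#' the training series; the training estimates fix the least-squares
#' offset aligning the truth to the estimation scale; the criterion is
#' the mean squared deviation of held-out intensities from the trained
#' model's prediction at the truth-aligned concentration. The
#' regression criterion (REML score of the training fits) and the
#' correlation between training estimates and truth are reported
#' alongside.
#'
#' @param arrays An [align_array_set()] result.
#' @param design A [dilution_design()].
#' @param spec A [model_spec()].
#' @param truth Named vector of true log-concentrations per sample
#'   (log-dilution units, arbitrary origin). Every sample in the array
#'   must have a truth value.
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Number of random fold partitions (default 30).
#' @param seed Integer seed for the partitions.
#' @param restrict_steps Optional dilution steps over which the CV
#'   criterion is evaluated (e.g. `1:2` in the dilution-design study);
#'   default all.
#' @param n_iter Iterations of the model fit (default 2).
#' @return A list of class `validation_report`: `cv_criterion`,
#'   `regression_criterion`, `correlation` (means over repeats),
#'   `n_repeats` and `per_repeat` (the per-repeat values).
#' @export
cross_validation_criterion <- function(arrays, design, spec, truth,
                                       n_folds = 5L, n_repeats = 30L,
                                       seed = 1L, restrict_steps = NULL,
                                       n_iter = 2L) {
  stopifnot(inherits(arrays, "array_set"))
  spots <- arrays$antibody
  unknown <- setdiff(unique(spots$sample_id), names(truth))
  if (length(unknown)) {
    stop("no truth value for sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  series <- series_ids(spots)
  ser_levels <- unique(series)
  if (length(ser_levels) < n_folds) {
    stop("fewer series than folds", call. = FALSE)
  }
  set.seed(seed)
  cv_rep <- reml_rep <- cor_rep <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    fold_of <- stats::setNames(
      sample(rep_len(seq_len(n_folds), length(ser_levels))), ser_levels)
    sq_err <- 0; n_spots <- 0L
    reml_folds <- cor_folds <- numeric(n_folds)
    for (fold in seq_len(n_folds)) {
      test_idx <- which(fold_of[series] == fold)
      train_idx <- setdiff(seq_len(nrow(spots)), test_idx)
      fit <- fit_normacurve(subset_array_set(arrays, train_idx), design,
                            spec, n_iter = n_iter)
      # align truth to the estimation scale by a least-squares offset
      q <- fit$quant[fit$quant$flag != "flat_series" & is.finite(fit$quant$x_hat), ]
      a <- mean(q$x_hat - truth[q$sample_id])
      reml_folds[fold] <- fit$model$reml_score
      cor_folds[fold] <- suppressWarnings(
        correlation_criterion(stats::setNames(q$x_hat, q$series_id),
                              stats::setNames(truth[q$sample_id], q$series_id)))
      eval_idx <- test_idx
      if (!is.null(restrict_steps)) {
        eval_idx <- eval_idx[spots$dilution_step[eval_idx] %in% restrict_steps]
      }
      eval_idx <- eval_idx[is.finite(spots$intensity[eval_idx])]
      if (!length(eval_idx)) next
      d_all <- center_dilution_covariates(design)
      u_truth <- truth[spots$sample_id[eval_idx]] + a +
        d_all[spots$dilution_step[eval_idx]]
      y_hat <- predict_additive_curve(fit$model$curve, u_truth) +
        additive_offsets_at(fit$model, arrays, eval_idx)
      sq_err <- sq_err + sum((spots$intensity[eval_idx] - y_hat)^2)
      n_spots <- n_spots + length(eval_idx)
    }
    cv_rep[rep_i] <- sq_err / n_spots
    reml_rep[rep_i] <- mean(reml_folds)
    cor_rep[rep_i] <- mean(cor_folds, na.rm = TRUE)
  }
  structure(
    list(cv_criterion = mean(cv_rep),
         regression_criterion = mean(reml_rep),
         correlation = mean(cor_rep),
         n_repeats = n_repeats,
         per_repeat = list(cv = cv_rep, reml = reml_rep, correlation = cor_rep)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation over %d repeat(s): CV = %.5g, REML = %.5g, cor = %.4f\n",
              x$n_repeats, x$cv_criterion, x$regression_criterion,
              x$correlation))
  invisible(x)
}

#' How many serial dilutions are needed?
#'
#' Refits the model keeping only the `k` most concentrated dilution
#' steps of every series, for each `k` requested, and reports the three
#' validation criteria. To compare across `k` the CV criterion is
#' evaluated on the two most concentrated steps only (the spots all
#' subsets share).
#'
#' @inheritParams cross_validation_criterion
#' @param k_values Numbers of retained dilution steps, each at least 2.
#' @return A data frame with one row per `k`: `k`, `cv_criterion`,
#'   `regression_criterion`, `correlation`.
#' @export
dilution_subsample_study <- function(arrays, design, spec, truth,
                                     k_values, seed = 1L,
                                     n_repeats = 30L, n_iter = 2L) {
  n_steps <- length(design$dilution_factors)
  if (any(k_values < 2L) || any(k_values > n_steps)) {
    stop("k_values must lie in 2..", n_steps, call. = FALSE)
  }
  rows <- lapply(k_values, function(k) {
    idx <- which(arrays$antibody$dilution_step <= k)
    design_k <- dilution_design(
      starting_concentration = design$starting_concentration,
      fold = design$fold,
      dilution_factors = design$dilution_factors[seq_len(k)])
    rep_k <- cross_validation_criterion(
      subset_array_set(arrays, idx), design_k, spec, truth,
      n_repeats = n_repeats, seed = seed, restrict_steps = 1:2,
      n_iter = n_iter)
    data.frame(k = k,
               cv_criterion = rep_k$cv_criterion,
               regression_criterion = rep_k$regression_criterion,
               correlation = rep_k$correlation)
  })
  do.call(rbind, rows)
}
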