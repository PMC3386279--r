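# Synthetic spike-in generator. Emulates a two-block randomized RPPA
# design (two 40x40 superarrays, serial 2-fold dilutions, technical
# replicates, a subset of samples deposited at varying starting
# amounts) together with spot-aligned negative-control (ctrl) and
# total-protein-stain (sypro) channels. The generative model is the
# extended SuperCurve read forward:
#   y = f(x + d) * noise + g(ctrl) + h(sypro) + a_R*R + a_C*C + floor,
# with the control channels affine in total spotted protein
# (amount x dilution factor) and the antibody noise multiplicative
# log-normal with a stated CV.

#' Parameters of a synthetic RPPA spike-in experiment
#'
#' Defaults reproduce the layout of a two-block 40x40 spike-in design:
#' 15 two-fold dilutions starting at 1 mg/ml, 6 technical replicates
#' per sample, randomized spot placement, and paired ctrl/sypro
#' channels affine in the total spotted protein. Planted covariate
#' effects (`ctrl_effect`, `sypro_effect`, `spatial_slopes`) default to
#' zero; simulation studies switch them on explicitly.
#'
#' @param n_samples Number of samples.
#' @param n_dilutions,fold,starting_concentration Serial-dilution
#'   design; see [dilution_design()].
#' @param n_replicates Technical replicates per sample (default 6).
#' @param blocks,block_rows,block_cols Array layout (default two 40x40
#'   blocks).
#' @param curve Named vector `c(alpha, beta, gamma)` of the logistic
#'   response: baseline intensity, dynamic range, slope per
#'   log-dilution unit.
#' @param true_shifts Named per-sample relative log-expression levels
#'   (log-dilution units); default: drawn uniformly on \[-2, 2\] from
#'   the seed.
#' @param amount_multipliers Named per-sample starting-amount
#'   multipliers (e.g. 0.8-1.2 for a 0.8-1.2 mg/ml deposit); default 1
#'   for all samples.
#' @param spatial_slopes `c(row =, col =)` linear intensity gradients
#'   per within-block row/column index.
#' @param ctrl_effect,sypro_effect Coefficients with which the observed
#'   ctrl/sypro intensities leak into the antibody signal.
#' @param ctrl_base,ctrl_gain,sypro_base,sypro_gain Affine maps from
#'   relative total protein to the control-channel intensities.
#' @param channel_cv Multiplicative noise CV of the control channels.
#' @param noise_cv Multiplicative log-normal noise CV of the antibody
#'   signal (default 0.10).
#' @param noise_floor_sd Additive background scatter (intensity units).
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_samples = 10L,
                              n_dilutions = 15L,
                              fold = 2,
                              starting_concentration = 1,
                              n_replicates = 6L,
                              blocks = 2L,
                              block_rows = 40L,
                              block_cols = 40L,
                              curve = c(alpha = 500, beta = 20000, gamma = 1),
                              true_shifts = NULL,
                              amount_multipliers = NULL,
                              spatial_slopes = c(row = 0, col = 0),
                              ctrl_effect = 0,
                              sypro_effect = 0,
                              ctrl_base = 300, ctrl_gain = 1500,
                              sypro_base = 1000, sypro_gain = 20000,
                              channel_cv = 0.05,
                              noise_cv = 0.10,
                              noise_floor_sd = 0,
                              seed = 1L) {
  p <- as.list(environment())
  capacity <- blocks * block_rows * block_cols
  n_spots <- n_samples * n_dilutions * n_replicates
  if (n_spots > capacity) {
    stop(sprintf("design error: %d spots exceed array capacity %d",
                 n_spots, capacity), call. = FALSE)
  }
  stopifnot(n_dilutions >= 2L, n_replicates >= 1L, noise_cv >= 0)
  structure(p, class = "simulation_params")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat(sprintf(paste0("Simulated RPPA design: %d samples x %d dilutions x %d reps",
                     " on %d block(s) of %dx%d; noise CV %.2f\n"),
              x$n_samples, x$n_dilutions, x$n_replicates,
              x$blocks, x$block_rows, x$block_cols, x$noise_cv))
  invisible(x)
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Simulate a spike-in RPPA experiment with known truth
#'
#' Generates one antibody array with spot-aligned ctrl and sypro
#' channels and full ground truth, deterministic given
#' `params$seed`. Samples are placed at random coordinates; when the
#' replicate count is even and two blocks are printed, the second block
#' repeats the first block's layout (replicate superarrays).
#'
#' @param params A [simulation_params()].
#' @return A list of class `rppa_simulation` with elements `arrays` (an
#'   [align_array_set()] result), `design` (the [dilution_design()]),
#'   `truth` (list: `shifts`, `amounts`, per-spot data frame `per_spot`
#'   with the noiseless signal and each planted contribution) and
#'   `params`.
#' @export
simulate_rppa_experiment <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed)

  samples <- sprintf("S%02d", seq_len(p$n_samples))
  shifts <- p$true_shifts
  if (is.null(shifts)) {
    shifts <- stats::setNames(stats::runif(p$n_samples, -2, 2), samples)
  } else {
    if (is.null(names(shifts))) names(shifts) <- samples
    samples <- names(shifts)
    p$n_samples <- length(samples)
  }
  amounts <- p$amount_multipliers
  if (is.null(amounts)) amounts <- stats::setNames(rep(1, length(samples)), samples)
  if (is.null(names(amounts))) names(amounts) <- samples
  stopifnot(all(samples %in% names(amounts)))

  design <- dilution_design(p$n_dilutions, p$fold, p$starting_concentration)
  d_cov <- center_dilution_covariates(design)

  grid <- expand.grid(sample_id = samples,
                      dilution_step = seq_len(p$n_dilutions),
                      replicate_id = seq_len(p$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)

  # randomized spot placement
  mirrored <- p$blocks == 2L && p$n_replicates %% 2L == 0L
  if (mirrored) {
    per_block <- n / 2L
    coords1 <- expand.grid(row = seq_len(p$block_rows),
                           col = seq_len(p$block_cols),
                           KEEP.OUT.ATTRS = FALSE)
    pick <- coords1[sample.int(nrow(coords1), per_block), , drop = FALSE]
    first_half <- grid$replicate_id <= p$n_replicates / 2L
    grid$block <- ifelse(first_half, 1L, 2L)
    # identical within-block layout in the two blocks
    ord1 <- which(first_half)
    ord2 <- which(!first_half)
    key1 <- paste(grid$sample_id[ord1], grid$dilution_step[ord1],
                  (grid$replicate_id[ord1] - 1L) %% (p$n_replicates / 2L))
    key2 <- paste(grid$sample_id[ord2], grid$dilution_step[ord2],
                  (grid$replicate_id[ord2] - 1L) %% (p$n_replicates / 2L))
    slot1 <- sample.int(per_block)
    grid$row <- NA_integer_; grid$col <- NA_integer_
    grid$row[ord1] <- pick$row[slot1]
    grid$col[ord1] <- pick$col[slot1]
    reorder <- match(key2, key1)
    grid$row[ord2] <- grid$row[ord1][reorder]
    grid$col[ord2] <- grid$col[ord1][reorder]
  } else {
    coords <- expand.grid(block = seq_len(p$blocks),
                          row = seq_len(p$block_rows),
                          col = seq_len(p$block_cols),
                          KEEP.OUT.ATTRS = FALSE)
    pick <- coords[sample.int(nrow(coords), n), , drop = FALSE]
    grid$block <- pick$block
    grid$row <- pick$row
    grid$col <- pick$col
  }

  amount <- amounts[grid$sample_id]
  dilution_factor <- design$dilution_factors[grid$dilution_step]
  total_protein <- amount * dilution_factor   # relative to 1 mg/ml deposit

  ctrl_true <- p$ctrl_base + p$ctrl_gain * total_protein
  sypro_true <- p$sypro_base + p$sypro_gain * total_protein
  ctrl_obs <- ctrl_true * lognormal_factor(n, p$channel_cv)
  sypro_obs <- sypro_true * lognormal_factor(n, p$channel_cv)

  u <- shifts[grid$sample_id] + d_cov[grid$dilution_step]
  signal <- logistic_mean(p$curve[["alpha"]], p$curve[["beta"]],
                          p$curve[["gamma"]], u)
  Rc <- grid$row - mean(grid$row)
  Cc <- grid$col - mean(grid$col)
  ctrl_contrib <- p$ctrl_effect * ctrl_obs
  sypro_contrib <- p$sypro_effect * sypro_obs
  spatial_contrib <- p$spatial_slopes[["row"]] * Rc + p$spatial_slopes[["col"]] * Cc
  floor_noise <- if (p$noise_floor_sd > 0) stats::rnorm(n, 0, p$noise_floor_sd) else 0
  y <- signal * lognormal_factor(n, p$noise_cv) +
    ctrl_contrib + sypro_contrib + spatial_contrib + floor_noise
  y <- pmax(y, 0)

  base <- data.frame(array_id = "sim1", block = grid$block,
                     row = grid$row, col = grid$col,
                     sample_id = grid$sample_id,
                     dilution_step = grid$dilution_step,
                     replicate_id = grid$replicate_id,
                     stringsAsFactors = FALSE)
  antibody <- cbind(base, intensity = y)
  ctrl_tab <- cbind(base, intensity = ctrl_obs)
  ctrl_tab$array_id <- "sim1_ctrl"
  sypro_tab <- cbind(base, intensity = sypro_obs)
  sypro_tab$array_id <- "sim1_sypro"
  arrays <- align_array_set(antibody, ctrl_tab, sypro_tab)

  per_spot <- data.frame(
    sample_id = grid$sample_id, dilution_step = grid$dilution_step,
    replicate_id = grid$replicate_id,
    signal = signal, ctrl_contrib = ctrl_contrib,
    sypro_contrib = sypro_contrib, spatial_contrib = spatial_contrib,
    amount = unname(amount), total_protein = unname(total_protein),
    stringsAsFactors = FALSE)

  structure(
    list(arrays = arrays, design = design,
         truth = list(shifts = shifts, amounts = amounts, per_spot = per_spot),
         params = p),
    class = "rppa_simulation")
}

#' @export
print.rppa_simulation <- function(x, ...) {
  cat(sprintf("Simulated RPPA experiment: %d spots, %d samples, seed %d\n",
              nrow(x$arrays$antibody), length(x$truth$shifts),
              x$params$seed))
  invisible(x)
}
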