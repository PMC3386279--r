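# Hand-built array set with a known u for every spot, letting the
# additive model be tested against its own generative equation.
additive_toy <- function(n_samples = 12L, n_dil = 8L, n_rep = 2L,
                         ctrl_fun = NULL, sypro_fun = NULL,
                         spatial = c(0, 0), noise_sd = 0, seed = 1L,
                         shifts = NULL) {
  set.seed(seed)
  if (is.null(shifts)) {
    shifts <- setNames(seq(-2, 2, length.out = n_samples),
                       sprintf("S%02d", 1:n_samples))
  }
  design <- dilution_design(n_dil)
  d <- center_dilution_covariates(design)
  grid <- expand.grid(i = seq_along(shifts), k = seq_len(n_dil),
                      r = seq_len(n_rep))
  n <- nrow(grid)
  side <- ceiling(sqrt(n))
  spots <- data.frame(
    array_id = "a1", block = 1L,
    row = ((seq_len(n) - 1L) %/% side) + 1L,
    col = ((seq_len(n) - 1L) %% side) + 1L,
    sample_id = names(shifts)[grid$i],
    dilution_step = grid$k, replicate_id = grid$r,
    stringsAsFactors = FALSE)
  u <- shifts[grid$i] + d[grid$k]
  y <- 200 + 8000 * plogis(u)
  ctrl <- sypro <- NULL
  if (!is.null(ctrl_fun)) {
    ctrl <- runif(n, 0, 1000)
    y <- y + ctrl_fun(ctrl)
  }
  if (!is.null(sypro_fun)) {
    sypro <- runif(n, 0, 5000)
    y <- y + sypro_fun(sypro)
  }
  y <- y + spatial[1] * (spots$row - mean(spots$row)) +
    spatial[2] * (spots$col - mean(spots$col)) +
    rnorm(n, 0, noise_sd)
  spots$intensity <- pmax(y, 0)
  mk <- function(v, id) if (is.null(v)) NULL else {
    ch <- spots; ch$intensity <- v; ch$array_id <- id; ch
  }
  list(arrays = align_array_set(spots, mk(ctrl, "c1"), mk(sypro, "s1")),
       design = design, shifts = shifts,
       x_series = setNames(shifts[grid$i], paste(spots$sample_id,
                                                 spots$replicate_id,
                                                 sep = ".r"))[
         !duplicated(paste(spots$sample_id, spots$replicate_id, sep = ".r"))])
}

test_that("a planted linear ctrl effect is recovered by the ctrl smooth", {
  toy <- additive_toy(ctrl_fun = function(c) 2 * c, noise_sd = 0)
  fit <- fit_additive_model(toy$arrays, toy$x_series, toy$design,
                            model_spec("sc1", "c"))
  cgrid <- seq(50, 950, length.out = 100)
  sc <- normacurve:::predict_covariate_smooth(fit, "ctrl", cgrid)
  slope <- coef(lm(sc ~ cgrid))[2]
  expect_lt(abs(slope - 2), 0.05)
})

test_that("covariate smooths are centered over the data", {
  toy <- additive_toy(ctrl_fun = function(c) 0.5 * sqrt(c), noise_sd = 20)
  fit <- fit_additive_model(toy$arrays, toy$x_series, toy$design,
                            model_spec("sc1", "c"))
  sc <- normacurve:::predict_covariate_smooth(fit, "ctrl", toy$arrays$ctrl)
  expect_lt(abs(mean(sc)), 1e-6 * sd(toy$arrays$antibody$intensity))
})

test_that("the all-off spec reduces to a curve-only fit matching an unpenalized spline", {
  toy <- additive_toy(noise_sd = 0)
  fit <- fit_additive_model(toy$arrays, toy$x_series, toy$design,
                            model_spec("sc1", "none"))
  d <- center_dilution_covariates(toy$design)
  spots <- toy$arrays$antibody
  u <- toy$shifts[spots$sample_id] + d[spots$dilution_step]
  pred <- normacurve:::predict_additive_curve(fit$curve, u)
  ref <- fitted(lm(spots$intensity ~ splines::bs(u, df = 9)))
  expect_lt(sqrt(mean((pred - ref)^2)),
            0.02 * diff(range(spots$intensity)))
})

test_that("all-zero control channels reproduce the no-covariate estimates", {
  sim <- quick_sim(seed = 21)
  zero <- structure(list(antibody = sim$arrays$antibody,
                         ctrl = rep(0, nrow(sim$arrays$antibody)),
                         sypro = rep(0, nrow(sim$arrays$antibody))),
                    class = "array_set")
  suppressWarnings(
    fit_cs <- fit_normacurve(zero, sim$design, model_spec("sc1", "cs")))
  fit_0 <- fit_normacurve(sim$arrays, sim$design, model_spec("sc1", "none"))
  expect_equal(fit_cs$quant$x_hat, fit_0$quant$x_hat, tolerance = 1e-6)
})

test_that("requesting a channel the array set lacks is a configuration error", {
  sim <- quick_sim(seed = 2)
  bare <- structure(list(antibody = sim$arrays$antibody,
                         ctrl = NULL, sypro = NULL), class = "array_set")
  expect_error(fit_additive_model(bare, NULL, sim$design,
                                  model_spec("sc1", "c")),
               "requires the ctrl channel")
})

test_that("the replicate random effect pools identical series into one estimate", {
  toy <- additive_toy(n_samples = 8L, n_rep = 1L, noise_sd = 0)
  # triplicate every series exactly
  ab <- toy$arrays$antibody
  reps <- do.call(rbind, lapply(1:3, function(r) {
    x <- ab; x$replicate_id <- r; x$row <- x$row + (r - 1L) * 20L; x
  }))
  arr <- align_array_set(reps)
  fit4 <- fit_normacurve(arr, toy$design, model_spec("sc4", "none"))
  fit1 <- fit_normacurve(arr, toy$design, model_spec("sc1", "none"))
  expect_identical(nrow(fit4$quant), 8L)        # one estimate per sample
  per_series <- tapply(fit1$quant$x_hat, fit1$quant$sample_id, unique)
  # identical series agree among themselves and with the pooled estimate
  expect_true(all(vapply(per_series, length, integer(1)) == 1L))
  expect_equal(fit4$quant$x_hat[order(fit4$quant$sample_id)],
               as.numeric(per_series[order(names(per_series))]),
               tolerance = 1e-6)
})

test_that("normalization subtracts exactly the requested smooths, additively", {
  toy <- additive_toy(ctrl_fun = function(c) 1.5 * c,
                      sypro_fun = function(s) 0.2 * s, noise_sd = 25)
  fit <- fit_additive_model(toy$arrays, toy$x_series, toy$design,
                            model_spec("sc1", "cs"))
  y <- toy$arrays$antibody$intensity
  expect_identical(normalize_intensities(toy$arrays, fit, "none"), y)
  yc <- normalize_intensities(toy$arrays, fit, "c")
  ys <- normalize_intensities(toy$arrays, fit, "s")
  ycs <- normalize_intensities(toy$arrays, fit, "cs")
  expect_equal(ycs, yc + ys - y, tolerance = 1e-10)  # order-free additivity
  # requesting a smooth the model never fitted is an error
  fit0 <- fit_additive_model(toy$arrays, toy$x_series, toy$design,
                             model_spec("sc1", "none"))
  expect_error(normalize_intensities(toy$arrays, fit0, "c"),
               "no smooth of 'ctrl'")
})

test_that("normalization is near-idempotent: refit ctrl smooth shrinks", {
  toy <- additive_toy(ctrl_fun = function(c) 2 * c, noise_sd = 30, seed = 4)
  fit <- fit_additive_model(toy$arrays, toy$x_series, toy$design,
                            model_spec("sc1", "c"))
  y_norm <- normalize_intensities(toy$arrays, fit, "c")
  arr2 <- toy$arrays
  arr2$antibody$intensity <- pmax(y_norm, 0)
  fit2 <- fit_additive_model(arr2, toy$x_series, toy$design,
                             model_spec("sc1", "c"))
  amp <- function(f) diff(range(normacurve:::predict_covariate_smooth(
    f, "ctrl", seq(50, 950, length.out = 100))))
  expect_lt(amp(fit2), 0.1 * amp(fit))
})

test_that("REML prefers the model containing a truly active covariate", {
  wins <- 0L
  for (s in 1:10) {
    toy <- additive_toy(ctrl_fun = function(c) 1.5 * c, noise_sd = 100,
                        seed = 100 + s)
    f_c <- fit_additive_model(toy$arrays, toy$x_series, toy$design,
                              model_spec("sc1", "c"))
    f_0 <- fit_additive_model(toy$arrays, toy$x_series, toy$design,
                              model_spec("sc1", "none"))
    wins <- wins + (f_c$reml_score < f_0$reml_score)
  }
  expect_gte(wins, 9L)
})

test_that("planted spatial gradients are recovered within 10% at ~1000 spots", {
  # moderate dynamic range keeps the gradient well above the
  # intensity-proportional noise of the brightest spots
  sim <- simulate_rppa_experiment(simulation_params(
    n_samples = 12L, n_dilutions = 15L, n_replicates = 6L,
    curve = c(alpha = 1000, beta = 4000, gamma = 1),
    noise_cv = 0.10, spatial_slopes = c(row = 25, col = -20), seed = 31))
  fit <- fit_normacurve(sim$arrays, sim$design, model_spec("sc3", "none"),
                        n_iter = 1L)
  expect_lt(abs(fit$model$spatial_coefs[["row"]] - 25) / 25, 0.10)
  expect_lt(abs(fit$model$spatial_coefs[["col"]] + 20) / 20, 0.10)
})
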