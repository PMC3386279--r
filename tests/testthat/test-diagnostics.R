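test_that("correlation criterion matches the textbook formula", {
  x <- setNames(1:5, letters[1:5])
  expect_equal(correlation_criterion(x, x), 1.0)
  expect_equal(correlation_criterion(-x, x), -1.0)
  set.seed(8)
  truth <- setNames(rnorm(30), paste0("s", 1:30))
  est <- truth + rnorm(30, 0, 0.3)
  byhand <- sum((est - mean(est)) * (truth - mean(truth))) /
    sqrt(sum((est - mean(est))^2) * sum((truth - mean(truth))^2))
  expect_equal(correlation_criterion(est, truth), byhand, tolerance = 1e-12)
  expect_warning(r <- correlation_criterion(setNames(rep(1, 5), names(x[1:5])), x),
                 "zero variance")
  expect_true(is.na(r))
  expect_error(correlation_criterion(x[1:2], x[1:2]), "at least 3")
})

test_that("the amount test detects a planted amount effect and not its absence", {
  amounts <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  gen <- function(effect) {
    grid <- expand.grid(a = amounts, k = 1:5, r = 1:6)
    mu <- 5000 * 2^(-(grid$k - 1)) * (if (effect) grid$a else 1)
    list(y = mu + rnorm(nrow(grid), 0, 100), amount = grid$a, dil = grid$k)
  }
  set.seed(12)
  d1 <- gen(TRUE)
  res <- test_amount_effect(d1$y, d1$amount, d1$dil)
  expect_s3_class(res, "effect_test_result")
  expect_lt(res$p_value, 0.01)
  # after dividing out the known multipliers, p-values are uniform
  set.seed(13)
  pvals <- replicate(200, {
    d <- gen(TRUE)
    test_amount_effect(d$y / d$amount * 1, d$amount, d$dil)$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_error(test_amount_effect(d1$y, rep(1, length(d1$y)), d1$dil),
               "single amount level")
})

test_that("the spatial test flags a planted row gradient and stays quiet on noise", {
  set.seed(5)
  n <- 1600L
  layout <- data.frame(row = sample(1:40, n, TRUE),
                       col = sample(1:40, n, TRUE),
                       sample_id = sample(sprintf("S%d", 1:10), n, TRUE))
  vals <- 0.05 * layout$row + rnorm(n, 0, 0.3)
  res <- test_spatial_effect(vals, layout)
  expect_lt(res$row$p_value, 1e-4)
  expect_gt(res$col$p_value, 0.01)

  # pure-noise rejection rate near alpha (quick calibration check)
  set.seed(6)
  hits <- replicate(200, {
    v <- rnorm(200)
    lay <- data.frame(row = sample(1:40, 200, TRUE),
                      col = sample(1:40, 200, TRUE),
                      sample_id = sample(c("A", "B"), 200, TRUE))
    r <- test_spatial_effect(v, lay)
    c(r$row$p_value < 0.05, r$col$p_value < 0.05)
  })
  expect_gte(mean(hits), 0.015)
  expect_lte(mean(hits), 0.09)
  expect_error(test_spatial_effect(1, data.frame(row = 1, col = 1,
                                                 sample_id = "A")),
               "too few spots")
})

test_that("variance components recover simulated inter/intra-array variances", {
  set.seed(44)
  gen <- function(sd_array, sd_resid, n_array = 20L, n_sample = 10L,
                  n_rep = 3L) {
    grid <- expand.grid(array = seq_len(n_array),
                        sample = seq_len(n_sample), rep = seq_len(n_rep))
    arr_eff <- rnorm(n_array, 0, sd_array)
    data.frame(
      x_hat = 0.5 * grid$sample + arr_eff[grid$array] +
        rnorm(nrow(grid), 0, sd_resid),
      sample_id = sprintf("S%d", grid$sample),
      array_id = sprintf("A%d", grid$array))
  }
  # average over replications: with 20 arrays a single draw of the
  # inter-array variance has ~30% sampling error by itself
  vcs <- replicate(6, {
    vc <- estimate_variance_components(gen(1.0, 0.5))
    c(vc$sigma2_array, vc$sigma2_resid)
  })
  expect_lt(abs(mean(vcs[1, ]) - 1.0), 0.20 * 1.0)
  expect_lt(abs(mean(vcs[2, ]) - 0.25), 0.20 * 0.25)

  # null inter-array variance collapses toward zero
  vc0 <- estimate_variance_components(gen(0, 0.5, n_array = 50L))
  expect_lt(vc0$sigma2_array, 0.01 * vc0$sigma2_resid)

  # shifting one sample moves only its fixed effect
  dat <- gen(0.8, 0.4)
  vc1 <- estimate_variance_components(dat)
  dat2 <- dat
  dat2$x_hat[dat2$sample_id == "S3"] <- dat2$x_hat[dat2$sample_id == "S3"] + 5
  vc2 <- estimate_variance_components(dat2)
  expect_equal(vc1$sigma2_array, vc2$sigma2_array, tolerance = 1e-8)
  expect_equal(vc1$sigma2_resid, vc2$sigma2_resid, tolerance = 1e-8)
  expect_equal(unname(vc2$sample_effects["S3"] - vc1$sample_effects["S3"]), 5,
               tolerance = 1e-8)

  # a single array leaves the inter-array variance inestimable
  one <- gen(0, 0.5, n_array = 1L)
  expect_true(is.na(estimate_variance_components(one)$sigma2_array))
})

test_that("analytic power matches stats::power.t.test and the null equals alpha", {
  pc <- power_curve(1.0, 3L, deltas = c(0, 0.5, 1, 2, 4), alpha = 0.05)
  expect_equal(pc$power[1], 0.05)
  ref <- vapply(c(0.5, 1, 2, 4), function(d) {
    stats::power.t.test(n = 3, delta = d, sd = 1, sig.level = 0.05,
                        type = "two.sample", strict = TRUE)$power
  }, numeric(1))
  expect_equal(pc$power[-1], ref, tolerance = 1e-9)
  # monotone in delta and in n
  expect_true(all(diff(pc$power) > 0))
  p_by_n <- vapply(2:6, function(n) power_curve(1, n, 1.5)$power, numeric(1))
  expect_true(all(diff(p_by_n) > 0))
  expect_error(power_curve(1, 1L, 1), "at least 2 replicates")
})
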