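test_that("pooled regression recovers the worked-example parameters", {
  iv <- series_to_intervals(appendix_series())
  fit <- fit_sgr_logv(iv, v0_assumed = 1)
  expect_equal(fit$lam, 3e-4, tolerance = 0.01)
  expect_equal(fit$sgr0, 1e-3, tolerance = 0.01)
  expect_equal(fit$selected_model, "general_gompertz")
  expect_gt(fit$r2, 0.999)
  expect_equal(fit$n_points, 20L)
})

test_that("exact linear data is fitted exactly", {
  iv <- data.frame(lesion_id = "z", t1 = 0:2 * 100, t2 = 1:3 * 100,
                   t_mid = 0, log_gm_volume = c(0, 2, 5),
                   sgr = 0.002 - 1e-4 * c(0, 2, 5))
  fit <- fit_sgr_logv(iv, v0_assumed = 1)
  expect_equal(fit$sgr0, 0.002)
  expect_equal(fit$lam, 1e-4)
  expect_equal(fit$r2, 1)
})

test_that("slope and intercept agree with a closed-form normal-equations oracle", {
  set.seed(201)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- rnorm(n, mean = 0.002 - 3e-4 * x, sd = 1e-4)
    iv <- data.frame(lesion_id = "o", t1 = seq_len(n) - 1, t2 = seq_len(n),
                     t_mid = 0, log_gm_volume = x, sgr = y)
    fit <- fit_sgr_logv(iv, v0_assumed = 1)
    # independent oracle: raw sums arithmetic
    sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
    slope_o <- (n * sxy - sx * sy) / (n * sxx - sx^2)
    int_o <- (sy - slope_o * sx) / n
    expect_equal(fit$slope, slope_o, tolerance = 1e-10)
    expect_equal(fit$intercept, int_o, tolerance = 1e-10)
  }
})

test_that("volume rescaling moves the intercept but not the slope", {
  iv <- series_to_intervals(appendix_series())
  fit <- fit_sgr_logv(iv, v0_assumed = 1)
  for (c_scale in c(1e-3, 42)) {
    iv2 <- iv
    iv2$log_gm_volume <- iv$log_gm_volume + log(c_scale)
    fit2 <- fit_sgr_logv(iv2, v0_assumed = 1)
    expect_equal(fit2$slope, fit$slope)
    expect_equal(fit2$intercept, fit$intercept - fit$slope * log(c_scale))
    # sgr0 at a fixed assumed reference volume shifts accordingly
    expect_equal(fit2$sgr0, fit$sgr0 - fit$slope * log(c_scale))
  }
})

test_that("the fit is invariant to record order", {
  iv <- series_to_intervals(appendix_series())
  set.seed(202)
  ivs <- iv[sample(nrow(iv)), ]
  f1 <- fit_sgr_logv(iv, v0_assumed = 1)
  f2 <- fit_sgr_logv(ivs, v0_assumed = 1)
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$intercept, f2$intercept)
})

test_that("a non-negative slope falls back to the heterogeneous model", {
  iv <- data.frame(lesion_id = "p", t1 = 0:3, t2 = 1:4, t_mid = 0,
                   log_gm_volume = c(0, 1, 2, 3),
                   sgr = c(0.001, 0.0012, 0.0015, 0.0016))
  expect_warning(fit <- fit_sgr_logv(iv, v0_assumed = 1), "truncated")
  expect_identical(fit$lam, 0)
  expect_true(fit$lam_truncated)
  expect_equal(fit$selected_model, "heterogeneous_exponential")
})

test_that("degenerate designs are refused", {
  iv <- series_to_intervals(appendix_series())
  expect_error(fit_sgr_logv(iv[1:2, ], v0_assumed = 1), "3 interval")
  same <- iv[1:4, ]; same$log_gm_volume <- 1.5
  expect_error(fit_sgr_logv(same, v0_assumed = 1), "degenerate")
  expect_error(fit_sgr_logv(iv, v0_assumed = -1), "positive")
})

test_that("per-lesion heterogeneous summary is the time-weighted mean SGR", {
  one <- data.frame(lesion_id = "a", t1 = 0, t2 = 100, t_mid = 50,
                    log_gm_volume = 0.5, sgr = 0.0031)
  expect_equal(describe_heterogeneous(one)$per_lesion$mean_sgr, 0.0031)
  two <- data.frame(lesion_id = "a", t1 = c(0, 100), t2 = c(100, 400),
                    t_mid = 0, log_gm_volume = c(0, 1),
                    sgr = c(0.001, 0.003))
  expect_equal(describe_heterogeneous(two)$per_lesion$mean_sgr, 0.0025)
})

test_that("heterogeneous cohort growth rates are recovered from noiseless data", {
  sim <- simulate_patient(lung_scenario(seed = 5))
  des <- describe_heterogeneous(patient_intervals(sim$series))
  truth <- sim$truth[match(des$per_lesion$lesion_id, sim$truth$lesion_id), ]
  expect_equal(des$per_lesion$mean_sgr, truth$sgr0, tolerance = 1e-10)
  expect_true(all(des$range >= min(truth$sgr0) - 1e-12))
})
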