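test_that("exact exponential accumulation is fitted exactly", {
  k0 <- 0.5 / 365                      # per day
  ft <- log(1:6) / k0
  fit <- fit_formation_rate(data.frame(lesion_id = letters[1:6],
                                       formation_t = ft))
  expect_equal(fit$k, 0.5)
  expect_equal(fit$r2, 1)
  expect_equal(fit$n_lesions, 6L)
  expect_equal(fit$t_first, 0)
})

test_that("two formation times give the saturated doubling rate", {
  fit <- fit_formation_rate(data.frame(lesion_id = c("a", "b"),
                                       formation_t = c(100, 400)))
  expect_equal(fit$k_per_day, log(2) / 300)
  expect_equal(fit$k, 365 * log(2) / 300)
})

test_that("the rate is recovered from noisy exponential inter-formation gaps", {
  set.seed(401)
  k_true <- 0.5; k_day <- k_true / 365
  khat <- replicate(200, {
    gaps <- stats::rexp(9, rate = k_day / diff(log(1:10)))
    ft <- cumsum(c(0, gaps))
    fit_formation_rate(data.frame(lesion_id = sprintf("l%02d", 1:10),
                                  formation_t = ft))$k
  })
  expect_lt(abs(stats::median(khat) - k_true) / k_true, 0.15)
})

test_that("the fit ignores the absolute epoch", {
  ft <- c(0, 200, 900, 1500)
  f1 <- fit_formation_rate(data.frame(lesion_id = letters[1:4],
                                      formation_t = ft))
  f2 <- fit_formation_rate(data.frame(lesion_id = letters[1:4],
                                      formation_t = ft + 5000))
  expect_equal(f1$k, f2$k)
  expect_equal(f1$r2, f2$r2)
})

test_that("predicted counts follow the fitted exponential", {
  k0 <- log(2) / 365                  # doubling per year
  ft <- log(1:6) / (k0)
  fit <- fit_formation_rate(data.frame(lesion_id = letters[1:6],
                                       formation_t = ft))
  expect_equal(predict_count(fit, fit$t_first), 1)
  expect_equal(predict_count(fit, fit$t_first + 365), 2, tolerance = 1e-8)
  # consistent with the number of lesions at the last formation
  expect_equal(predict_count(fit, max(ft)), 6, tolerance = 1e-8)
  # nondecreasing in t
  tt <- seq(0, 4000, by = 250)
  expect_true(all(diff(predict_count(fit, tt)) >= 0))
  expect_warning(predict_count(fit, fit$t_first - 10), "extrapolated")
})

test_that("degenerate formation sets are refused", {
  expect_error(fit_formation_rate(data.frame(lesion_id = "a",
                                             formation_t = 1)),
               "at least 2")
  expect_error(fit_formation_rate(data.frame(lesion_id = c("a", "b"),
                                             formation_t = c(5, 5))),
               "coincide")
  expect_message(
    fit <- fit_formation_rate(data.frame(lesion_id = c("a", "b", "c"),
                                         formation_t = c(0, 300, NA))),
    "dropping")
  expect_equal(fit$n_lesions, 2L)
})

test_that("the Gompertz pathway dates lesions later and yields a larger rate", {
  # the same simulated data, analysed under both growth assumptions
  sim <- simulate_patient(cohort_scenario(noise_cv = 0, seed = 11))
  rep <- analyze_patient(sim)
  expect_equal(rep$formations$pathway, "general_gompertz")
  f_gom <- rep$formations$table
  f_exp <- exponential_formations(sim$series)
  expect_true(all(f_gom$formation_t >
                  f_exp$formation_t[match(f_gom$lesion_id, f_exp$lesion_id)]))
  k_gom <- fit_formation_rate(f_gom)$k
  k_exp <- fit_formation_rate(f_exp)$k
  expect_gt(k_gom, k_exp)
})
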