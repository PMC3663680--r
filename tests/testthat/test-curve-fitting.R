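test_that("exponential fit is exact on noiseless exponential data", {
  ge <- growth_params(sgr0 = 0.002, lam = 0, v0 = 0.7, t0 = 0)
  s <- gomp_series("e1", ge, c(100, 400, 900, 1600))
  f <- fit_exponential(s)
  expect_equal(f$params$sgr0, 0.002, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_equal(f$model, "exponential")
})

test_that("a two-point exponential fit equals the interval SGR", {
  s <- lesion_series("e2", c(0, 250), c(1.0, 1.9))
  f <- fit_exponential(s)
  expect_equal(f$params$sgr0, interval_sgr(1.0, 1.9, 0, 250))
  expect_equal(f$r2, 1)
  expect_error(fit_exponential(lesion_series("x", 5, 1)), "2 measurements")
})

test_that("exponential back-extrapolation recovers a one-cell origin", {
  ge <- growth_params(sgr0 = 0.002, lam = 0, v0 = 1e-9, t0 = 0)
  s <- gomp_series("e3", ge, c(9000, 9180, 9360))
  f <- fit_exponential(s)
  expect_equal(f$formation_time, 0, tolerance = 1e-6)
})

test_that("Gompertz fit recovers noiseless truth from four points", {
  gp <- appendix_params()
  s <- gomp_series("g1", gp, c(400, 1300, 2200, 3100))
  f <- fit_gompertz(s)
  expect_equal(f$params$lam, gp$lam, tolerance = 1e-3)
  # SGR of the fitted curve at unit volume should match the truth at v=1
  expect_equal(instantaneous_sgr(f$params, 1), 0.001, tolerance = 1e-3)
  expect_gt(f$r2, 0.999999)
  expect_true(f$converged)
})

test_that("exactly exponential data drives lambda to the boundary", {
  ge <- growth_params(sgr0 = 0.0015, lam = 0, v0 = 2, t0 = 0)
  s <- gomp_series("g2", ge, c(0, 300, 700, 1200))
  fg <- fit_gompertz(s)
  fe <- fit_exponential(s)
  expect_equal(fg$params$lam, 0)
  expect_equal(fg$params$sgr0, fe$params$sgr0, tolerance = 1e-8)
  expect_equal(fg$sse, fe$sse, tolerance = 1e-10)
  expect_error(fit_gompertz(lesion_series("x", c(0, 100), c(1, 2))),
               "3 measurements")
})

test_that("Gompertz residual never exceeds the exponential residual", {
  set.seed(301)
  for (i in 1:15) {
    gp <- random_params()
    t <- sort(gp$t0 + runif(sample(3:8, 1), 0, 6000))
    v <- volume_at(gp, t) * exp(rnorm(length(t), sd = 0.1))
    s <- lesion_series("n", t, v)
    expect_lte(fit_gompertz(s)$sse, fit_exponential(s)$sse + 1e-10)
  }
})

test_that("fits are equivariant under time shifts and volume rescaling", {
  gp <- appendix_params()
  t <- c(500, 1100, 1900, 2600)
  s <- gomp_series("q", gp, t)
  f <- fit_gompertz(s)
  shifted <- lesion_series("q", t + 100, s$v)
  fs <- fit_gompertz(shifted)
  expect_equal(fs$formation_time, f$formation_time + 100, tolerance = 1e-4)
  scaled <- lesion_series("q", t, s$v * 50)
  fc <- fit_gompertz(scaled)
  expect_equal(fc$params$lam, f$params$lam, tolerance = 1e-6)
  expect_equal(fc$params$v0, f$params$v0 * 50, tolerance = 1e-6)
  # exponential fit: same properties, exactly
  fe <- fit_exponential(s)
  expect_equal(fit_exponential(shifted)$formation_time,
               fe$formation_time + 100)
  expect_equal(fit_exponential(scaled)$params$sgr0, fe$params$sgr0)
})

test_that("model comparison reports evidence without forcing a choice", {
  ge <- growth_params(sgr0 = 0.0015, lam = 0, v0 = 2, t0 = 0)
  s <- gomp_series("c1", ge, c(0, 300, 700, 1200))
  cmp <- compare_models(fit_exponential(s), fit_gompertz(s))
  expect_equal(cmp$delta_r2, 0, tolerance = 1e-10)
  expect_equal(cmp$sgr0_ratio, 1, tolerance = 1e-8)
  expect_equal(cmp$preferred, "indeterminate")

  # strong deceleration over a long window: Gompertz clearly better
  gp <- growth_params(sgr0 = 0.004, lam = 1e-3, v0 = 0.5, t0 = 0)
  s2 <- gomp_series("c2", gp, seq(0, 4000, by = 500))
  cmp2 <- compare_models(fit_exponential(s2), fit_gompertz(s2))
  expect_gt(cmp2$delta_r2, 0.02)
  expect_equal(cmp2$preferred, "gompertz")

  a <- fit_exponential(gomp_series("a", ge, c(0, 100, 200)))
  b <- fit_gompertz(gomp_series("b", ge, c(0, 100, 200, 300)))
  expect_error(compare_models(a, b), "different lesions")
})
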