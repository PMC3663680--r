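# Shared fixtures: the worked-example Gompertz curve (SGR 0.001/day at
# t = 0, unit volume, lambda 0.0003/day, six-monthly visits) and its
# published rounded table, plus small builders.

appendix_params <- function() growth_params(sgr0 = 0.001, lam = 3e-4,
                                            v0 = 1, t0 = 0)

appendix_series <- function(id = "apx") {
  t <- seq(0, 3600, by = 180)
  lesion_series(id, t, volume_at(appendix_params(), t))
}

# printed reference values: t, months, V, geometric-mean V, ln V, SGR
appendix_printed <- function() {
  m <- matrix(c(
       0,   0, 1.00, 1.00, 0.00, 0.00100,
     180,   6, 1.19, 1.09, 0.09, 0.00097,
     360,  12, 1.41, 1.29, 0.26, 0.00092,
     540,  18, 1.65, 1.52, 0.42, 0.00087,
     720,  24, 1.91, 1.77, 0.57, 0.00083,
     900,  30, 2.20, 2.05, 0.72, 0.00078,
    1080,  36, 2.52, 2.35, 0.86, 0.00074,
    1260,  42, 2.86, 2.68, 0.99, 0.00070,
    1440,  48, 3.22, 3.03, 1.11, 0.00067,
    1620,  54, 3.61, 3.41, 1.23, 0.00063,
    1800,  60, 4.02, 3.81, 1.34, 0.00060,
    1980,  66, 4.45, 4.23, 1.44, 0.00057,
    2160,  72, 4.90, 4.67, 1.54, 0.00054,
    2340,  78, 5.37, 5.13, 1.64, 0.00051,
    2520,  84, 5.86, 5.61, 1.72, 0.00048,
    2700,  90, 6.36, 6.11, 1.81, 0.00046,
    2880,  96, 6.88, 6.62, 1.89, 0.00043,
    3060, 102, 7.41, 7.14, 1.97, 0.00041,
    3240, 108, 7.94, 7.67, 2.04, 0.00039,
    3420, 114, 8.49, 8.21, 2.11, 0.00037,
    3600, 120, 9.04, 8.76, 2.17, 0.00035),
    ncol = 6, byrow = TRUE)
  colnames(m) <- c("t", "t_months", "v", "v_geomean", "ln_v", "sgr")
  m
}

# a noiseless series sampled from an arbitrary curve
gomp_series <- function(id, params, times) {
  lesion_series(id, times, volume_at(params, times))
}

# random positive-parameter curve for property loops
random_params <- function() {
  growth_params(sgr0 = runif(1, 1e-4, 0.02),
                lam = runif(1, 1e-5, 1e-3),
                v0 = 10^runif(1, -9, 1),
                t0 = runif(1, -1000, 1000))
}

# lung-like heterogeneous-exponential scenario used in several tests
lung_scenario <- function(seed, noise_cv = 0, n_lesions = 7L) {
  cohort_scenario("heterogeneous_exponential", sgr0 = 0.0023,
                  sgr_dispersion = 0.3, n_lesions = n_lesions,
                  visit_times = seq(22 * 365, 32 * 365, length.out = 32),
                  noise_cv = noise_cv, seed = seed)
}
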