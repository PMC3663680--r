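#' Worked-example table: Gompertz growth sampled every six months
#'
#' Deterministic textbook fixture: a tumour with SGR 0.001/day at t = 0 and
#' unit volume, decelerating with lambda = 0.0003/day, measured every 180
#' days for ten years. Each row pairs the interval SGR of the two
#' consecutive measurements ending at that row with the log geometric mean
#' of their volumes; the first row carries the initial condition (the
#' instantaneous SGR at t = 0) rather than an interval record.
#'
#' @param sgr0 SGR at t = 0, fraction/day.
#' @param lam Growth deceleration constant, 1/day.
#' @param t_step Visit spacing, days.
#' @param n_visits Number of rows (including t = 0).
#' @return Data frame with columns \code{t} (days), \code{t_months},
#'   \code{v}, \code{v_geomean}, \code{ln_v}, \code{sgr}, at full
#'   precision. See \code{\link{format_appendix_table}} for the printed
#'   rounding.
#' @examples
#' format_appendix_table(make_appendix_table())
#' @export
make_appendix_table <- function(sgr0 = 0.001, lam = 3e-4, t_step = 180,
                                n_visits = 21L) {
  gp <- growth_params(sgr0 = sgr0, lam = lam, v0 = 1, t0 = 0)
  t <- t_step * (seq_len(n_visits) - 1L)
  v <- volume_at(gp, t)
  prev <- c(NA_real_, v[-n_visits])
  data.frame(
    t = t,
    t_months = days_to_months(t),
    v = v,
    v_geomean = c(v[1L], sqrt(prev[-1L] * v[-1L])),
    ln_v = c(log(v[1L]), paired_log_volume(prev[-1L], v[-1L])),
    sgr = c(sgr0, interval_sgr(prev[-1L], v[-1L], t[-n_visits], t[-1L])))
}

#' Round the worked-example table to its printed precision
#'
#' Volumes and log volumes to 2 decimals, SGR to 5 decimals.
#'
#' @param tab Output of \code{\link{make_appendix_table}}.
#' @return The table with rounded numeric columns.
#' @export
format_appendix_table <- function(tab) {
  tab$v <- round(tab$v, 2)
  tab$v_geomean <- round(tab$v_geomean, 2)
  tab$ln_v <- round(tab$ln_v, 2)
  tab$sgr <- round(tab$sgr, 5)
  tab
}

#' Define a synthetic metastatic cohort scenario
#'
#' Ground-truth description of a simulated patient used for end-to-end
#' validation: either all metastases grow along one shared Gompertz curve
#' from the one-cell volume (\code{"general_gompertz"}) and differ only in
#' formation time, or each grows exponentially with its own rate drawn
#' from a lognormal spread (\code{"heterogeneous_exponential"}). New
#' metastases accumulate exponentially at rate \code{formation_rate_k};
#' lesions are observed on a fixed visit schedule with multiplicative
#' lognormal measurement noise and a detection threshold.
#'
#' Defaults emulate a patient of the kind that motivates the method: six
#' liver metastases under a shared Gompertz model with SGR 0.79 %/day at
#' one cell and lambda 0.00023/day, followed with eight annual scans once
#' lesions become detectable.
#'
#' @param truth_model \code{"general_gompertz"} or
#'   \code{"heterogeneous_exponential"}.
#' @param sgr0 SGR at the one-cell volume, fraction/day (the lognormal
#'   median of per-lesion rates in the heterogeneous case).
#' @param lam Growth deceleration constant, 1/day (forced to 0 for the
#'   heterogeneous-exponential truth).
#' @param sgr_dispersion Lognormal sigma of per-lesion SGR
#'   (heterogeneous case only).
#' @param formation_rate_k Exponential accumulation rate of metastasis
#'   count, 1/year.
#' @param n_lesions Number of metastases formed.
#' @param visit_times Observation times, days (epoch = formation of the
#'   first metastasis).
#' @param noise_cv Fractional multiplicative volume measurement error
#'   (lognormal sigma \code{log(1 + noise_cv)}, unit mean).
#' @param detection_volume Smallest true volume visible on imaging, cm^3.
#' @param one_cell_volume Volume of one cell, cm^3.
#' @param formation_jitter Lognormal sigma multiplying inter-formation
#'   gaps (0 = deterministic exponential accumulation).
#' @param seed Integer RNG seed; same seed, same patient.
#' @return List of class \code{"cohort_scenario"}.
#' @export
cohort_scenario <- function(truth_model = c("general_gompertz",
                                            "heterogeneous_exponential"),
                            sgr0 = 0.0079, lam = 0.00023,
                            sgr_dispersion = 0.3,
                            formation_rate_k = 0.5,
                            n_lesions = 6L,
                            visit_times = 365 * (10:17),
                            noise_cv = 0.1,
                            detection_volume = 0.1,
                            one_cell_volume = 1e-9,
                            formation_jitter = 0,
                            seed = 1L) {
  truth_model <- match.arg(truth_model)
  if (truth_model == "heterogeneous_exponential") lam <- 0
  stopifnot(n_lesions >= 1L, noise_cv >= 0, sgr_dispersion >= 0,
            formation_jitter >= 0, length(visit_times) >= 1L,
            formation_rate_k > 0, sgr0 > 0, lam >= 0)
  if (!(detection_volume > one_cell_volume && one_cell_volume > 0))
    stop("need detection_volume > one_cell_volume > 0")
  structure(list(truth_model = truth_model, sgr0 = sgr0, lam = lam,
                 sgr_dispersion = sgr_dispersion,
                 formation_rate_k = formation_rate_k,
                 n_lesions = as.integer(n_lesions),
                 visit_times = sort(as.numeric(visit_times)),
                 noise_cv = noise_cv,
                 detection_volume = detection_volume,
                 one_cell_volume = one_cell_volume,
                 formation_jitter = formation_jitter,
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

#' Simulate a patient's longitudinal lesion measurements
#'
#' Draws a cohort from a \code{\link{cohort_scenario}}. Formation times:
#' the first metastasis forms at day 0 and the gap before lesion i + 1 has
#' mean \eqn{(\ln(i+1) - \ln i)/k}, so the cumulative count grows
#' exponentially at rate k in expectation (exactly, when
#' \code{formation_jitter = 0}). Each lesion grows from one cell per the
#' truth model. A visit records a lesion only when its true volume has
#' reached the detection threshold; the recorded volume carries unit-mean
#' lognormal noise (so the mean log measurement error is
#' \eqn{-\sigma^2/2}).
#'
#' @param scenario A \code{\link{cohort_scenario}}.
#' @return List of class \code{"simulated_patient"}: \code{scenario};
#'   \code{measurements} (data frame \code{lesion_id}, \code{t}, \code{v}
#'   of detected records); \code{series} (named list of
#'   \code{\link{lesion_series}} for lesions with >= 1 record);
#'   \code{truth} (data frame \code{lesion_id}, \code{formation_t},
#'   \code{sgr0}, \code{lam} for every lesion, detected or not).
#' @export
simulate_patient <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  sc <- scenario
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(sc$seed)

  k_day <- sc$formation_rate_k / 365
  n <- sc$n_lesions
  gaps <- if (n > 1L) diff(log(seq_len(n))) / k_day else numeric(0)
  if (sc$formation_jitter > 0 && n > 1L)
    gaps <- gaps * stats::rlnorm(n - 1L,
                                 meanlog = -sc$formation_jitter^2 / 2,
                                 sdlog = sc$formation_jitter)
  form_t <- cumsum(c(0, gaps))
  ids <- sprintf("L%02d", seq_len(n))

  lesion_sgr <- if (sc$truth_model == "heterogeneous_exponential")
    sc$sgr0 * stats::rlnorm(n, meanlog = 0, sdlog = sc$sgr_dispersion)
  else rep(sc$sgr0, n)

  sigma <- log(1 + sc$noise_cv)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gp <- growth_params(sgr0 = lesion_sgr[i], lam = sc$lam,
                        v0 = sc$one_cell_volume, t0 = form_t[i])
    vis <- sc$visit_times[sc$visit_times >= form_t[i]]
    if (!length(vis)) next
    v_true <- volume_at(gp, vis)
    det <- v_true >= sc$detection_volume
    if (!any(det)) next
    v_meas <- v_true[det]
    if (sigma > 0)
      v_meas <- v_meas * stats::rlnorm(sum(det), meanlog = -sigma^2 / 2,
                                       sdlog = sigma)
    rows[[i]] <- data.frame(lesion_id = ids[i], t = vis[det], v = v_meas,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  meas <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  if (is.null(meas) || nrow(meas) == 0L)
    stop(sprintf(paste0("scenario yields no detectable lesion: last visit day %g, ",
                        "detection threshold %g cm^3, truth model %s"),
                 max(sc$visit_times), sc$detection_volume, sc$truth_model))
  structure(list(
    scenario = sc,
    measurements = meas,
    series = split_series(meas),
    truth = data.frame(lesion_id = ids, formation_t = form_t,
                       sgr0 = lesion_sgr, lam = sc$lam,
                       stringsAsFactors = FALSE)),
    class = "simulated_patient")
}
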