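#' Pooled regression of interval SGR on log volume
#'
#' The core estimator. Because the instantaneous SGR of a Gompertzian
#' tumour is linear in the log of its volume,
#' \eqn{SGR = SGR_0 - \lambda \ln(V/V_0)},
#' the regression of interval SGR on log geometric-mean volume -- pooled
#' over all metastases of a patient, with no time coordinate -- identifies
#' the shared (general) growth model without knowing any lesion's age:
#' \eqn{\lambda} = minus the slope, and
#' \eqn{SGR_0 = } intercept \eqn{ + } slope \eqn{\times \ln V_0} for the
#' assumed reference volume \eqn{V_0} (by default one cell, 1e-9 cm^3).
#'
#' Model selection: a significantly negative slope indicates that growth
#' deceleration dominates the growth-rate variation, so a general Gompertz
#' model is selected; otherwise the lesions are best described as growing
#' exponentially with heterogeneous rates. Negative and zero SGR records
#' are always included.
#'
#' @param intervals An \code{"sgr_intervals"} data frame (see
#'   \code{\link{series_to_intervals}}); at least 3 records.
#' @param v0_assumed Reference volume at which \code{sgr0} is reported,
#'   cm^3. Default 1e-9 (one cell).
#' @param alpha Significance level for the slope test used in model
#'   selection. Default 0.05.
#' @return An object of class \code{"linearized_fit"}: list with
#'   \code{intercept}, \code{slope}, \code{lam}, \code{sgr0},
#'   \code{v0_assumed}, \code{r2}, \code{p_slope}, \code{n_points},
#'   \code{n_lesions}, \code{selected_model} (\code{"general_gompertz"} or
#'   \code{"heterogeneous_exponential"}), \code{lam_truncated} (TRUE when a
#'   non-negative slope was truncated to \code{lam = 0}).
#' @export
fit_sgr_logv <- function(intervals, v0_assumed = 1e-9, alpha = 0.05) {
  stopifnot(is.data.frame(intervals),
            all(c("log_gm_volume", "sgr") %in% names(intervals)))
  if (!is.finite(v0_assumed) || v0_assumed <= 0)
    stop("'v0_assumed' must be positive")
  n <- nrow(intervals)
  if (n < 3L) stop("at least 3 interval records are required")
  x <- intervals$log_gm_volume
  y <- intervals$sgr
  if (diff(range(x)) == 0)
    stop("degenerate design: all log volumes identical")
  fit <- stats::lm(y ~ x)
  # noiseless data is a legitimate input; summary.lm's "essentially
  # perfect fit" warning is noise here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  p_slope <- sm$coefficients[2L, 4L]
  r2 <- sm$r.squared
  lam_trunc <- slope >= 0
  if (lam_trunc)
    warning("non-negative slope: lambda truncated to 0 (no deceleration signal)")
  selected <- if (slope < 0 && p_slope < alpha) "general_gompertz"
              else "heterogeneous_exponential"
  structure(list(
    intercept = intercept, slope = slope,
    lam = if (lam_trunc) 0 else -slope,
    sgr0 = intercept + slope * log(v0_assumed),
    v0_assumed = v0_assumed, r2 = r2, p_slope = p_slope,
    n_points = n,
    n_lesions = length(unique(intervals$lesion_id)),
    alpha = alpha,
    selected_model = selected, lam_truncated = lam_trunc),
    class = "linearized_fit")
}

#' @export
print.linearized_fit <- function(x, ...) {
  cat("Pooled SGR vs log-volume regression\n")
  cat(sprintf("  %d interval records from %d lesion(s)\n",
              x$n_points, x$n_lesions))
  cat(sprintf("  slope = %.3g, intercept = %.3g, r2 = %.3f, p(slope) = %.3g\n",
              x$slope, x$intercept, x$r2, x$p_slope))
  cat(sprintf("  lambda = %.3g /day, SGR0 = %.3g /day (%.2g %%/day) at V0 = %g cm^3\n",
              x$lam, x$sgr0, 100 * x$sgr0, x$v0_assumed))
  cat(sprintf("  selected model: %s\n", x$selected_model))
  invisible(x)
}

#' General growth curve implied by a linearized fit
#'
#' @param fit A \code{\link{fit_sgr_logv}} result.
#' @return A \code{\link{growth_params}} with \code{t0 = 0} anchored at the
#'   assumed reference volume (the curve is at \code{v0_assumed} at t = 0).
#' @export
general_curve <- function(fit) {
  stopifnot(inherits(fit, "linearized_fit"))
  growth_params(sgr0 = fit$sgr0, lam = fit$lam, v0 = fit$v0_assumed, t0 = 0)
}

#' Per-lesion exponential growth-rate summary
#'
#' Reporting companion for the heterogeneous-exponential branch: each
#' lesion's time-weighted mean SGR (total log growth divided by total
#' observed time, i.e. intervals weighted by their length) and the spread
#' across lesions.
#'
#' @param intervals An \code{"sgr_intervals"} data frame with >= 1 record.
#' @return List with \code{per_lesion} (data frame: \code{lesion_id},
#'   \code{mean_sgr}, \code{n_intervals}, \code{total_days}) and
#'   \code{range} (min/max of the per-lesion means).
#' @export
describe_heterogeneous <- function(intervals) {
  stopifnot(is.data.frame(intervals), nrow(intervals) >= 1L)
  dt <- intervals$t2 - intervals$t1
  per <- lapply(split(seq_len(nrow(intervals)), intervals$lesion_id),
                function(i) {
    data.frame(lesion_id = intervals$lesion_id[i[1L]],
               mean_sgr = sum(intervals$sgr[i] * dt[i]) / sum(dt[i]),
               n_intervals = length(i),
               total_days = sum(dt[i]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  per <- per[order(per$lesion_id), , drop = FALSE]
  rownames(per) <- NULL
  list(per_lesion = per, range = range(per$mean_sgr))
}
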