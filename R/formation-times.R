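#' Formation time of one lesion under the general growth curve
#'
#' Under the general-model assumption, every metastasis of a patient grows
#' along one shared curve and lesions differ only by their time origin.
#' This fit slides the general curve in time to match one lesion's
#' measurements: it finds the scalar shift s minimising
#' \eqn{\sum_i [\ln v_i - \ln V(t_i - s)]^2}, where V is the general curve
#' anchored at the one-cell volume at time 0. The shift s is then the
#' lesion's formation time (the day the shifted curve is at one cell).
#'
#' The general curve must be anchored at the one-cell volume
#' (\code{v0 = } one cell, \code{t0 = 0}), as produced by
#' \code{\link{general_curve}}. A single-point series is solved in closed
#' form; otherwise a deterministic bracketed 1-D search
#' (\code{\link[stats]{optimize}}) with a bracket guaranteed to contain
#' the single-point solution is used.
#'
#' @param series A \code{\link{lesion_series}}.
#' @param general \code{\link{growth_params}} of the general model
#'   (\code{lam >= 0}, anchored at one cell, positive \code{sgr0}).
#' @return List of class \code{"formation_estimate"}: \code{lesion_id},
#'   \code{formation_t} (days), \code{sse} (log space), \code{n_points}.
#' @export
shift_fit <- function(series, general) {
  series <- as_series(series)
  stopifnot(inherits(general, "growth_params"))
  if (general$sgr0 <= 0)
    stop("general curve must have positive sgr0")
  plateau <- plateau_volume(general)
  if (any(series$v >= plateau))
    stop(sprintf("lesion '%s': volume unreachable under general model (at/above plateau %g)",
                 series$lesion_id[1L], plateau))
  n <- nrow(series)
  # closed-form single-point inversion; also the bracket centre
  s1 <- series$t[1L] - time_at_volume(general, series$v[1L]) + general$t0
  if (n == 1L) {
    return(structure(list(lesion_id = series$lesion_id[1L],
                          formation_t = s1, sse = 0, n_points = 1L),
                     class = "formation_estimate"))
  }
  y <- log(series$v)
  obj <- function(s) sum((y - log(volume_at(general, series$t - s + general$t0)))^2)
  span <- diff(range(series$t))
  lo <- s1 - 10 * span
  hi <- series$t[1L]
  opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-10)
  # polish: optimize() can stop short of machine precision near flat minima
  s_hat <- opt$minimum
  structure(list(lesion_id = series$lesion_id[1L],
                 formation_t = s_hat, sse = obj(s_hat), n_points = n),
            class = "formation_estimate")
}

#' @export
print.formation_estimate <- function(x, ...) {
  cat(sprintf("lesion '%s': formation at day %.1f (sse = %.3g over %d points)\n",
              x$lesion_id, x$formation_t, x$sse, x$n_points))
  invisible(x)
}

#' Formation times for all lesions of a patient
#'
#' Applies \code{\link{shift_fit}} to every lesion and returns the
#' estimates sorted by formation time (ties broken by lesion id), the
#' order in which the formation-rate fit consumes them.
#'
#' @param series_list List of \code{\link{lesion_series}} (or a patient
#'   measurement data frame).
#' @param general General-model \code{\link{growth_params}}.
#' @return Data frame of class \code{"formation_table"} with columns
#'   \code{lesion_id}, \code{formation_t}, \code{sse}, \code{n_points},
#'   sorted ascending by \code{formation_t}.
#' @export
estimate_all_formations <- function(series_list, general) {
  if (is.data.frame(series_list)) series_list <- split_series(series_list)
  stopifnot(length(series_list) >= 1L)
  ests <- lapply(series_list, function(s) {
    tryCatch(shift_fit(s, general), error = function(e)
      stop(sprintf("formation fit failed for lesion '%s': %s",
                   s$lesion_id[1L], conditionMessage(e)), call. = FALSE))
  })
  out <- data.frame(
    lesion_id = vapply(ests, `[[`, character(1L), "lesion_id"),
    formation_t = vapply(ests, `[[`, numeric(1L), "formation_t"),
    sse = vapply(ests, `[[`, numeric(1L), "sse"),
    n_points = vapply(ests, `[[`, integer(1L), "n_points"),
    stringsAsFactors = FALSE)
  out <- out[order(out$formation_t, out$lesion_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("formation_table", "data.frame"))
}

#' Formation times from per-lesion exponential fits
#'
#' Companion for the heterogeneous-exponential branch: with a different
#' growth rate per lesion there is no shared curve to shift, so each
#' lesion's formation time is the back-extrapolation of its own
#' exponential fit to one cell. Lesions with fewer than 2 points or
#' non-positive growth yield \code{NA} and are reported with a reason.
#'
#' @param series_list List of \code{\link{lesion_series}} (or a patient
#'   measurement data frame).
#' @param one_cell One-cell volume, cm^3.
#' @return A \code{"formation_table"} data frame (see
#'   \code{\link{estimate_all_formations}}) with an extra \code{note}
#'   column; rows with \code{NA} formation times sort last.
#' @export
exponential_formations <- function(series_list, one_cell = 1e-9) {
  if (is.data.frame(series_list)) series_list <- split_series(series_list)
  rows <- lapply(series_list, function(s) {
    if (nrow(s) < 2L)
      return(data.frame(lesion_id = s$lesion_id[1L], formation_t = NA_real_,
                        sse = NA_real_, n_points = nrow(s),
                        note = "fewer than 2 points",
                        stringsAsFactors = FALSE))
    f <- fit_exponential(s, one_cell = one_cell)
    data.frame(lesion_id = f$lesion_id, formation_t = f$formation_time,
               sse = f$sse, n_points = f$n_points,
               note = if (is.finite(f$formation_time)) ""
                      else "non-growing lesion",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$formation_t, out$lesion_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("formation_table", "data.frame"))
}
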