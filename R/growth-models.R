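#' Growth-curve parameters
#'
#' Container for the parameters of an exponential or Gompertzian tumour
#' growth curve. The exponential model is the \code{lam = 0} member of the
#' same family, so every downstream routine handles both models through one
#' type.
#'
#' The Gompertzian curve is
#' \deqn{V(t) = V_0 \exp\!\left[\frac{SGR_0}{\lambda}
#'   \left(1 - e^{-\lambda (t - t_0)}\right)\right],}
#' where \eqn{SGR_0} is the specific growth rate at the reference time
#' \eqn{t_0} (at which the volume is \eqn{V_0}) and \eqn{\lambda} is the
#' growth deceleration constant. As \eqn{\lambda \to 0} the curve reduces
#' to exponential growth \eqn{V_0 e^{SGR_0 (t - t_0)}}.
#'
#' @param sgr0 Specific growth rate at the reference point, fraction/day.
#'   Negative and zero values are allowed (shrinking or static lesions are
#'   kept, never discarded).
#' @param lam Growth deceleration constant, 1/day; must be >= 0.
#'   \code{lam = 0} selects the exponential model.
#' @param v0 Reference volume (cm^3 or arbitrary units); must be > 0.
#' @param t0 Reference time in days.
#' @return An object of class \code{"growth_params"}.
#' @examples
#' gp <- growth_params(sgr0 = 0.001, lam = 3e-4, v0 = 1, t0 = 0)
#' volume_at(gp, 3600)
#' @export
growth_params <- function(sgr0, lam = 0, v0 = 1, t0 = 0) {
  stopifnot(length(sgr0) == 1L, length(lam) == 1L,
            length(v0) == 1L, length(t0) == 1L)
  if (!is.finite(sgr0)) stop("'sgr0' must be finite")
  if (!is.finite(lam) || lam < 0) stop("'lam' must be finite and >= 0")
  if (!is.finite(v0) || v0 <= 0) stop("'v0' must be positive")
  if (!is.finite(t0)) stop("'t0' must be finite")
  structure(list(sgr0 = as.numeric(sgr0), lam = as.numeric(lam),
                 v0 = as.numeric(v0), t0 = as.numeric(t0)),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  model <- if (x$lam == 0) "exponential" else "Gompertz"
  cat(sprintf("%s growth curve: SGR0 = %g /day, lambda = %g /day, V0 = %g at t0 = %g d\n",
              model, x$sgr0, x$lam, x$v0, x$t0))
  if (x$lam > 0)
    cat(sprintf("  plateau volume: %g\n", plateau_volume(x)))
  invisible(x)
}

# Exponential branch is used when lam*|t - t0| is below this, so the
# lam -> 0 limit is numerically continuous (avoids 0/0).
.lam_switch_tol <- 1e-9

#' Volume of the growth curve at given times
#'
#' Evaluates the exponential (\code{lam = 0}) or Gompertzian growth curve.
#' Vectorised over \code{t}.
#'
#' @param params A \code{\link{growth_params}} object.
#' @param t Time(s) in days.
#' @return Volume(s), same units as \code{params$v0}.
#' @export
volume_at <- function(params, t) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(t))) stop("'t' must be finite")
  dt <- t - params$t0
  lam <- params$lam
  expo <- lam * abs(dt) < .lam_switch_tol
  out <- numeric(length(dt))
  out[expo] <- params$v0 * exp(params$sgr0 * dt[expo])
  if (any(!expo))
    out[!expo] <- params$v0 *
      exp((params$sgr0 / lam) * (1 - exp(-lam * dt[!expo])))
  out
}

#' Instantaneous specific growth rate at a given volume
#'
#' The time-eliminated form of the Gompertz model:
#' \eqn{SGR(V) = SGR_0 - \lambda \ln(V / V_0)}. For \code{lam = 0}
#' the SGR is constant at \code{sgr0} regardless of volume.
#'
#' @param params A \code{\link{growth_params}} object.
#' @param v Volume(s); must be > 0.
#' @return SGR in fraction/day.
#' @export
instantaneous_sgr <- function(params, v) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(v) | v <= 0)) stop("'v' must be positive and finite")
  params$sgr0 - params$lam * log(v / params$v0)
}

#' Plateau (asymptotic) volume of a Gompertz curve
#'
#' \eqn{V_\infty = V_0 e^{SGR_0/\lambda}}. Infinite for the exponential
#' model with positive growth.
#'
#' @param params A \code{\link{growth_params}} object.
#' @return Plateau volume; \code{Inf} when \code{lam = 0} and
#'   \code{sgr0 > 0}.
#' @export
plateau_volume <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  if (params$lam == 0) {
    if (params$sgr0 > 0) return(Inf)
    if (params$sgr0 < 0) return(0)
    return(params$v0)
  }
  params$v0 * exp(params$sgr0 / params$lam)
}

#' Convert specific growth rate to doubling time, and back
#'
#' \eqn{DT = \ln 2 / SGR}. A non-positive SGR has no finite doubling time
#' and raises a dedicated error condition (\code{"metagrowth_no_doubling"}),
#' distinct from invalid input.
#'
#' @param sgr Specific growth rate, fraction/day.
#' @return Doubling time in days.
#' @export
sgr_to_dt <- function(sgr) {
  if (any(!is.finite(sgr))) stop("'sgr' must be finite")
  if (any(sgr <= 0))
    stop(structure(class = c("metagrowth_no_doubling", "error", "condition"),
                   list(message = "non-positive SGR has no finite doubling time",
                        call = sys.call())))
  log(2) / sgr
}

#' @rdname sgr_to_dt
#' @param dt Doubling time in days; must be > 0.
#' @export
dt_to_sgr <- function(dt) {
  if (any(!is.finite(dt) | dt <= 0)) stop("'dt' must be positive and finite")
  log(2) / dt
}

#' Format a duration in days as whole months
#'
#' Reporting convention: 1 month = 30 days, rounded half away from zero.
#' Days remain the canonical internal unit; months appear only in
#' formatted output.
#'
#' @param days Duration(s) in days.
#' @param label Append \code{" months"} to the result?
#' @return Integer month count (or labelled character when
#'   \code{label = TRUE}).
#' @examples
#' days_to_months(sgr_to_dt(0.011))   # 2
#' days_to_months(sgr_to_dt(0.0014))  # 17
#' @export
days_to_months <- function(days, label = FALSE) {
  x <- days / 30
  m <- sign(x) * floor(abs(x) + 0.5)  # round half away from zero
  if (label) paste(m, "months") else m
}

#' Time at which the growth curve reaches a target volume
#'
#' Closed-form inversion of the growth curve, used e.g. to back-extrapolate
#' a lesion to the one-cell volume (1e-9 cm^3). For \code{lam > 0} the
#' target must lie strictly below the plateau volume.
#'
#' @param params A \code{\link{growth_params}} object with
#'   \code{sgr0 != 0}.
#' @param v_target Target volume(s); must be > 0 and reachable.
#' @return Time(s) in days at which \code{volume_at(params, t) == v_target}.
#' @export
time_at_volume <- function(params, v_target) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(v_target) | v_target <= 0))
    stop("'v_target' must be positive and finite")
  if (params$sgr0 == 0) stop("static curve (sgr0 = 0) cannot be inverted")
  lr <- log(v_target / params$v0)
  if (params$lam == 0) return(params$t0 + lr / params$sgr0)
  arg <- 1 - (params$lam / params$sgr0) * lr
  if (any(arg <= 0))
    stop("unreachable volume: target at or above the Gompertz plateau")
  params$t0 - log(arg) / params$lam
}
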