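#' Build a validated lesion measurement series
#'
#' A lesion series is a data frame of one lesion's volume measurements with
#' columns \code{lesion_id}, \code{t} (days) and \code{v} (cm^3), sorted by
#' time. Volumes must be strictly positive: a volume of 0 means the lesion
#' was not visible and belongs to the detection layer, not here. Duplicate
#' time points make the interval SGR undefined and are rejected.
#'
#' @param lesion_id Lesion identifier (single string).
#' @param t Measurement times, days.
#' @param v Measured volumes, cm^3; all > 0.
#' @return A data frame of class \code{"lesion_series"} sorted by \code{t}.
#' @export
lesion_series <- function(lesion_id, t, v) {
  stopifnot(length(lesion_id) == 1L, length(t) == length(v), length(t) >= 1L)
  if (any(!is.finite(t))) stop("measurement times must be finite")
  if (any(!is.finite(v) | v <= 0))
    stop("volumes must be positive; zero/invisible measurements are not series members")
  if (anyDuplicated(t))
    stop(sprintf("duplicate time points in lesion '%s'", lesion_id))
  o <- order(t)
  structure(data.frame(lesion_id = as.character(lesion_id),
                       t = as.numeric(t)[o], v = as.numeric(v)[o],
                       stringsAsFactors = FALSE),
            class = c("lesion_series", "data.frame"))
}

#' Interval specific growth rate between two measurements
#'
#' \eqn{SGR = \ln(V_2/V_1) / (t_2 - t_1)}. Zero and negative values are
#' legitimate growth rates and are returned unchanged.
#'
#' @param v1,v2 Volumes at \code{t1} and \code{t2}; both > 0.
#' @param t1,t2 Times in days with \code{t2 > t1}.
#' @return SGR in fraction/day.
#' @export
interval_sgr <- function(v1, v2, t1, t2) {
  if (any(!is.finite(c(v1, v2)) | c(v1, v2) <= 0))
    stop("volumes must be positive and finite")
  if (any(t2 <= t1)) stop("'t2' must be greater than 't1'")
  log(v2 / v1) / (t2 - t1)
}

#' Log geometric-mean volume of a measurement pair
#'
#' The volume coordinate paired with each interval SGR:
#' \eqn{(\ln V_1 + \ln V_2)/2 = \ln\sqrt{V_1 V_2}}.
#'
#' @param v1,v2 Volumes; both > 0.
#' @return Natural log of the geometric mean volume.
#' @export
paired_log_volume <- function(v1, v2) {
  if (any(!is.finite(c(v1, v2)) | c(v1, v2) <= 0))
    stop("volumes must be positive and finite")
  (log(v1) + log(v2)) / 2
}

#' Interval SGR records for one lesion
#'
#' Converts a lesion series of n measurements into the n - 1 consecutive-pair
#' records used by the pooled SGR-vs-log-volume regression: for each pair of
#' consecutive measurements, the interval SGR and the log geometric-mean
#' volume. Consecutive pairs only -- all-pairs differencing would correlate
#' the errors. \code{t_mid} is carried for diagnostics; the regression
#' deliberately uses no time coordinate.
#'
#' @param series A \code{\link{lesion_series}} (or a data frame with columns
#'   \code{lesion_id}, \code{t}, \code{v} for one lesion).
#' @return Data frame of class \code{"sgr_intervals"} with columns
#'   \code{lesion_id}, \code{t1}, \code{t2}, \code{t_mid},
#'   \code{log_gm_volume}, \code{sgr}; zero rows (with a message) for a
#'   single-measurement series.
#' @export
series_to_intervals <- function(series) {
  if (!inherits(series, "lesion_series"))
    series <- lesion_series(series$lesion_id[1], series$t, series$v)
  n <- nrow(series)
  if (n < 2L) {
    message(sprintf("lesion '%s': fewer than 2 measurements, no intervals",
                    series$lesion_id[1]))
    out <- data.frame(lesion_id = character(), t1 = numeric(),
                      t2 = numeric(), t_mid = numeric(),
                      log_gm_volume = numeric(), sgr = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("sgr_intervals", "data.frame")))
  }
  i <- seq_len(n - 1L)
  out <- data.frame(
    lesion_id = series$lesion_id[i],
    t1 = series$t[i], t2 = series$t[i + 1L],
    t_mid = (series$t[i] + series$t[i + 1L]) / 2,
    log_gm_volume = paired_log_volume(series$v[i], series$v[i + 1L]),
    sgr = interval_sgr(series$v[i], series$v[i + 1L],
                       series$t[i], series$t[i + 1L]),
    stringsAsFactors = FALSE)
  structure(out, class = c("sgr_intervals", "data.frame"))
}

#' Interval records for every lesion of a patient
#'
#' @param series_list A list of \code{\link{lesion_series}}, or a patient
#'   measurement data frame with columns \code{lesion_id}, \code{t},
#'   \code{v} covering several lesions.
#' @return One \code{"sgr_intervals"} data frame, lesions concatenated.
#' @export
patient_intervals <- function(series_list) {
  if (is.data.frame(series_list))
    series_list <- split_series(series_list)
  parts <- lapply(series_list, series_to_intervals)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  structure(out, class = c("sgr_intervals", "data.frame"))
}

#' Split a patient measurement table into lesion series
#'
#' @param measurements Data frame with columns \code{lesion_id}, \code{t},
#'   \code{v}.
#' @return Named list of \code{\link{lesion_series}}, one per lesion, in
#'   order of first appearance.
#' @export
split_series <- function(measurements) {
  stopifnot(all(c("lesion_id", "t", "v") %in% names(measurements)))
  ids <- unique(measurements$lesion_id)
  out <- lapply(ids, function(id) {
    m <- measurements[measurements$lesion_id == id, , drop = FALSE]
    lesion_series(id, m$t, m$v)
  })
  names(out) <- ids
  out
}
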