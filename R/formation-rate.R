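#' Exponential metastasis formation-rate fit
#'
#' Fits an exponential increase to the cumulative number of metastases
#' versus formation time. With lesions sorted by formation time and rank
#' i = 1..n, the model is \eqn{N(t) = e^{k (t - t_1)}}: least squares of
#' \eqn{\ln i} on \eqn{t_i - t_1} through the origin, so the count is
#' exactly 1 at the formation of the first metastasis. k is reported per
#' year (1 year = 365 days); only differences of formation times enter,
#' so the patient epoch is irrelevant.
#'
#' @param formations A \code{"formation_table"} (see
#'   \code{\link{estimate_all_formations}}) or data frame with columns
#'   \code{lesion_id}, \code{formation_t}; rows with \code{NA} formation
#'   times are dropped with a message. At least 2 finite times, not all
#'   coincident.
#' @return Object of class \code{"rate_fit"}: \code{k} (1/year),
#'   \code{k_per_day}, \code{t_first} (days), \code{r2}, \code{n_lesions}.
#' @export
fit_formation_rate <- function(formations) {
  stopifnot(is.data.frame(formations),
            all(c("lesion_id", "formation_t") %in% names(formations)))
  keep <- is.finite(formations$formation_t)
  if (any(!keep))
    message(sprintf("dropping %d lesion(s) without a finite formation time",
                    sum(!keep)))
  ft <- sort(formations$formation_t[keep])
  n <- length(ft)
  if (n < 2L) stop("formation-rate fit requires at least 2 formation times")
  if (diff(range(ft)) == 0)
    stop("all formation times coincide; rate undefined")
  x <- ft - ft[1L]
  y <- log(seq_len(n))
  slope <- sum(x * y) / sum(x * x)       # through-origin OLS
  sse <- sum((y - slope * x)^2)
  sst <- sum(y^2)                         # origin-constrained total SS
  structure(list(k = slope * 365, k_per_day = slope, t_first = ft[1L],
                 r2 = 1 - sse / sst, n_lesions = n),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("metastasis formation rate: k = %.3g /year over %d lesions (r2 = %.3f)\n",
              x$k, x$n_lesions, x$r2))
  cat(sprintf("  first metastasis formed at day %.1f\n", x$t_first))
  invisible(x)
}

#' Expected number of metastases at a time point
#'
#' \eqn{N(t) = e^{k (t - t_1)}}, the continuous expectation of the fitted
#' exponential accumulation; 1 at the formation of the first metastasis.
#' Times before the first formation extrapolate to values below 1 and
#' raise a warning.
#'
#' @param fit A \code{\link{fit_formation_rate}} result.
#' @param t Time(s) in days (same epoch as the formation times).
#' @return Expected continuous count(s); round for an integer estimate.
#' @export
predict_count <- function(fit, t) {
  stopifnot(inherits(fit, "rate_fit"))
  if (any(t < fit$t_first))
    warning("time(s) before the first formation: extrapolated count < 1")
  exp(fit$k_per_day * (t - fit$t_first))
}
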