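#' Read longitudinal lesion measurements
#'
#' Reads a patient's measurement table (CSV or TSV, UTF-8, header
#' required, \code{#} comment lines ignored) with columns
#' \code{lesion_id}, \code{time} and \code{volume_cm3}. \code{time} is
#' either numeric days or an ISO-8601 date; dates are converted to days
#' from the epoch (the earliest date in the file when no epoch is given).
#'
#' @param path Input file path.
#' @param sep Field separator; guessed from the extension
#'   (\code{.tsv}/\code{.txt} = tab, otherwise comma) when \code{NULL}.
#' @param epoch Optional \code{Date} (or parseable string) mapped to day
#'   0; used for calendar-year reporting.
#' @param strict If \code{TRUE} (default) non-positive volumes are an
#'   error naming the offending line; if \code{FALSE} they are dropped
#'   with a message.
#' @param patient_id Identifier stored in the dataset; default the file
#'   name.
#' @return List of class \code{"patient_dataset"}: \code{patient_id},
#'   \code{epoch} (\code{Date} or \code{NA}), \code{measurements} (data
#'   frame \code{lesion_id}, \code{t}, \code{v}), \code{series} (named
#'   list of \code{\link{lesion_series}}), \code{source} (path).
#' @export
read_measurements <- function(path, sep = NULL, epoch = NULL,
                              strict = TRUE, patient_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE,
                           strip.white = TRUE, fileEncoding = "UTF-8")
  need <- c("lesion_id", "time", "volume_cm3")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))

  tcol <- raw$time
  if (is.character(tcol)) {
    as_num <- suppressWarnings(as.numeric(tcol))
    if (all(is.finite(as_num))) {
      t_days <- as_num
    } else {
      dates <- as.Date(tcol, format = "%Y-%m-%d")
      bad <- which(is.na(dates))
      if (length(bad))
        stop(sprintf("unparseable time value(s) at data row(s): %s",
                     paste(utils::head(bad, 5L), collapse = ", ")))
      if (is.null(epoch)) epoch <- min(dates)
      epoch <- as.Date(epoch)
      t_days <- as.numeric(dates - epoch)
    }
  } else t_days <- as.numeric(tcol)
  if (!is.null(epoch)) epoch <- as.Date(epoch)

  v <- as.numeric(raw$volume_cm3)
  bad_v <- which(!is.finite(v) | v <= 0)
  if (length(bad_v)) {
    if (strict)
      stop(sprintf("non-positive/invalid volume at data row(s): %s",
                   paste(utils::head(bad_v, 5L), collapse = ", ")))
    message(sprintf("dropping %d row(s) with non-positive volume",
                    length(bad_v)))
    raw <- raw[-bad_v, , drop = FALSE]
    t_days <- t_days[-bad_v]; v <- v[-bad_v]
  }
  m <- data.frame(lesion_id = as.character(raw$lesion_id), t = t_days,
                  v = v, stringsAsFactors = FALSE)
  dup <- duplicated(m[, c("lesion_id", "t")])
  if (any(dup))
    stop(sprintf("duplicate (lesion, time) pair(s) at data row(s): %s",
                 paste(utils::head(which(dup), 5L), collapse = ", ")))
  m <- m[order(m$lesion_id, m$t), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(patient_id = patient_id %||% basename(path),
                 epoch = if (is.null(epoch)) as.Date(NA) else epoch,
                 measurements = m, series = split_series(m),
                 source = path),
            class = "patient_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a measurement table in the package's input dialect
#'
#' @param measurements Data frame with columns \code{lesion_id}, \code{t},
#'   \code{v} (e.g. from \code{\link{simulate_patient}}).
#' @param path Output path; extension selects comma vs tab.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- data.frame(lesion_id = measurements$lesion_id,
                    time = measurements$t,
                    volume_cm3 = measurements$v)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' @param v0_assumed Reference volume for the pooled regression, cm^3
#'   (default one cell, 1e-9).
#' @param one_cell One-cell volume used for formation-time extrapolation.
#' @param alpha Significance level of the slope test (model selection).
#' @param indifference_margin Delta r-squared below which the direct-fit
#'   model comparison declares no winner.
#' @return List of class \code{"analysis_config"}.
#' @export
analysis_config <- function(v0_assumed = 1e-9, one_cell = 1e-9,
                            alpha = 0.05, indifference_margin = 0.02) {
  stopifnot(v0_assumed > 0, one_cell > 0, alpha > 0, alpha < 1,
            indifference_margin >= 0)
  structure(list(v0_assumed = v0_assumed, one_cell = one_cell,
                 alpha = alpha,
                 indifference_margin = indifference_margin),
            class = "analysis_config")
}

#' Run the full per-patient estimation pipeline
#'
#' Executes the stages in order: (1-2) interval SGR records with log
#' geometric-mean volumes for every lesion; (3) pooled SGR-vs-log-volume
#' regression and model selection; (4) construction of the general growth
#' curve from the fitted parameters, anchored at one cell; (5) per-lesion
#' formation times -- by time-origin shifting of the general curve when a
#' general Gompertz model is selected, by per-lesion exponential
#' back-extrapolation otherwise -- followed by the formation-rate fit.
#' Both direct fits (exponential, and Gompertz where three points exist)
#' are also run per lesion for comparison. Deterministic for a fixed
#' dataset and configuration; stages that cannot run are recorded in
#' \code{skipped} with a reason, never dropped silently.
#'
#' @param dataset A \code{\link{read_measurements}} result, or any list
#'   with \code{measurements} (\code{lesion_id}, \code{t}, \code{v}) such
#'   as a \code{\link{simulate_patient}} output.
#' @param config An \code{\link{analysis_config}}.
#' @return List of class \code{"patient_report"} with elements
#'   \code{patient_id}, \code{config}, \code{intervals},
#'   \code{linearized}, \code{general}, \code{formations} (table +
#'   \code{pathway}), \code{rate}, \code{direct_fits},
#'   \code{comparisons}, \code{heterogeneous}, \code{skipped},
#'   \code{provenance}.
#' @export
analyze_patient <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  meas <- dataset$measurements
  stopifnot(is.data.frame(meas), nrow(meas) >= 1L)
  series <- split_series(meas)
  skipped <- list()

  intervals <- patient_intervals(series)

  linearized <- NULL; general <- NULL
  if (nrow(intervals) >= 3L) {
    linearized <- withCallingHandlers(
      fit_sgr_logv(intervals, v0_assumed = config$v0_assumed,
                   alpha = config$alpha),
      warning = function(w) invokeRestart("muffleWarning"))
  } else {
    skipped$linearized <- sprintf(
      "pooled regression needs >= 3 interval records, found %d",
      nrow(intervals))
  }

  formations <- NULL; pathway <- NULL
  if (!is.null(linearized)) {
    if (linearized$selected_model == "general_gompertz") {
      pathway <- "general_gompertz"
      general <- general_curve(linearized)
      formations <- tryCatch(estimate_all_formations(series, general),
                             error = function(e) {
        skipped$formations <<- conditionMessage(e); NULL })
    } else {
      pathway <- "heterogeneous_exponential"
      formations <- exponential_formations(series,
                                           one_cell = config$one_cell)
    }
  } else skipped$formations <- "no growth model (linearized stage skipped)"

  rate <- NULL
  if (!is.null(formations) &&
      sum(is.finite(formations$formation_t)) >= 2L &&
      diff(range(formations$formation_t[is.finite(formations$formation_t)])) > 0) {
    rate <- suppressMessages(fit_formation_rate(formations))
  } else skipped$rate <- "fewer than 2 distinct finite formation times"

  direct <- list(); comparisons <- list()
  for (s in series) {
    id <- s$lesion_id[1L]
    ef <- if (nrow(s) >= 2L) fit_exponential(s, one_cell = config$one_cell)
          else NULL
    gf <- if (nrow(s) >= 3L)
      withCallingHandlers(fit_gompertz(s, one_cell = config$one_cell),
                          warning = function(w) invokeRestart("muffleWarning"))
    else NULL
    if (is.null(ef))
      skipped[[paste0("direct_", id)]] <- "exponential fit needs >= 2 points"
    else if (is.null(gf))
      skipped[[paste0("gompertz_", id)]] <- "Gompertz fit needs >= 3 points"
    direct[[id]] <- list(exponential = ef, gompertz = gf)
    if (!is.null(ef) && !is.null(gf))
      comparisons[[id]] <- compare_models(ef, gf,
                                          margin = config$indifference_margin)
  }

  heterogeneous <- if (nrow(intervals) >= 1L)
    describe_heterogeneous(intervals) else NULL

  src <- dataset$source %||% NA_character_
  structure(list(
    patient_id = dataset$patient_id %||% "patient",
    epoch = dataset$epoch %||% as.Date(NA),
    config = config,
    intervals = intervals,
    linearized = linearized,
    general = general,
    formations = if (!is.null(formations))
      list(pathway = pathway, table = formations) else NULL,
    rate = rate,
    direct_fits = direct,
    comparisons = comparisons,
    heterogeneous = heterogeneous,
    skipped = skipped,
    provenance = list(
      package = "metagrowth",
      version = as.character(utils::packageVersion("metagrowth")),
      schema = 1L,
      input = src,
      input_md5 = if (!is.na(src) && file.exists(src))
        unname(tools::md5sum(src)) else NA_character_,
      n_measurements = nrow(meas),
      n_lesions = length(series),
      config = unclass(config))),
    class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("patient '%s': %d lesions, %d measurements\n", x$patient_id,
              x$provenance$n_lesions, x$provenance$n_measurements))
  if (!is.null(x$linearized)) print(x$linearized)
  if (!is.null(x$rate)) print(x$rate)
  if (length(x$skipped)) {
    cat("skipped stages:\n")
    for (nm in names(x$skipped)) cat(sprintf("  %s: %s\n", nm, x$skipped[[nm]]))
  }
  invisible(x)
}

#' Serialise a patient report
#'
#' JSON is loss-less and schema-versioned; the TSV summary mirrors a
#' per-lesion results table: one row per (lesion, model) with the number
#' of points, SGR0 as %/day, lambda, formation day (and calendar year
#' when the dataset carried an epoch date) and r-squared, plus a patient
#' footer row with the pooled-regression parameters and formation rate.
#'
#' @param report A \code{\link{analyze_patient}} result.
#' @param path Output path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  stopifnot(inherits(report, "patient_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE)
    return(invisible(path))
  }
  rows <- list()
  year_of <- function(day) {
    if (is.null(report$epoch) || is.na(report$epoch) || !is.finite(day))
      return(NA_character_)
    format(report$epoch + round(day), "%Y")
  }
  for (id in names(report$direct_fits)) {
    for (model in c("exponential", "gompertz")) {
      f <- report$direct_fits[[id]][[model]]
      if (is.null(f)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lesion = id, n = f$n_points, model = model,
        sgr0_pct_per_day = sprintf("%.2f", 100 * f$sgr0),
        lambda_per_day = sprintf("%.5f", f$params$lam),
        formation_day = sprintf("%.1f", f$formation_time),
        formation_year = year_of(f$formation_time),
        r2 = sprintf("%.3f", f$r2), stringsAsFactors = FALSE)
    }
  }
  lin <- report$linearized
  rows[[length(rows) + 1L]] <- data.frame(
    lesion = "PATIENT",
    n = if (is.null(lin)) NA_integer_ else lin$n_points,
    model = if (is.null(lin)) "none" else lin$selected_model,
    sgr0_pct_per_day = if (is.null(lin)) "" else sprintf("%.2f", 100 * lin$sgr0),
    lambda_per_day = if (is.null(lin)) "" else sprintf("%.5f", lin$lam),
    formation_day = if (is.null(report$rate)) ""
                    else sprintf("%.1f", report$rate$t_first),
    formation_year = if (is.null(report$rate)) NA_character_
                     else year_of(report$rate$t_first),
    r2 = if (is.null(report$rate)) ""
         else sprintf("k=%.3g/yr r2=%.3f", report$rate$k, report$rate$r2),
    stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# plain nested list for loss-less JSON serialisation
report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "growth_params") || inherits(x, "linearized_fit") ||
        inherits(x, "rate_fit") || inherits(x, "direct_fit") ||
        inherits(x, "analysis_config"))
      return(lapply(unclass(x), strip))
    if (inherits(x, "data.frame")) return(as.data.frame(unclass(x)))
    if (inherits(x, "Date")) return(format(x))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- strip(unclass(report))
  out$intervals <- as.data.frame(report$intervals)
  class(out$intervals) <- "data.frame"
  out
}

#' Read back a JSON patient report
#'
#' @param path Path written by \code{\link{write_report}}.
#' @return Nested list mirroring the report structure.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
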