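# Derived measures: entry-rate series, extraction ratios, percent-of-dose
# curves, cumulative removal, moving averages, peak/plateau statistics and
# band ratios.

# centered moving average with edges truncated to the available span
centered_ma <- function(x, window) {
  n <- length(x)
  if (window > n) stop("window larger than series", call. = FALSE)
  if (window %% 2 == 0) stop("window must be odd for centered smoothing",
                             call. = FALSE)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# maximum of the rolling mean over full windows
rolling_peak <- function(x, window) {
  n <- length(x)
  if (n <= window) return(mean(x))
  cs <- cumsum(c(0, x))
  max((cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window)
}

#' Smooth a series or summarize it to a scalar
#'
#' `mode = "smooth"` returns the centered moving average (default span 181
#' TS, edges truncated to the available span); `mode = "peak"` the maximum
#' of the rolling 1,000-TS mean; `mode = "plateau"` the mean of the final
#' `tail_frac` of the smoothed series.
#'
#' @param x Numeric series (one value per TS).
#' @param mode `"smooth"`, `"peak"`, or `"plateau"`.
#' @param window Smoothing span (odd; `"smooth"`/`"plateau"`) or averaging
#'   window (`"peak"`).
#' @param tail_frac Final fraction of the series averaged for the plateau.
#' @return Numeric vector (`"smooth"`) or scalar.
#' @export
smooth_and_summarize <- function(x, mode = c("smooth", "peak", "plateau"),
                                 window = NULL, tail_frac = 0.25) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  switch(mode,
    smooth = centered_ma(x, window %||% 181L),
    peak = rolling_peak(x, window %||% 1000L),
    plateau = {
      sm <- centered_ma(x, min(window %||% 181L,
                               2L * (length(x) %/% 2L) - 1L))
      n <- length(sm)
      mean(sm[max(1L, n - floor(tail_frac * n) + 1L):n], na.rm = TRUE)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold ratio
#'
#' @param a,b Scalars; returns `a / b`, or `NA` when `b` is zero
#'   (undefined).
#' @return Scalar.
#' @export
fold_ratio <- function(a, b) {
  if (!length(b) || !is.finite(b) || b == 0) return(NA_real_)
  a / b
}

band_size <- function(record, scope) {
  switch(scope,
         all = record$n_vhpc,
         PP = record$band_sizes[["PP"]],
         CL = record$band_sizes[["CL"]],
         PC = record$band_sizes[["PC"]],
         stop("unknown band scope: ", scope, call. = FALSE))
}

# entries per vHPC per TS within a band
entry_rate_series <- function(record, scope = "all") {
  col <- switch(scope, all = "entries_all", PP = "entries_pp",
                CL = "entries_cl", PC = "entries_pc",
                stop("unknown band scope: ", scope, call. = FALSE))
  record$series[, col] / band_size(record, scope)
}

#' Extract a derived time series
#'
#' Turns the raw per-TS count series of an execution (or the per-execution
#' average over an experiment) into the study's measures:
#'
#' * `entry_rate`: hepatocyte entry events per vHPC per TS within a band
#'   scope (`"all"`, `"PP"`, `"CL"`, `"PC"`).
#' * `percent_dose`: percent of the test-compound dose in a compartment
#'   scope (`"intro"`, `"body"` -- Media in culture --, `"extracellular"`,
#'   `"cells"`, or `"marker_body"` for the internal standard).
#' * `percent_dose_per_vhpc`: percent of dose held inside vHPCs per vHPC
#'   within a band scope.
#' * `extraction_ratio`: per-TS (inflow - outflow) / inflow on the
#'   181-TS-smoothed inflow and outflow (portal-vein in / central-vein out
#'   for vHuman; Media-Cell Interface in/out for vCulture). TSs with zero
#'   smoothed inflow are `NA`. `er_denominator = "cv"` instead divides by
#'   the outflow, reproducing the perfused-liver form
#'   (PV - CV) / CV, which is unbounded above.
#' * `cumulative_removal`: percent of dose irreversibly removed
#'   (metabolized; for a compound with `p_exit = 0`, retained in cells).
#' * `metabolite_percent`: metabolite amount as percent of dose
#'   (`"total"` or `"body"`).
#'
#' @param x An [execution_record] or [experiment_result].
#' @param metric One of the metrics above.
#' @param scope Band or compartment scope; see the metric list.
#' @param smooth_window Smoothing span used by `extraction_ratio`.
#' @param er_denominator `"in"` (default) or `"cv"`.
#' @return For a record, a numeric vector (one value per TS); for an
#'   experiment, a data frame with `ts`, `mean`, `sd` across executions.
#' @export
series_extract <- function(x,
                           metric = c("entry_rate", "percent_dose",
                                      "percent_dose_per_vhpc",
                                      "extraction_ratio",
                                      "cumulative_removal",
                                      "metabolite_percent"),
                           scope = "all",
                           smooth_window = 181L,
                           er_denominator = c("in", "cv")) {
  metric <- match.arg(metric)
  er_denominator <- match.arg(er_denominator)
  if (inherits(x, "experiment_result")) {
    per_exec <- vapply(x$records, function(r) {
      series_extract(r, metric, scope, smooth_window, er_denominator)
    }, numeric(x$cfg$n_ts))
    return(data.frame(ts = seq_len(nrow(per_exec)),
                      mean = rowMeans(per_exec),
                      sd = apply(per_exec, 1L, sd)))
  }
  stopifnot(inherits(x, "execution_record"))
  s <- x$series
  dose <- x$dose_test
  switch(metric,
    entry_rate = entry_rate_series(x, scope),
    percent_dose = {
      col <- switch(scope,
                    intro = s[, "intro_t"], body = s[, "body_t"],
                    media = s[, "body_t"], extracellular = s[, "extra_t"],
                    cells = s[, "cell_all"], marker_body = s[, "body_m"],
                    stop("unknown compartment scope: ", scope, call. = FALSE))
      100 * col / (if (scope == "marker_body") x$dose_marker else dose)
    },
    percent_dose_per_vhpc = {
      col <- switch(scope, all = "cell_all", PP = "cell_pp", CL = "cell_cl",
                    PC = "cell_pc", stop("unknown band scope: ", scope,
                                         call. = FALSE))
      100 * s[, col] / dose / band_size(x, scope)
    },
    extraction_ratio = {
      infl <- centered_ma(s[, "inflow_t"], smooth_window)
      outf <- centered_ma(s[, "outflow_t"], smooth_window)
      er <- if (er_denominator == "in") (infl - outf) / infl
            else (infl - outf) / outf
      er[infl <= 0] <- NA_real_
      er
    },
    cumulative_removal = {
      if (x$compound$p_exit == 0) 100 * s[, "cell_all"] / dose
      else 100 * s[, "cum_metab"] / dose
    },
    metabolite_percent = {
      col <- switch(scope, total = "met_total", body = "met_body",
                    media = "met_body",
                    stop("unknown metabolite scope: ", scope, call. = FALSE))
      100 * s[, col] / dose
    })
}

#' Per-band summary statistics
#'
#' Peak and plateau entry rates per vHPC and (optionally) the percent of
#' dose held per vHPC at a given TS, for each band of a vHuman experiment
#' (or the single pooled scope of a vCulture experiment).
#'
#' @param x An [experiment_result].
#' @param at_ts TS at which to report percent of dose per vHPC, or `NULL`.
#' @return Data frame, one row per band.
#' @export
band_summary <- function(x, at_ts = NULL) {
  stopifnot(inherits(x, "experiment_result"))
  scopes <- if (x$cfg$system == "vhuman") c("PP", "CL", "PC", "all") else "all"
  rows <- lapply(scopes, function(sc) {
    per_exec <- function(mode) {
      mean(vapply(x$records, function(r) {
        smooth_and_summarize(entry_rate_series(r, sc), mode = mode)
      }, numeric(1)))
    }
    pct <- if (is.null(at_ts)) NA_real_ else {
      mean(vapply(x$records, function(r) {
        series_extract(r, "percent_dose_per_vhpc", sc)[at_ts]
      }, numeric(1)))
    }
    data.frame(band = sc,
               n_vhpc = mean(vapply(x$records, band_size, numeric(1), sc)),
               peak_entry_rate = per_exec("peak"),
               plateau_entry_rate = per_exec("plateau"),
               percent_dose_per_vhpc = pct)
  })
  do.call(rbind, rows)
}

#' Write experiment time series and summary to disk
#'
#' One CSV per metric (`ts`, `mean`, `sd`, plus per-band columns where the
#' metric is band-resolved) and a JSON summary of scalar statistics.
#'
#' @param x An [experiment_result].
#' @param path Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "experiment_result"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  human <- x$cfg$system == "vhuman"
  files <- character(0)
  emit <- function(df, name) {
    f <- file.path(path, paste0(name, ".csv"))
    write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  er <- series_extract(x, "entry_rate", "all")
  if (human) {
    for (sc in c("PP", "CL", "PC")) {
      b <- series_extract(x, "entry_rate", sc)
      er[[paste0("mean_", sc)]] <- b$mean
    }
  }
  emit(er, "entry_rate")
  emit(series_extract(x, "percent_dose", "body"), "percent_dose_body")
  emit(series_extract(x, "percent_dose", "cells"), "percent_dose_cells")
  emit(series_extract(x, "extraction_ratio"), "extraction_ratio")
  emit(series_extract(x, "cumulative_removal"), "cumulative_removal")
  if (x$cfg$compound$p_bind > 0) {
    emit(series_extract(x, "metabolite_percent", "total"),
         "metabolite_percent")
  }
  summary <- list(
    system = x$cfg$system,
    compound = x$cfg$compound$name,
    fraction_unbound = x$cfg$compound$fraction_unbound,
    n_mc = x$cfg$n_mc, n_ts = x$cfg$n_ts,
    dose_total = x$cfg$dose_total,
    mean_n_vhpc = mean(x$n_vhpc),
    band_summary = band_summary(x))
  jf <- file.path(path, "summary.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(files, jf))
}

#' Read back a written time-series CSV
#'
#' @param path Directory written by [write_timeseries()].
#' @param name Metric file name without extension.
#' @return Data frame.
#' @export
read_timeseries <- function(path, name = "entry_rate") {
  read.csv(file.path(path, paste0(name, ".csv")))
}
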