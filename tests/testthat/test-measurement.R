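# minimal hand-built execution record for closed-form checks
fake_record <- function(n_ts = 600L, inflow = 200, outflow = 150,
                        body = 50, dose = 100L) {
  s <- matrix(0, n_ts, 23,
              dimnames = list(NULL, c(
                "intro_t", "body_t", "extra_t", "cell_all", "cell_pp",
                "cell_cl", "cell_pc", "met_total", "met_body", "cum_metab",
                "entries_all", "entries_pp", "entries_cl", "entries_pc",
                "inflow_t", "outflow_t", "intro_m", "body_m", "extra_m",
                "inflow_m", "outflow_m", "cum_entries", "bound_t")))
  s[, "inflow_t"] <- inflow
  s[, "outflow_t"] <- outflow
  s[, "body_t"] <- body
  s[, "entries_all"] <- 10
  structure(list(seed = 1L, system = "vculture",
                 compound = preset_spec("vC1", 1), n_ts = n_ts,
                 n_vhpc = 100L, band_sizes = c(PP = 0L, CL = 0L, PC = 0L),
                 dose_test = dose, dose_marker = dose, series = s,
                 counters = setNames(numeric(8), c(
                   "att_entry", "n_entry", "att_exit", "n_exit", "att_bind",
                   "n_bind", "n_release", "n_metab")),
                 vhpc_entries = integer(100L)),
            class = "execution_record")
}

test_that("smoothing and summaries have their closed-form values", {
  const <- rep(3.5, 500)
  expect_equal(smooth_and_summarize(const, "smooth"), const)
  expect_equal(smooth_and_summarize(const, "peak"), 3.5)
  expect_equal(smooth_and_summarize(const, "plateau"), 3.5)

  # impulse: centered moving average preserves mass away from the edges
  imp <- c(rep(0, 400), 1, rep(0, 400))
  expect_equal(sum(smooth_and_summarize(imp, "smooth")), 1)

  # plateau of a linear ramp equals the mean of the smoothed tail
  ramp <- seq_len(1000)
  pl <- smooth_and_summarize(ramp, "plateau", tail_frac = 0.25)
  expect_equal(pl, mean(smooth_and_summarize(ramp, "smooth")[751:1000]))

  expect_error(smooth_and_summarize(1:10, "smooth", window = 4), "odd")
  expect_error(smooth_and_summarize(1:10, "smooth", window = 181), "window")
})

test_that("fold ratios divide and mark the undefined case", {
  expect_equal(fold_ratio(2, 1), 2)
  expect_equal(fold_ratio(7.3, 7.3), 1)
  expect_true(is.na(fold_ratio(1, 0)))
})

test_that("extraction ratio follows (in - out) / in, with the CV variant", {
  r <- fake_record(inflow = 200, outflow = 150)
  er <- series_extract(r, "extraction_ratio")
  expect_equal(unique(round(er, 12)), 0.25)
  er_cv <- series_extract(r, "extraction_ratio", er_denominator = "cv")
  expect_equal(unique(round(er_cv, 12)), round(50 / 150, 12))
  # zero inflow is undefined
  r0 <- fake_record(inflow = 0)
  expect_true(all(is.na(series_extract(r0, "extraction_ratio"))))
})

test_that("percent-of-dose and entry-rate scales are correct", {
  r <- fake_record(body = 50, dose = 100L)
  expect_equal(unique(series_extract(r, "percent_dose", "body")), 50)
  expect_equal(unique(series_extract(r, "entry_rate", "all")), 10 / 100)
})

test_that("written time series round-trip and stochastic SDs are nonzero", {
  res <- run_experiment(quick_cfg("vculture", "vC2", 0.5, dose = 1000L,
                                  n_ts = 400L, n_mc = 2L))
  dir <- tempfile("ts")
  files <- write_timeseries(res, dir)
  expect_true(all(file.exists(files)))
  back <- read_timeseries(dir, "entry_rate")
  fwd <- series_extract(res, "entry_rate", "all")
  expect_equal(back$mean, fwd$mean)
  expect_equal(back$sd, fwd$sd)
  expect_gt(max(back$sd), 0)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$n_mc, 2L)
})
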