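test_that("experiments average their executions and echo the configuration", {
  cfg <- quick_cfg("vculture", "vC1", 0.5, dose = 800L, n_ts = 300L, n_mc = 2L)
  res <- run_experiment(cfg)
  expect_length(res$records, 2L)
  expect_equal(res$series_mean,
               (res$records[[1]]$series + res$records[[2]]$series) / 2,
               ignore_attr = TRUE)
  one <- run_experiment(quick_cfg("vculture", "vC1", 0.5, dose = 800L,
                                  n_ts = 300L, n_mc = 1L))
  expect_equal(one$series_mean, one$records[[1]]$series, ignore_attr = TRUE)
  expect_true(all(one$series_sd == 0))
})

test_that("Marker behaves as an internal standard across test compounds", {
  base <- list(dose = 4000L, n_ts = 800L, n_mc = 2L, seed = 7L)
  res1 <- run_experiment(quick_cfg("vculture", "vC1", 1.0, dose = base$dose,
                                   n_ts = base$n_ts, n_mc = base$n_mc,
                                   seed = base$seed))
  res2 <- run_experiment(quick_cfg("vculture", "vC2", 0.1, dose = base$dose,
                                   n_ts = base$n_ts, n_mc = base$n_mc,
                                   seed = base$seed))
  m1 <- mean(res1$series_mean[600:800, "body_m"])
  m2 <- mean(res2$series_mean[600:800, "body_m"])
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("halving the dose leaves percent-of-dose series unchanged within noise", {
  r_full <- run_experiment(quick_cfg("vculture", "vC1", 1.0, dose = 4000L,
                                     n_ts = 600L, n_mc = 2L, seed = 11L))
  r_half <- run_experiment(quick_cfg("vculture", "vC1", 1.0, dose = 2000L,
                                     n_ts = 600L, n_mc = 2L, seed = 31L))
  p_full <- series_extract(r_full, "percent_dose", "cells")$mean[400:600]
  p_half <- series_extract(r_half, "percent_dose", "cells")$mean[400:600]
  expect_lt(abs(mean(p_full) - mean(p_half)) / mean(p_full), 0.1)
})

test_that("cross-system comparison refuses mismatched configurations", {
  cu <- run_experiment(quick_cfg("vculture", "vC1", 1.0, dose = 500L,
                                 n_ts = 200L))
  hu <- run_experiment(quick_cfg("vhuman", "vC1", 0.5, dose = 500L,
                                 n_ts = 200L))
  expect_error(cross_system_compare(cu, hu), "not matched")
  expect_error(cross_system_compare(cu, cu), "vculture and a vhuman")
})

test_that("configuration files load, validate, and round-trip", {
  cfg <- quick_cfg("vhuman", "vC3", 0.2, dose = 1234L, n_ts = 111L, n_mc = 2L)
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- load_config(f)
  expect_equal(back$system, "vhuman")
  expect_equal(back$compound$name, "vC3")
  expect_equal(back$compound$fraction_unbound, 0.2)
  expect_equal(back$dose_total, 1234L)
  expect_equal(back$n_ts, 111L)
  expect_equal(back$flow, cfg$flow)
  expect_equal(back$structure, cfg$structure)

  writeLines("system: vculture\nnonsense_key: 1", f)
  expect_error(load_config(f), "nonsense_key")
  writeLines("system: vculture\nfraction_unbound: 1.5", f)
  expect_error(load_config(f), "fraction_unbound")

  # minimal file fills documented defaults
  writeLines("system: vculture\ncompound: vC1\nfraction_unbound: 1.0", f)
  mini <- load_config(f)
  expect_equal(mini$dose_total, 100000L)
  expect_equal(mini$n_ts, 21600L)
  expect_equal(mini$n_mc, 12L)

  # shipped recipe reproduces the vC2 low-unbound-fraction condition
  recipe <- system.file("recipes", "fig7_vc2_fu005.yaml", package = "hepasim")
  rc <- load_config(recipe)
  expect_equal(rc$system, "vhuman")
  expect_equal(rc$compound$name, "vC2")
  expect_equal(rc$compound$fraction_unbound, 0.05)
  expect_equal(rc$n_mc, 12L)
  expect_equal(rc$n_ts, 21600L)
})

test_that("the command-line interface simulates, validates, and reports usage", {
  expect_equal(cli_main(character(0)), 1L)
  expect_equal(cli_main(c("validate-graph", "--seed", "2")), 0L)
  out <- tempfile("cli")
  cfgf <- tempfile(fileext = ".yaml")
  write_config(quick_cfg("vculture", "vC1", 1.0, dose = 400L, n_ts = 200L),
               cfgf)
  expect_equal(cli_main(c("simulate", "--config", cfgf, "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "entry_rate.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(length(man$seeds), 1L)
})
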