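test_that("binomial compartment transfer is exact at the extremes", {
  set.seed(101)
  expect_equal(transfer_fraction(500L, 0), 0L)
  expect_equal(transfer_fraction(500L, 1), 500L)
  moved <- transfer_fraction(10000L, 0.1)
  expect_lt(abs(moved - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
})

test_that("an empty system only advances the clock", {
  cfg <- quick_cfg(dose = 0L, n_ts = 5L)
  r <- run_execution(cfg, 1)
  expect_equal(unname(r$counters["n_entry"]), 0)
  expect_true(all(r$series == 0))
})

test_that("with zero biases grid compounds never move", {
  set.seed(102)
  st <- build_culture_structure()
  state <- init_system_state(st, 200L, standard_fraction = 0,
                             dosing_mode = "bolus")
  fl <- flow_params(f_media_to_interface = 1, forward_bias = 0,
                    lateral_bias = 0)
  # one TS distributes everything to the Interface
  a <- advance_one_ts(state, st, preset_spec("Marker"), fl)
  expect_true(all(a$state$loc == 5L))
  b <- advance_one_ts(a$state, st, preset_spec("Marker"), fl, n_ts = 20L)
  expect_identical(b$state$ss, a$state$ss)
  expect_identical(b$state$w, a$state$w)
  expect_identical(b$state$l, a$state$l)
  expect_true(all(b$state$loc == 5L))
})

test_that("Marker registers zero entry events and is conserved", {
  cfg <- quick_cfg("vhuman", dose = 1000L, n_ts = 400L,
                   compound = "Marker", check = TRUE)
  cfg$standard_fraction <- 1
  r <- run_execution(cfg, 3)
  expect_equal(unname(r$counters["n_entry"]), 0)
  expect_true(all(r$series[, "entries_all"] == 0))
})

test_that("non-removed compounds are conserved at every TS", {
  cfg <- quick_cfg("vhuman", "vC1", 1, dose = 2000L, n_ts = 600L,
                   check = TRUE)
  r <- run_execution(cfg, 4)   # check = TRUE asserts inside the engine
  tot <- rowSums(r$series[, c("intro_t", "body_t", "extra_t", "cell_all")])
  expect_true(all(tot == r$dose_test))
  totm <- rowSums(r$series[, c("intro_m", "body_m", "extra_m")])
  expect_true(all(totm == r$dose_marker))
})

test_that("for vC2 every entry is a removal: held amount equals cumulative entries", {
  cfg <- quick_cfg("vculture", "vC2", 0.5, dose = 2000L, n_ts = 800L,
                   check = TRUE)
  r <- run_execution(cfg, 5)
  expect_equal(r$series[, "cell_all"], r$series[, "cum_entries"],
               ignore_attr = TRUE)
  expect_gt(r$series[800, "cum_entries"], 0)
})

test_that("parent plus metabolite count is conserved under metabolism", {
  cfg <- quick_cfg("vculture", "vC4", 1, dose = 4000L, n_ts = 1500L,
                   check = TRUE)
  r <- run_execution(cfg, 6)
  expect_gt(unname(r$counters["n_metab"]), 0)
  parent <- rowSums(r$series[, c("intro_t", "body_t", "extra_t", "cell_all")])
  expect_true(all(parent + r$series[, "met_total"] == r$dose_test))
  # metabolite eventually reaches the Media compartment
  expect_gt(r$series[1500, "met_body"], 0)
})

test_that("entry, exit, binding and metabolism frequencies match their parameters", {
  spec <- compound_spec("probe", fraction_unbound = 0.3, p_exit = 0.5,
                        p_bind = 0.1, p_metabolize = 0.1)
  cfg <- quick_cfg("vculture", spec, dose = 5000L, n_ts = 2000L, check = TRUE)
  r <- run_execution(cfg, 7)
  cnt <- r$counters
  expect_gt(cnt[["att_entry"]], 1e4)
  expect_binomial(cnt[["n_entry"]], cnt[["att_entry"]], 0.3, "entry")
  expect_binomial(cnt[["n_exit"]], cnt[["att_exit"]], 0.5, "exit")
  expect_binomial(cnt[["n_bind"]], cnt[["att_bind"]], 0.1, "binding")
  expect_binomial(cnt[["n_metab"]], cnt[["n_release"]], 0.1, "metabolism")
})

test_that("portal distribution spreads compounds evenly over layer-0 SSs", {
  set.seed(103)
  st <- build_lobule_structure()
  state <- init_system_state(st, 4500L, standard_fraction = 0,
                             dosing_mode = "bolus")
  fl <- flow_params(f_body_to_pv = 1)
  a <- advance_one_ts(state, st, preset_spec("vC1", 1), fl)
  s <- a$state
  expect_true(all(s$loc %in% c(4L, 5L)))             # Core or Interface
  layer0 <- which(st$ss_layer == 0L) - 1L
  expect_true(all(s$ss %in% layer0))
  counts <- tabulate(s$ss + 1L, length(st$ss_len))[layer0 + 1L]
  expect_lt(max(abs(counts - 100)), 3 * sqrt(4500 * (1 / 45) * (44 / 45)) + 1)
  expect_binomial(sum(s$loc == 4L), length(s$loc), 0.5, "core split")
})

test_that("executions are deterministic given (cfg, seed)", {
  cfg <- quick_cfg("vhuman", "vC3", 0.5, dose = 1000L, n_ts = 300L)
  a <- run_execution(cfg, 9)
  b <- run_execution(cfg, 9)
  expect_identical(a$series, b$series)
  expect_identical(a$counters, b$counters)
  c_ <- run_execution(cfg, 10)
  expect_false(identical(a$series, c_$series))
})

test_that("MC means are insensitive to agent insertion order", {
  # reversing agent order (test compound first instead of Marker first)
  # must leave MC-mean outputs unchanged within MC noise
  set.seed(104)
  st <- build_culture_structure()
  run_order <- function(rev_order, seed) {
    set.seed(seed)
    state <- init_system_state(st, 2000L)
    if (rev_order) {
      o <- rev(seq_along(state$typ))
      for (f in c("typ", "loc")) state[[f]] <- state[[f]][o]
    }
    res <- advance_one_ts(state, st, preset_spec("vC1", 1),
                          n_ts = 600L, record = TRUE)
    mean(res$series[400:600, "entries_all"])
  }
  fwd <- vapply(1:4, function(s) run_order(FALSE, s), numeric(1))
  bwd <- vapply(1:4, function(s) run_order(TRUE, 10 + s), numeric(1))
  expect_lt(abs(mean(fwd) - mean(bwd)),
            3 * sqrt(var(fwd) / 4 + var(bwd) / 4) + 0.05 * mean(fwd))
})
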