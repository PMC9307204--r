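# Complete executions and Monte Carlo experiments.

#' Experiment configuration
#'
#' Bundles everything one experiment needs: the system, the test compound
#' and its unbound fraction, the dosing protocol, run length, Monte Carlo
#' replication, and the structural/flow/band parameter blocks. Defaults are
#' the full-scale study conditions (Dose 100,000 with Marker always 50%,
#' 21,600 TS, 12 MC executions); reduced-scale runs set `dose_total`,
#' `n_ts`, and `n_mc` directly.
#'
#' @param system `"vculture"` or `"vhuman"`.
#' @param compound Preset name (see [preset_spec()]) or a [compound_spec()].
#' @param fraction_unbound Extracellular unbound fraction (sets the entry
#'   probability); ignored when `compound` is already a spec.
#' @param dose_total Total dosed objects (test compound plus Marker).
#' @param standard_fraction Marker share of the dose.
#' @param n_ts Execution length in time-steps.
#' @param n_mc Number of Monte Carlo executions per experiment.
#' @param base_seed Seeds are `base_seed + 1 .. base_seed + n_mc`.
#' @param dosing_mode `"first_order"` (via Intro space) or `"bolus"` (all in
#'   Body/Media at TS 0).
#' @param flow A [flow_params()].
#' @param structure A [structure_config()].
#' @param bands A [band_spec()].
#' @param check Assert conservation invariants every TS (slower).
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(system = c("vculture", "vhuman"),
                              compound = "vC1",
                              fraction_unbound = 1,
                              dose_total = 100000L,
                              standard_fraction = 0.5,
                              n_ts = 21600L,
                              n_mc = 12L,
                              base_seed = 1L,
                              dosing_mode = c("first_order", "bolus"),
                              flow = flow_params(),
                              structure = structure_config(),
                              bands = band_spec(),
                              check = FALSE) {
  system <- match.arg(system)
  dosing_mode <- match.arg(dosing_mode)
  if (is.character(compound)) {
    compound <- preset_spec(compound, fraction_unbound)
  }
  stopifnot(inherits(compound, "compound_spec"),
            inherits(flow, "flow_params"),
            inherits(structure, "structure_config"),
            inherits(bands, "band_spec"),
            dose_total >= 0, n_mc >= 1, n_ts >= 1,
            standard_fraction >= 0, standard_fraction <= 1)
  structure(list(system = system, compound = compound,
                 dose_total = as.integer(dose_total),
                 standard_fraction = standard_fraction,
                 n_ts = as.integer(n_ts), n_mc = as.integer(n_mc),
                 base_seed = as.integer(base_seed),
                 dosing_mode = dosing_mode, flow = flow,
                 structure = structure, bands = bands,
                 check = isTRUE(check)),
            class = "experiment_config")
}

#' Run one seeded execution
#'
#' Builds a fresh Monte Carlo-sampled system (structure, graph, enzyme
#' counts), places the dose, and advances `n_ts` time-steps. The whole run
#' is determined by `(cfg, seed)`: structure sampling and dynamics share one
#' seeded RNG stream in a fixed draw order.
#'
#' @param cfg An [experiment_config()].
#' @param seed Integer seed for this execution.
#' @return List of class `execution_record`: `seed`, `n_vhpc`,
#'   `band_sizes`, the per-TS `series` matrix (counts; see
#'   [series_extract()] for derived measures), engine `counters`,
#'   per-vHPC cumulative `vhpc_entries`, and dose bookkeeping.
#' @export
run_execution <- function(cfg, seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(as.integer(seed))
  structure_obj <- if (cfg$system == "vhuman") {
    build_lobule_structure(cfg$structure, cfg$bands)
  } else {
    build_culture_structure(cfg$structure)
  }
  state <- init_system_state(structure_obj, cfg$dose_total,
                             cfg$standard_fraction, cfg$dosing_mode)
  res <- advance_one_ts(state, structure_obj, cfg$compound, cfg$flow,
                        n_ts = cfg$n_ts, record = TRUE, check = cfg$check)
  n_marker <- sum(state$typ == 0L)
  structure(list(seed = as.integer(seed),
                 system = cfg$system,
                 compound = cfg$compound,
                 n_ts = cfg$n_ts,
                 n_vhpc = structure_obj$n_vhpc,
                 band_sizes = structure_obj$band_sizes,
                 dose_test = length(state$typ) - n_marker,
                 dose_marker = n_marker,
                 series = res$series,
                 counters = res$state$counters,
                 vhpc_entries = res$state$vhpc_entries),
            class = "execution_record")
}

#' Run a Monte Carlo experiment
#'
#' Runs `n_mc` executions with seeds `base_seed + 1 .. base_seed + n_mc`,
#' each with a freshly sampled structure, and stores the element-wise mean
#' and SD of every per-TS series.
#'
#' @param cfg An [experiment_config()].
#' @return List of class `experiment_result`: the config echo, the list of
#'   [execution_record]s, `series_mean` / `series_sd` matrices, and the mean
#'   vHPC count.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  records <- lapply(seq_len(cfg$n_mc), function(i) {
    run_execution(cfg, cfg$base_seed + i)
  })
  arr <- vapply(records, function(r) r$series,
                matrix(0, cfg$n_ts, ncol(records[[1]]$series)))
  m <- apply(arr, c(1, 2), mean)
  s <- if (cfg$n_mc > 1) apply(arr, c(1, 2), sd) else m * 0
  dimnames(m) <- dimnames(s) <- dimnames(records[[1]]$series)
  structure(list(cfg = cfg, records = records,
                 series_mean = m, series_sd = s,
                 n_vhpc = vapply(records, `[[`, numeric(1), "n_vhpc")),
            class = "experiment_result")
}

#' @export
print.execution_record <- function(x, ...) {
  cat(sprintf(
    "<execution_record> %s, %s (fu %.3g), seed %d\n  %d TS, %d vHPCs, %s entries, %s metabolized\n",
    x$system, x$compound$name, x$compound$fraction_unbound, x$seed, x$n_ts,
    x$n_vhpc, format(x$counters[["n_entry"]], big.mark = ","),
    format(x$counters[["n_metab"]], big.mark = ",")))
  invisible(x)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %s, %s (fu %.3g): %d MC executions x %d TS\n  mean vHPC count %.1f\n",
    x$cfg$system, x$cfg$compound$name, x$cfg$compound$fraction_unbound,
    x$cfg$n_mc, x$cfg$n_ts, mean(x$n_vhpc)))
  invisible(x)
}

#' Compare matched culture and human experiments
#'
#' Computes the per-vHPC peak (rolling 1,000-TS mean) and plateau entry
#' rates in each system, the vHuman/vCulture fold prediction ratio
#' (underprediction > 1, overprediction < 1), the vHuman band gradients
#' (CL/PP and PC/PP), and an equivalence verdict: the cross-system
#' validation target is achieved when the mean +/- `margin_sd` * SD
#' intervals of the two systems overlap, or when the relative difference is
#' below `equivalence_rel`.
#'
#' @param culture,human [experiment_result]s from matched configurations
#'   (same compound, unbound fraction, dose, TS count and MC count).
#' @param statistic Entry-rate summary used for the fold ratio.
#' @param margin_sd Width, in per-system MC SDs, of the equivalence margin.
#' @param equivalence_rel Relative-difference floor of the margin. The
#'   culture layout is structurally identical across executions, so its MC
#'   SD can be vanishingly small; a pure SD-overlap test would then reject
#'   rate pairs a few tenths of a percent apart. The floor encodes the
#'   working definition of 1:1 equivalency for mean rates judged across
#'   replicate stochastic executions.
#' @return List of class `cross_system_comparison`.
#' @export
cross_system_compare <- function(culture, human,
                                 statistic = c("plateau", "peak"),
                                 margin_sd = 1, equivalence_rel = 0.05) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(culture, "experiment_result"),
            inherits(human, "experiment_result"))
  if (culture$cfg$system != "vculture" || human$cfg$system != "vhuman") {
    stop("arguments must be a vculture and a vhuman result, in that order",
         call. = FALSE)
  }
  mismatch <- c(
    compound = culture$cfg$compound$name != human$cfg$compound$name,
    fraction_unbound = culture$cfg$compound$fraction_unbound !=
      human$cfg$compound$fraction_unbound,
    dose_total = culture$cfg$dose_total != human$cfg$dose_total,
    n_ts = culture$cfg$n_ts != human$cfg$n_ts,
    n_mc = culture$cfg$n_mc != human$cfg$n_mc)
  if (any(mismatch)) {
    stop("configurations are not matched: ",
         paste(names(mismatch)[mismatch], collapse = ", "), call. = FALSE)
  }
  stat_one <- function(res, mode) {
    vapply(res$records, function(r) {
      smooth_and_summarize(entry_rate_series(r, "all"), mode = mode)
    }, numeric(1))
  }
  summarize <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  out <- list(
    compound = human$cfg$compound$name,
    fraction_unbound = human$cfg$compound$fraction_unbound,
    statistic = statistic,
    culture_peak = summarize(stat_one(culture, "peak")),
    human_peak = summarize(stat_one(human, "peak")),
    culture_plateau = summarize(stat_one(culture, "plateau")),
    human_plateau = summarize(stat_one(human, "plateau")))
  cs <- out[[paste0("culture_", statistic)]]
  hs <- out[[paste0("human_", statistic)]]
  out$fold_human_over_culture <- fold_ratio(hs[["mean"]], cs[["mean"]])
  gap <- abs(hs[["mean"]] - cs[["mean"]])
  out$target_achieved <-
    gap <= margin_sd * (hs[["sd"]] + cs[["sd"]]) ||
    gap <= equivalence_rel * mean(c(hs[["mean"]], cs[["mean"]]))
  grad <- function(mode) {
    pp <- mean(vapply(human$records, function(r) {
      smooth_and_summarize(entry_rate_series(r, "PP"), mode = mode)
    }, numeric(1)))
    cl <- mean(vapply(human$records, function(r) {
      smooth_and_summarize(entry_rate_series(r, "CL"), mode = mode)
    }, numeric(1)))
    pc <- mean(vapply(human$records, function(r) {
      smooth_and_summarize(entry_rate_series(r, "PC"), mode = mode)
    }, numeric(1)))
    c(CL_over_PP = fold_ratio(cl, pp), PC_over_PP = fold_ratio(pc, pp))
  }
  out$human_gradients <- grad(statistic)
  class(out) <- "cross_system_comparison"
  out
}

#' @export
print.cross_system_comparison <- function(x, ...) {
  cat(sprintf("<cross_system_comparison> %s (fu %.3g), %s entry rates\n",
              x$compound, x$fraction_unbound, x$statistic))
  cat(sprintf("  vCulture: %.4g (SD %.2g)   vHuman: %.4g (SD %.2g)\n",
              x[[paste0("culture_", x$statistic)]][["mean"]],
              x[[paste0("culture_", x$statistic)]][["sd"]],
              x[[paste0("human_", x$statistic)]][["mean"]],
              x[[paste0("human_", x$statistic)]][["sd"]]))
  cat(sprintf("  fold (vHuman/vCulture): %.3g   target %s\n",
              x$fold_human_over_culture,
              if (isTRUE(x$target_achieved)) "ACHIEVED" else "NOT achieved"))
  cat(sprintf("  vHuman gradients: CL/PP %.3g, PC/PP %.3g\n",
              x$human_gradients[["CL_over_PP"]],
              x$human_gradients[["PC_over_PP"]]))
  invisible(x)
}
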