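# Per-time-step stochastic update rules and the engine interface.
#
# The full per-TS update (dosing/absorption, compartment transfers, core
# flow, biased random walk, entry/exit, enzyme binding, metabolism, SS exit
# routing) runs in compiled code (src/engine.cpp) over a flat agent-state
# representation; this file provides the state constructor, the R-level
# stepping interface, and small standalone primitives.

#' Flow and movement parameters
#'
#' Per-time-step transfer probabilities and biased-random-walk weights.
#' These govern simulated absorption, hepatic blood flow, and extra-cellular
#' percolation; the values are system-level defaults shared by all compound
#' types (Marker, vC1-vC4 and Metabolites).
#'
#' @param k_absorption Per-TS transfer probability Intro -> Body (Media);
#'   first-order absorption.
#' @param f_body_to_pv Per-TS transfer probability Body -> portal vein
#'   (vHuman).
#' @param f_media_to_interface Per-TS transfer probability Media ->
#'   Media-Cell Interface (vCulture).
#' @param ss_flow_rate Per-TS forward-advance probability in the Core.
#' @param forward_bias,lateral_bias Walk weights for the extra-cellular
#'   grids. Each step a compound moves one grid space downstream (weight
#'   `forward_bias`), laterally around the circumference or radially to an
#'   adjacent concentric grid (weight `lateral_bias` per available move), or
#'   stays; weights are normalized when they sum above one.
#' @param core_split Probability that a compound distributed from the PV
#'   enters the Core (otherwise the Interface) of a layer-0 SS.
#' @param lateral_hop_guard After this many consecutive intra-layer hops the
#'   next SS exit must use an inter-layer edge, preventing unbounded lateral
#'   cycling.
#'
#' @details The transfer fractions and walk biases are not observable
#'   quantities; the defaults are the frozen output of the bounded
#'   calibration documented in `scripts/calibrate_flow.R`, which matches the
#'   periportal-to-pericentral entry-rate gradient and the cross-system peak
#'   ratio while preserving cross-system equivalence of vC1 entry rates.
#' @return List of class `flow_params`.
#' @export
flow_params <- function(k_absorption = 0.002,
                        f_body_to_pv = 0.03,
                        f_media_to_interface = 0.03,
                        ss_flow_rate = 0.8,
                        forward_bias = 0.2,
                        lateral_bias = 0.3,
                        core_split = 0.5,
                        lateral_hop_guard = 10L) {
  p <- c(k_absorption = k_absorption, f_body_to_pv = f_body_to_pv,
         f_media_to_interface = f_media_to_interface,
         ss_flow_rate = ss_flow_rate, core_split = core_split)
  if (any(p < 0 | p > 1)) stop("transfer probabilities must lie in [0, 1]",
                               call. = FALSE)
  if (forward_bias < 0 || lateral_bias < 0) {
    stop("walk biases must be non-negative", call. = FALSE)
  }
  structure(list(k_absorption = k_absorption, f_body_to_pv = f_body_to_pv,
                 f_media_to_interface = f_media_to_interface,
                 ss_flow_rate = ss_flow_rate, forward_bias = forward_bias,
                 lateral_bias = lateral_bias, core_split = core_split,
                 lateral_hop_guard = as.integer(lateral_hop_guard)),
            class = "flow_params")
}

#' Binomial compartment transfer
#'
#' Each of `n` objects in a source compartment independently moves to the
#' destination with probability `p` (binomial thinning).
#'
#' @param n Object count in the source compartment.
#' @param p Per-object transfer probability.
#' @return Integer count of objects moved.
#' @export
transfer_fraction <- function(n, p) {
  stopifnot(p >= 0, p <= 1, n >= 0)
  if (n == 0) return(0L)
  rbinom(1L, n, p)
}

#' Initial system state
#'
#' Creates the flat agent-state for one execution: `dose_total` compound
#' objects of which `standard_fraction` are Marker, all placed in the Intro
#' space (first-order dosing) or directly in Body/Media (bolus).
#'
#' @param structure A [build_lobule_structure()] or
#'   [build_culture_structure()] result.
#' @param dose_total Total number of dosed objects.
#' @param standard_fraction Marker share of the dose.
#' @param dosing_mode `"first_order"` or `"bolus"`.
#' @return List of class `system_state`.
#' @export
init_system_state <- function(structure, dose_total = 100000L,
                              standard_fraction = 0.5,
                              dosing_mode = c("first_order", "bolus")) {
  dosing_mode <- match.arg(dosing_mode)
  dose_total <- as.integer(dose_total)
  stopifnot(dose_total >= 0, standard_fraction >= 0, standard_fraction <= 1)
  n_marker <- as.integer(round(dose_total * standard_fraction))
  n_test <- dose_total - n_marker
  n <- dose_total
  start_loc <- if (dosing_mode == "bolus") 1L else 0L
  P <- structure$n_pos
  structure(list(
    ts = 0L,
    typ = rep.int(c(0L, 1L), c(n_marker, n_test)),
    loc = rep.int(start_loc, n),
    ss = integer(n), w = integer(n), l = integer(n),
    bound = integer(n), rel_ts = integer(n), metflag = integer(n),
    lat_hops = integer(n), last_entry_ts = rep.int(-1L, n),
    enz_occ = integer(P),
    counters = setNames(numeric(8),
                        c("att_entry", "n_entry", "att_exit", "n_exit",
                          "att_bind", "n_bind", "n_release", "n_metab")),
    vhpc_entries = integer(P)
  ), class = "system_state")
}

# Engine argument marshalling ------------------------------------------------

engine_structure <- function(structure) {
  out <- list(is_culture = isTRUE(structure$is_culture),
              width = structure$width,
              ss_layer = structure$ss_layer,
              ss_len = structure$ss_len,
              goff = structure$goff,
              open = structure$open,
              nenz = structure$nenz,
              band = structure$band)
  if (!out$is_culture) {
    e <- structure$graph$edges
    # per-SS outgoing edges, inter-layer (and CV, dst -1) first, intra after
    e <- e[order(e$src, e$intra), ]
    n_ss <- length(structure$ss_len)
    deg <- tabulate(e$src, n_ss)
    out$edge_dst <- as.integer(e$dst) - 1L      # CV (0) becomes -1
    out$estart <- as.integer(c(0L, cumsum(deg))[seq_len(n_ss)])
    out$eintra <- as.integer(tabulate(e$src[e$intra], n_ss))
    out$einter <- as.integer(deg - out$eintra)
    out$layer0 <- as.integer(which(structure$ss_layer == 0L) - 1L)
  }
  out
}

engine_comp <- function(spec, metabolite = preset_spec("Metabolite")) {
  list(crossing = as.integer(c(FALSE, spec$membrane_crossing,
                               metabolite$membrane_crossing)),
       p_enter = c(0, effective_p_enter(spec), 0),
       p_exit = c(0, spec$p_exit, metabolite$p_exit),
       p_bind = spec$p_bind,
       p_metabolize = spec$p_metabolize,
       bind_cycles = spec$bind_cycles)
}

engine_flow <- function(flow, is_culture) {
  list(k_absorption = flow$k_absorption,
       f_in = if (is_culture) flow$f_media_to_interface else flow$f_body_to_pv,
       ss_flow_rate = flow$ss_flow_rate,
       forward_bias = flow$forward_bias,
       lateral_bias = flow$lateral_bias,
       core_split = flow$core_split,
       lateral_hop_guard = flow$lateral_hop_guard)
}

#' Advance a system state
#'
#' Applies the full per-time-step update `n_ts` times: absorption transfer,
#' Body -> PV (or Media -> Interface) transfer, PV distribution to layer-0
#' SSs, core flow and biased random walks, hepatocyte entry attempts,
#' scheduled releases and metabolism, enzyme binding, exits, SS exit routing
#' and CV -> Body returns. Object counts are conserved (parents plus
#' metabolites); with `check = TRUE` conservation and enzyme-occupancy
#' invariants are asserted every TS.
#'
#' @param state A [init_system_state()] result (or a previously returned
#'   state).
#' @param structure The system structure the state was built for.
#' @param compound The test-compound [compound_spec()].
#' @param flow A [flow_params()].
#' @param n_ts Number of time-steps to advance.
#' @param record Record the per-TS series matrix.
#' @param check Assert conservation invariants every TS.
#' @return List with the updated `state` and (when `record`) a `series`
#'   matrix with one row per TS.
#' @export
advance_one_ts <- function(state, structure, compound,
                           flow = flow_params(), n_ts = 1L,
                           record = FALSE, check = FALSE) {
  stopifnot(inherits(state, "system_state"),
            inherits(compound, "compound_spec"))
  run_engine_cpp(engine_structure(structure), engine_comp(compound),
                 engine_flow(flow, isTRUE(structure$is_culture)),
                 as.integer(n_ts), state, record, check)
}
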