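# Compound types and the entry-probability model.
#
# A compound spec is an immutable parameter set. Five presets are provided:
# Marker (non-permeant internal standard), vC1/vC2 (the two removal extremes
# for highly permeable compounds), vC3 (slow metabolism), vC4 (intermediate
# metabolism), plus the Metabolite type created when a bound compound is
# metabolized.

#' Construct a compound specification
#'
#' A compound spec bundles every per-compound parameter used by the
#' simulation engine: membrane permeation, the entry/exit probabilities, the
#' enzyme-binding and metabolism probabilities, and the extra-cellular
#' movement biases.
#'
#' @param name Label for the compound.
#' @param membrane_crossing Logical; if `FALSE` the compound can never enter
#'   a cell (this is how Marker and Metabolites behave) and can traverse the
#'   endothelial layer only through open fenestrae.
#' @param fraction_unbound Fraction of the compound not bound to protein and
#'   hence available to enter a hepatocyte; in `[0, 1]`.
#' @param p_enter_unbound Per-time-step entry probability of an unbound,
#'   collocated compound. Kept at 1 for the highly permeable compounds
#'   studied here.
#' @param p_exit Per-time-step exit probability of an unbound intracellular
#'   compound.
#' @param p_bind Per-time-step probability of binding one unoccupied enzyme.
#' @param p_metabolize Probability, drawn once at binding time, that the
#'   bound compound is deleted and replaced by a Metabolite on release.
#' @param bind_cycles Number of time-steps a bound compound stays bound.
#' @param forward_bias,lateral_bias Dimensionless biased-random-walk weights
#'   used while the compound is extra-cellular. `NA` means "use the system
#'   flow parameters", which is the default for all presets.
#' @param is_metabolite Logical; metabolite objects never re-enter cells.
#'
#' @return An object of class `compound_spec`.
#' @seealso [preset_spec()], [effective_p_enter()]
#' @export
compound_spec <- function(name,
                          membrane_crossing = TRUE,
                          fraction_unbound = 1,
                          p_enter_unbound = 1,
                          p_exit = 1,
                          p_bind = 0,
                          p_metabolize = 0,
                          bind_cycles = 10L,
                          forward_bias = NA_real_,
                          lateral_bias = NA_real_,
                          is_metabolite = FALSE) {
  probs <- c(fraction_unbound = fraction_unbound,
             p_enter_unbound = p_enter_unbound,
             p_exit = p_exit, p_bind = p_bind, p_metabolize = p_metabolize)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop("probability field(s) outside [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (bind_cycles < 0) stop("bind_cycles must be >= 0", call. = FALSE)
  if (is_metabolite && membrane_crossing) {
    stop("a Metabolite does not enter cells: membrane_crossing must be FALSE",
         call. = FALSE)
  }
  structure(list(
    name = as.character(name),
    membrane_crossing = isTRUE(membrane_crossing),
    fraction_unbound = as.numeric(fraction_unbound),
    p_enter_unbound = as.numeric(p_enter_unbound),
    p_exit = as.numeric(p_exit),
    p_bind = as.numeric(p_bind),
    p_metabolize = as.numeric(p_metabolize),
    bind_cycles = as.integer(bind_cycles),
    forward_bias = as.numeric(forward_bias),
    lateral_bias = as.numeric(lateral_bias),
    is_metabolite = isTRUE(is_metabolite)
  ), class = "compound_spec")
}

#' Preset compound specifications
#'
#' The five compound types used throughout: `Marker` is the non-permeant
#' internal standard; `vC1` enters and exits freely and is never removed
#' (`p_exit = 1`, no binding); `vC2` experiences maximal removal (it enters
#' but never exits, `p_exit = 0`); `vC3` is very slowly metabolized
#' (`p_bind = 0.01`, `p_metabolize = 0.005`); `vC4` has intermediate
#' metabolism (`p_bind = 0.1`, `p_metabolize = 0.015`); `Metabolite` exits
#' cells with probability 1 and never re-enters. All permeant presets use
#' `p_enter_unbound = 1` and `bind_cycles = 10` and share the system
#' movement biases.
#'
#' @param name One of `"Marker"`, `"vC1"`, `"vC2"`, `"vC3"`, `"vC4"`,
#'   `"Metabolite"`.
#' @param fraction_unbound Extracellular unbound fraction; ignored for
#'   `Marker` and `Metabolite`.
#' @return A [compound_spec()].
#' @examples
#' preset_spec("vC2", 0.5)$p_exit       # 0
#' preset_spec("vC4", 1.0)$p_bind       # 0.1
#' preset_spec("Marker")$membrane_crossing  # FALSE
#' @export
preset_spec <- function(name, fraction_unbound = 1) {
  switch(as.character(name),
    Marker = compound_spec("Marker", membrane_crossing = FALSE,
                           fraction_unbound = 1, p_exit = 1),
    vC1 = compound_spec("vC1", fraction_unbound = fraction_unbound,
                        p_exit = 1, p_bind = 0),
    vC2 = compound_spec("vC2", fraction_unbound = fraction_unbound,
                        p_exit = 0, p_bind = 0),
    vC3 = compound_spec("vC3", fraction_unbound = fraction_unbound,
                        p_exit = 1, p_bind = 0.01, p_metabolize = 0.005),
    vC4 = compound_spec("vC4", fraction_unbound = fraction_unbound,
                        p_exit = 1, p_bind = 0.1, p_metabolize = 0.015),
    Metabolite = compound_spec("Metabolite", membrane_crossing = FALSE,
                               p_exit = 1, is_metabolite = TRUE),
    stop("unknown compound preset: ", name, call. = FALSE)
  )
}

#' Effective per-time-step entry probability
#'
#' Only the unbound fraction of a collocated compound is available to enter
#' a hepatocyte, so the entry probability is
#' `fraction_unbound * p_enter_unbound`; a non-permeant compound
#' (`membrane_crossing = FALSE`) never enters.
#'
#' @param spec A [compound_spec()].
#' @return A probability in `[0, 1]`.
#' @examples
#' effective_p_enter(preset_spec("vC1", 0.3))  # 0.3
#' effective_p_enter(preset_spec("Marker"))    # 0
#' @export
effective_p_enter <- function(spec) {
  stopifnot(inherits(spec, "compound_spec"))
  if (!spec$membrane_crossing) return(0)
  spec$fraction_unbound * spec$p_enter_unbound
}

#' Single-attempt entry draws
#'
#' Simulates independent single entry attempts for a compound spec. Used for
#' verifying that entry frequencies match [effective_p_enter()].
#'
#' @param spec A [compound_spec()].
#' @param n Number of independent attempts.
#' @return Logical vector of length `n`.
#' @export
attempt_entry <- function(spec, n = 1L) {
  runif(n) < effective_p_enter(spec)
}

#' Default fraction-unbound sweep
#'
#' The seven extracellular unbound fractions spanning 0.05 to 1.0 at which
#' every compound is studied.
#'
#' @return Numeric vector of length 7.
#' @export
default_fu_sweep <- function() c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8, 1.0)

#' @export
print.compound_spec <- function(x, ...) {
  cat(sprintf(
    "<compound_spec> %s\n  membrane_crossing: %s  fu: %.3g  pEnter: %.3g  pExit: %.3g\n  pBind: %.3g  pMetabolize: %.3g  bindCycles: %d%s\n",
    x$name, x$membrane_crossing, x$fraction_unbound, effective_p_enter(x),
    x$p_exit, x$p_bind, x$p_metabolize, x$bind_cycles,
    if (x$is_metabolite) "  [metabolite]" else ""))
  invisible(x)
}
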