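# Configuration files and experiment recipes.
#
# A config file is YAML (or JSON) with top-level keys mirroring
# experiment_config(), e.g.:
#
#   system: vhuman
#   compound: vC2
#   fraction_unbound: 0.05
#   n_mc: 12
#   flow:
#     ss_flow_rate: 0.5

config_keys <- c("system", "compound", "fraction_unbound", "dose_total",
                 "standard_fraction", "n_ts", "n_mc", "base_seed",
                 "dosing_mode", "flow", "structure", "bands", "check")

#' Load an experiment configuration file
#'
#' Reads a YAML (or JSON) recipe, fills defaults for omitted fields,
#' validates every invariant, and rejects unknown keys.
#'
#' @param path Config file.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sub_build <- function(block, builder) {
    if (is.null(block)) return(builder())
    known <- names(formals(builder))
    bad <- setdiff(names(block), known)
    if (length(bad)) {
      stop("unknown key(s) in ", deparse(substitute(builder)), " block: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(builder, block)
  }
  fu <- raw$fraction_unbound %||% 1
  if (fu < 0 || fu > 1) {
    stop("fraction_unbound must lie in [0, 1]", call. = FALSE)
  }
  experiment_config(
    system = raw$system %||% "vculture",
    compound = raw$compound %||% "vC1",
    fraction_unbound = fu,
    dose_total = raw$dose_total %||% 100000L,
    standard_fraction = raw$standard_fraction %||% 0.5,
    n_ts = raw$n_ts %||% 21600L,
    n_mc = raw$n_mc %||% 12L,
    base_seed = raw$base_seed %||% 1L,
    dosing_mode = raw$dosing_mode %||% "first_order",
    flow = sub_build(raw$flow, flow_params),
    structure = sub_build(raw$structure, structure_config),
    bands = sub_build(raw$bands, band_spec),
    check = raw$check %||% FALSE)
}

#' Serialize a configuration back to YAML
#'
#' @param cfg An [experiment_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  out <- list(system = cfg$system,
              compound = cfg$compound$name,
              fraction_unbound = cfg$compound$fraction_unbound,
              dose_total = cfg$dose_total,
              standard_fraction = cfg$standard_fraction,
              n_ts = cfg$n_ts, n_mc = cfg$n_mc, base_seed = cfg$base_seed,
              dosing_mode = cfg$dosing_mode,
              flow = unclass(cfg$flow),
              structure = lapply(unclass(cfg$structure), function(v) {
                if (!is.null(names(v)) && length(v) > 1) as.list(v) else v
              }),
              bands = unclass(cfg$bands))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write the full recipe-file grid
#'
#' Generates one YAML recipe per figure condition (vC1-vC4, both systems,
#' the seven-value unbound-fraction sweep) plus reduced-scale test variants
#' (dose 10,000, 6,000 TS, 3 MC executions). A few representative recipes
#' also ship pre-generated in `inst/recipes`.
#'
#' @param dir Output directory.
#' @param reduced Also write the reduced-scale variants.
#' @return Invisibly, the files written.
#' @export
write_recipe_files <- function(dir, reduced = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sys in c("vculture", "vhuman")) {
    for (cmp in c("vC1", "vC2", "vC3", "vC4")) {
      for (fu in default_fu_sweep()) {
        tag <- sprintf("%s_%s_fu%03d", sys, tolower(cmp), round(fu * 100))
        cfg <- experiment_config(sys, cmp, fu)
        files <- c(files, write_config(cfg, file.path(dir, paste0(tag, ".yaml"))))
        if (reduced) {
          cfg_r <- experiment_config(sys, cmp, fu, dose_total = 10000L,
                                     n_ts = 6000L, n_mc = 3L)
          files <- c(files, write_config(
            cfg_r, file.path(dir, paste0(tag, "_reduced.yaml"))))
        }
      }
    }
  }
  invisible(files)
}
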