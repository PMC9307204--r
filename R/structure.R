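# Spatial substrate: sinusoidal-segment (SS) grids with resident endothelial
# cells and vHepatocytes, and the flattened single-layer culture layout.
#
# A quasi-3D SS is a Core flow channel wrapped by concentric 2D grids
# (Interface, Endothelial, Space of Disse, Hepatocyte). Grids are cylinders:
# the width dimension (circumference, clamped at 15) wraps, the length
# (flow) dimension does not. The Hepatocyte grid is fully occupied by vHPCs;
# the Endothelial grid is 99% occupied by endothelial cells, with ~1% open
# fenestrae (at least one per SS) through which non-permeant objects reach
# the Space of Disse.

#' Structure configuration
#'
#' Structural constants of the two systems. Defaults are the values used for
#' every experiment: five layers of 45/25/20/15/9 SSs, 55/65/35/25
#' inter-layer and 20/7/5/2/0 intra-layer flow edges, SS width clamped at 15
#' grid spaces, 5 to 10 enzymes per vHPC, 1% open endothelial locations, and
#' a discrete SS length law on 3..8 grid spaces whose mean (~4.956) puts the
#' expected vLiver hepatocyte count at 114 * 15 * 4.956 = 8475.
#'
#' @param layer_sizes Integer vector, SSs per lobule layer.
#' @param inter_layer_edges Integer vector, flow edges between consecutive
#'   layers.
#' @param intra_layer_edges Integer vector, lateral edges within each layer.
#' @param width SS circumference in grid spaces.
#' @param length_probs Named numeric vector: probability of each integer SS
#'   length. Must be a proper distribution with bounded integer support in
#'   3..8.
#' @param culture_units Number of culture SS units.
#' @param culture_length Fixed hepatocyte-space length in culture.
#' @param enzymes_min,enzymes_max Bounds of the discrete uniform law for the
#'   number of enzymes per vHPC.
#' @param open_fraction Fraction of endothelial locations left open.
#' @return A list of class `structure_config`.
#' @export
structure_config <- function(layer_sizes = c(45L, 25L, 20L, 15L, 9L),
                             inter_layer_edges = c(55L, 65L, 35L, 25L),
                             intra_layer_edges = c(20L, 7L, 5L, 2L, 0L),
                             width = 15L,
                             length_probs = default_length_probs(),
                             culture_units = 114L,
                             culture_length = 5L,
                             enzymes_min = 5L,
                             enzymes_max = 10L,
                             open_fraction = 0.01) {
  length_probs <- unlist(length_probs)   # tolerate YAML-parsed lists
  cfg <- list(layer_sizes = as.integer(layer_sizes),
              inter_layer_edges = as.integer(inter_layer_edges),
              intra_layer_edges = as.integer(intra_layer_edges),
              width = as.integer(width),
              length_probs = length_probs,
              culture_units = as.integer(culture_units),
              culture_length = as.integer(culture_length),
              enzymes_min = as.integer(enzymes_min),
              enzymes_max = as.integer(enzymes_max),
              open_fraction = open_fraction)
  validate_length_probs(cfg$length_probs)
  class(cfg) <- "structure_config"
  cfg
}

#' Default SS length distribution
#'
#' Discrete law on lengths 3..8 grid spaces, moment-matched so that the mean
#' length is ~4.956 (expected vLiver vHPC count 8475 with SD ~162), the mean
#' per-execution minimum over 114 SSs is ~3.2, and the mean maximum is ~7.4.
#' `scripts/tune_length_dist.R` documents the matching.
#'
#' @return Named probability vector.
#' @export
default_length_probs <- function() {
  c(`3` = 0.014, `4` = 0.378, `5` = 0.354, `6` = 0.150,
    `7` = 0.100, `8` = 0.004)
}

validate_length_probs <- function(p) {
  v <- suppressWarnings(as.integer(names(p)))
  if (length(p) == 0 || any(is.na(v))) {
    stop("length_probs must be named by integer lengths", call. = FALSE)
  }
  if (any(v < 3L) || any(v > 8L)) {
    stop("length distribution support must lie in 3..8 grid spaces",
         call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("length_probs must be a probability distribution", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample sinusoidal-segment dimensions
#'
#' Width is clamped at 15 grid spaces; length is drawn from the (bounded,
#' integer) length distribution.
#'
#' @param n Number of SSs to sample.
#' @param length_probs Named probability vector over integer lengths (see
#'   [default_length_probs()]).
#' @param width SS circumference.
#' @return Data frame with columns `width` and `length`.
#' @export
sample_ss_dims <- function(n, length_probs = default_length_probs(),
                           width = 15L) {
  validate_length_probs(length_probs)
  lens <- as.integer(names(length_probs))
  idx <- sample.int(length(lens), n, replace = TRUE, prob = length_probs)
  data.frame(width = rep.int(as.integer(width), n), length = lens[idx])
}

#' Build one sinusoidal segment
#'
#' Allocates the concentric grids for a single SS: one vHPC per Hepatocyte
#' location with an enzyme count drawn from a discrete uniform law, and a
#' per-SS rounded count of open endothelial locations (at least one, sampled
#' without replacement) so every SS gives non-permeant objects a route to
#' the Space of Disse.
#'
#' @param dims One-row data frame from [sample_ss_dims()], or a list with
#'   `width` and `length`.
#' @param layer Lobule layer index (0-4), or `"culture"`.
#' @param cfg A [structure_config()].
#' @return List of class `sinusoidal_segment` with fields `width`, `length`,
#'   `layer`, `n_vhpc`, `n_enzymes` (integer vector, one per vHPC in
#'   column-major (w, l) order), and `open` (logical vector over endothelial
#'   locations in the same order).
#' @export
build_ss <- function(dims, layer = 0L, cfg = structure_config()) {
  w <- as.integer(dims$width); len <- as.integer(dims$length)
  stopifnot(w >= 1L, len >= 1L)
  n <- w * len
  n_open <- max(1L, as.integer(round(cfg$open_fraction * n)))
  open <- logical(n)
  open[sample.int(n, n_open)] <- TRUE
  structure(list(
    width = w, length = len, layer = layer, n_vhpc = n,
    n_enzymes = sample(seq.int(cfg$enzymes_min, cfg$enzymes_max), n,
                       replace = TRUE),
    open = open
  ), class = "sinusoidal_segment")
}

# Flat per-position arrays for a set of SSs, used by the simulation engine.
# Position index for SS s at (w, l), all 0-based in the engine:
#   goff[s] + l * width + w.
flatten_sss <- function(ss_list, layers, width) {
  lens <- vapply(ss_list, function(s) s$length, integer(1))
  sizes <- width * lens
  goff <- c(0L, cumsum(sizes))[seq_along(ss_list)]
  list(ss_layer = as.integer(layers),
       ss_len = lens,
       goff = as.integer(goff),
       n_pos = sum(sizes),
       nenz = unlist(lapply(ss_list, function(s) s$n_enzymes),
                     use.names = FALSE),
       open = unlist(lapply(ss_list, function(s) s$open), use.names = FALSE))
}

#' Build a full vLiver (lobule) structure
#'
#' Samples SS dimensions, builds every SS, samples the lobule flow graph,
#' and assigns each vHPC a periportal / centrilobular / pericentral band.
#' Uses the current RNG stream, so the structure is reproducible under a
#' fixed seed.
#'
#' @param cfg A [structure_config()].
#' @param bands A [band_spec()].
#' @return List of class `liver_structure`: per-SS arrays (`ss_layer`,
#'   `ss_len`, `goff`), per-vHPC arrays (`nenz`, `open`, `band`, `dPV`,
#'   `dCV`), the sampled [lobule_graph], `n_vhpc` and the per-band vHPC
#'   counts `band_sizes`.
#' @export
build_lobule_structure <- function(cfg = structure_config(),
                                   bands = band_spec()) {
  layers <- rep.int(seq_along(cfg$layer_sizes) - 1L, cfg$layer_sizes)
  dims <- sample_ss_dims(length(layers), cfg$length_probs, cfg$width)
  ss_list <- lapply(seq_along(layers), function(i) {
    build_ss(dims[i, ], layers[i], cfg)
  })
  flat <- flatten_sss(ss_list, layers, cfg$width)
  graph <- build_lobule_graph(lobule_graph_spec(
    layer_sizes = cfg$layer_sizes,
    inter_layer_edges = cfg$inter_layer_edges,
    intra_layer_edges = cfg$intra_layer_edges))
  bnd <- assign_bands(flat, cfg$width, bands)
  structure(c(flat, list(
    width = cfg$width, graph = graph, is_culture = FALSE,
    n_vhpc = flat$n_pos,
    band = bnd$band, dPV = bnd$dPV, dCV = bnd$dCV,
    band_sizes = c(PP = sum(bnd$band == 1L), CL = sum(bnd$band == 2L),
                   PC = sum(bnd$band == 3L))
  )), class = "liver_structure")
}

#' Build the vCulture structure
#'
#' 114 single-layer SS units, each a 15 x 5 Hepatocyte Space under a merged
#' Media-Cell Interface; no Core, Endothelial, or Disse grids. One vHPC per
#' grid location, 8,550 in total at defaults.
#'
#' @param cfg A [structure_config()]. `culture_units` and `culture_length`
#'   control the layout.
#' @return List of class `culture_structure` with the same flat arrays as
#'   [build_lobule_structure()] (bands are absent: `band` is 0 everywhere).
#' @export
build_culture_structure <- function(cfg = structure_config()) {
  nu <- cfg$culture_units
  dims <- data.frame(width = rep.int(cfg$width, nu),
                     length = rep.int(cfg$culture_length, nu))
  ss_list <- lapply(seq_len(nu), function(i) build_ss(dims[i, ], "culture", cfg))
  flat <- flatten_sss(ss_list, rep.int(0L, nu), cfg$width)
  structure(c(flat, list(
    width = cfg$width, graph = NULL, is_culture = TRUE,
    n_vhpc = flat$n_pos,
    band = rep.int(0L, flat$n_pos),
    dPV = rep(NA_real_, flat$n_pos), dCV = rep(NA_real_, flat$n_pos),
    band_sizes = c(PP = 0L, CL = 0L, PC = 0L)
  )), class = "culture_structure")
}

#' @export
print.liver_structure <- function(x, ...) {
  cat(sprintf(
    "<liver_structure> %d SSs in layers [%s], %d vHPCs\n  bands PP/CL/PC: %d/%d/%d  edges: %d inter + %d intra\n",
    length(x$ss_len), paste(tabulate(x$ss_layer + 1L), collapse = "/"),
    x$n_vhpc, x$band_sizes[["PP"]], x$band_sizes[["CL"]],
    x$band_sizes[["PC"]], sum(!x$graph$edges$intra & x$graph$edges$dst > 0),
    sum(x$graph$edges$intra)))
  invisible(x)
}

#' @export
print.culture_structure <- function(x, ...) {
  cat(sprintf("<culture_structure> %d units of %d x %d, %d vHPCs\n",
              length(x$ss_len), x$width, x$ss_len[1], x$n_vhpc))
  invisible(x)
}
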