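# The Monte Carlo-sampled directed lobule flow graph.
#
# Nodes are SSs grouped into five layers; the portal vein (PV) feeds every
# layer-0 SS and every layer-4 SS drains to the central vein (CV).
# Inter-layer edges run layer k -> k+1 only (the inter-layer subgraph is
# acyclic); intra-layer edges mimic sinusoid interconnections and are
# traversed laterally (they do not advance the layer).

#' Lobule graph specification
#'
#' Edge and node counts are fixed for all experiments; only the SS-to-SS
#' connections are resampled per execution.
#'
#' @param layer_sizes SSs per layer (sums to 114 at defaults).
#' @param inter_layer_edges Edges between consecutive layers (55/65/35/25).
#' @param intra_layer_edges Edges within each layer (20/7/5/2/0).
#' @return List of class `lobule_graph_spec`.
#' @export
lobule_graph_spec <- function(layer_sizes = c(45L, 25L, 20L, 15L, 9L),
                              inter_layer_edges = c(55L, 65L, 35L, 25L),
                              intra_layer_edges = c(20L, 7L, 5L, 2L, 0L)) {
  stopifnot(length(inter_layer_edges) == length(layer_sizes) - 1L,
            length(intra_layer_edges) == length(layer_sizes))
  need <- pmax(layer_sizes[-length(layer_sizes)], layer_sizes[-1])
  if (any(inter_layer_edges < need)) {
    stop("inter-layer edge counts cannot cover every node", call. = FALSE)
  }
  structure(list(layer_sizes = as.integer(layer_sizes),
                 inter_layer_edges = as.integer(inter_layer_edges),
                 intra_layer_edges = as.integer(intra_layer_edges)),
            class = "lobule_graph_spec")
}

# Sample m distinct directed (src, dst) pairs between node sets a and b such
# that every src has >= 1 outgoing and every dst >= 1 incoming edge.
sample_bipartite_edges <- function(a, b, m, max_retry = 1000L) {
  M <- max(length(a), length(b))
  for (try in seq_len(max_retry)) {
    src <- rep_len(sample(a), M)
    dst <- rep_len(sample(b), M)
    extra <- m - M
    if (extra > 0L) {
      src <- c(src, sample(a, extra, replace = TRUE))
      dst <- c(dst, sample(b, extra, replace = TRUE))
    }
    if (!anyDuplicated(paste(src, dst))) {
      return(data.frame(src = src, dst = dst))
    }
  }
  stop("could not sample distinct inter-layer edges", call. = FALSE)
}

# Sample m distinct directed intra-layer pairs (no self loops), with a
# random orientation for each sampled pair.
sample_intra_edges <- function(nodes, m, max_retry = 1000L) {
  if (m == 0L) return(data.frame(src = integer(0), dst = integer(0)))
  n <- length(nodes)
  if (m > n * (n - 1L)) stop("too many intra-layer edges", call. = FALSE)
  for (try in seq_len(max_retry)) {
    src <- nodes[sample.int(n, m, replace = TRUE)]
    off <- sample.int(n - 1L, m, replace = TRUE)
    dst <- nodes[(match(src, nodes) - 1L + off) %% n + 1L]
    if (!anyDuplicated(paste(src, dst))) {
      return(data.frame(src = src, dst = dst))
    }
  }
  stop("could not sample distinct intra-layer edges", call. = FALSE)
}

#' Build a Monte Carlo-sampled lobule flow graph
#'
#' Edge endpoints are sampled uniformly subject to exact edge counts, full
#' coverage (every node of layer k >= 1 has an inbound inter-layer edge,
#' every node of layer k <= 3 an outbound one), no self loops, and no
#' duplicate directed pairs. Node ids are 1..114 in layer order; `dst = 0`
#' denotes the CV.
#'
#' @param spec A [lobule_graph_spec()].
#' @return List of class `lobule_graph` with `layer` (per-node layer),
#'   `edges` (data frame `src`, `dst`, `intra`), and `spec`.
#' @export
build_lobule_graph <- function(spec = lobule_graph_spec()) {
  sizes <- spec$layer_sizes
  nlay <- length(sizes)
  layer <- rep.int(seq_len(nlay) - 1L, sizes)
  nodes <- split(seq_along(layer), layer)
  inter <- do.call(rbind, lapply(seq_len(nlay - 1L), function(k) {
    sample_bipartite_edges(nodes[[k]], nodes[[k + 1L]],
                           spec$inter_layer_edges[k])
  }))
  inter$intra <- FALSE
  cv <- data.frame(src = nodes[[nlay]], dst = 0L, intra = FALSE)
  intra <- do.call(rbind, lapply(seq_len(nlay), function(k) {
    sample_intra_edges(nodes[[k]], spec$intra_layer_edges[k])
  }))
  if (nrow(intra)) intra$intra <- TRUE
  edges <- rbind(inter, cv, if (nrow(intra)) intra)
  rownames(edges) <- NULL
  structure(list(layer = layer, edges = edges, spec = spec),
            class = "lobule_graph")
}

# Breadth-first reachability over a directed edge list.
bfs_reachable <- function(n_nodes, src, dst, from) {
  seen <- logical(n_nodes)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(dst[src %in% frontier & dst > 0L])
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Validate a lobule graph
#'
#' Report-only checks: exact edge counts per layer pair and per layer,
#' coverage (no node without inbound/outbound inter-layer edges), forward
#' orientation of inter-layer edges, and PV/CV reachability by breadth-first
#' search.
#'
#' @param graph A [lobule_graph].
#' @return List of class `graph_validation` with per-check results and an
#'   overall `pass` flag.
#' @export
validate_graph <- function(graph) {
  spec <- graph$spec
  layer <- graph$layer
  e <- graph$edges
  nlay <- length(spec$layer_sizes)
  checks <- list()

  inter <- e[!e$intra & e$dst > 0L, ]
  got_inter <- vapply(seq_len(nlay - 1L), function(k) {
    sum(layer[inter$src] == k - 1L & layer[inter$dst] == k)
  }, integer(1))
  checks$inter_counts <- identical(got_inter, spec$inter_layer_edges)
  checks$inter_forward <- all(layer[inter$dst] == layer[inter$src] + 1L)

  intra <- e[e$intra, ]
  got_intra <- vapply(seq_len(nlay), function(k) {
    sum(layer[intra$src] == k - 1L)
  }, integer(1))
  checks$intra_counts <- identical(got_intra, spec$intra_layer_edges)
  checks$intra_same_layer <-
    !nrow(intra) || all(layer[intra$src] == layer[intra$dst] &
                          intra$src != intra$dst)

  cv_src <- e$src[e$dst == 0L]
  checks$cv_edges <- identical(sort(cv_src), which(layer == nlay - 1L))
  checks$no_duplicates <- !anyDuplicated(paste(e$src, e$dst))

  pv_reach <- bfs_reachable(length(layer), e$src, e$dst,
                            which(layer == 0L))
  # co-reachability to CV: reverse edges, start from CV sources
  rev_ok <- bfs_reachable(length(layer), e$dst[e$dst > 0L],
                          e$src[e$dst > 0L], cv_src)
  checks$reachable_from_pv <- all(pv_reach)
  checks$coreachable_to_cv <- all(rev_ok)
  orphans <- which(!pv_reach | !rev_ok)

  structure(list(checks = checks, orphans = orphans,
                 pass = all(unlist(checks))),
            class = "graph_validation")
}

#' @export
print.graph_validation <- function(x, ...) {
  cat("<graph_validation>", if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$checks)) {
    cat(sprintf("  %-20s %s\n", nm, if (x$checks[[nm]]) "ok" else "FAIL"))
  }
  if (length(x$orphans)) {
    cat("  orphaned nodes:", paste(x$orphans, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Band thresholds
#'
#' Distance thresholds (in grid spaces) defining the periportal (PP) and
#' pericentral (PC) bands: a vHPC is PP when its distance from the PV is
#' below `pp_max_dPV` and PC when its distance from the CV is below
#' `pc_max_dCV`; everything else is centrilobular (CL). The defaults, 5 grid
#' spaces (about one mean SS length), align PP with layer 0 and PC with
#' layer 4.
#'
#' @param pp_max_dPV,pc_max_dCV Positive thresholds in grid spaces.
#' @return List of class `band_spec`.
#' @export
band_spec <- function(pp_max_dPV = 5, pc_max_dCV = 5) {
  stopifnot(pp_max_dPV > 0, pc_max_dCV > 0)
  structure(list(pp_max_dPV = pp_max_dPV, pc_max_dCV = pc_max_dCV),
            class = "band_spec")
}

# Assign each vHPC a PP/CL/PC band from its distance indices. dPV is the
# mean upstream path length (approximated by mean SS length times the layer
# index) plus the intra-SS position along the flow direction; dCV is the
# symmetric distance from the CV. PP wins if thresholds ever overlap.
assign_bands <- function(flat, width, bands = band_spec()) {
  mean_len <- mean(flat$ss_len)
  n_ss <- length(flat$ss_len)
  band <- integer(flat$n_pos)
  dPV <- dCV <- numeric(flat$n_pos)
  nlay <- max(flat$ss_layer) + 1L
  for (s in seq_len(n_ss)) {
    len <- flat$ss_len[s]
    lay <- flat$ss_layer[s]
    idx <- flat$goff[s] + seq_len(width * len)
    pos_l <- rep(0:(len - 1L), each = width)
    d_pv <- lay * mean_len + pos_l
    d_cv <- (nlay - 1L - lay) * mean_len + (len - 1L - pos_l)
    dPV[idx] <- d_pv
    dCV[idx] <- d_cv
    b <- rep.int(2L, width * len)
    b[d_cv < bands$pc_max_dCV] <- 3L
    b[d_pv < bands$pp_max_dPV] <- 1L   # PP wins on overlap
    band[idx] <- b
  }
  list(band = band, dPV = dPV, dCV = dCV)
}

#' Export band assignment
#'
#' One row per vHPC: owning SS, layer, grid position, distance indices and
#' band label, suitable for writing to CSV.
#'
#' @param structure A [build_lobule_structure()] result.
#' @return Data frame.
#' @export
band_table <- function(structure) {
  stopifnot(inherits(structure, "liver_structure"))
  n_ss <- length(structure$ss_len)
  w <- structure$width
  rows <- lapply(seq_len(n_ss), function(s) {
    len <- structure$ss_len[s]
    idx <- structure$goff[s] + seq_len(w * len)
    data.frame(vhpc_id = idx, ss_id = s, layer = structure$ss_layer[s],
               w = rep(seq_len(w), len), l = rep(seq_len(len), each = w),
               dPV = structure$dPV[idx], dCV = structure$dCV[idx],
               band = c("PP", "CL", "PC")[structure$band[idx]])
  })
  do.call(rbind, rows)
}

#' Export the flow graph as an edge list
#'
#' @param graph A [lobule_graph].
#' @param path Optional file; when given, a whitespace-separated edge list
#'   (`src dst type`) is written (CV is node 0).
#' @return The edge data frame, invisibly when written to file.
#' @export
edge_list <- function(graph, path = NULL) {
  e <- graph$edges
  e$type <- ifelse(e$intra, "intra", "inter")
  e$intra <- NULL
  if (!is.null(path)) {
    utils::write.table(e, path, quote = FALSE, row.names = FALSE)
    return(invisible(e))
  }
  e
}
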