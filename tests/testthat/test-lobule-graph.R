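test_that("sampled lobule graphs carry the fixed node and edge counts", {
  set.seed(51)
  g <- build_lobule_graph()
  expect_length(g$layer, 114L)
  expect_equal(tabulate(g$layer + 1L), c(45L, 25L, 20L, 15L, 9L))
  e <- g$edges
  inter <- e[!e$intra & e$dst > 0L, ]
  counts <- table(factor(g$layer[inter$src], levels = 0:3))
  expect_equal(unname(c(counts)), c(55L, 65L, 35L, 25L))
  expect_equal(sum(!e$intra & e$dst > 0L), 180L)
  intra <- table(factor(g$layer[e$src[e$intra]], levels = 0:4))
  expect_equal(unname(c(intra)), c(20L, 7L, 5L, 2L, 0L))
  expect_equal(sum(e$intra), 34L)
  expect_equal(sum(e$dst == 0L), 9L)   # one CV edge per layer-4 SS
})

test_that("graph validation passes across seeds and igraph confirms reachability", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    set.seed(60 + s)
    g <- build_lobule_graph()
    v <- validate_graph(g)
    expect_true(v$pass, label = paste("seed", s))
  }
  # independent reachability oracle on the last graph: PV (node 115) and CV
  # (node 116) attached explicitly
  e <- g$edges
  el <- rbind(cbind(e$src, ifelse(e$dst == 0L, 116L, e$dst)),
              cbind(115L, which(g$layer == 0L)))
  ig <- igraph::graph_from_edgelist(el, directed = TRUE)
  d_from_pv <- igraph::distances(ig, v = 115, mode = "out")[1, 1:114]
  d_to_cv <- igraph::distances(ig, v = 116, mode = "in")[1, 1:114]
  expect_true(all(is.finite(d_from_pv)))
  expect_true(all(is.finite(d_to_cv)))
})

test_that("an injected defect is reported with the orphaned node", {
  set.seed(81)
  g <- build_lobule_graph()
  victim <- which(g$layer == 4L)[1]
  g$edges <- g$edges[!(g$edges$src == victim & g$edges$dst == 0L), ]
  v <- validate_graph(g)
  expect_false(v$pass)
  expect_true(victim %in% v$orphans)
})

test_that("unsatisfiable edge specifications are rejected", {
  expect_error(lobule_graph_spec(inter_layer_edges = c(10L, 65L, 35L, 25L)),
               "cover")
})

test_that("band assignment is total, exclusive, and anchored at PV and CV", {
  set.seed(82)
  st <- build_lobule_structure()
  expect_true(all(st$band %in% 1:3))
  expect_equal(sum(st$band_sizes), st$n_vhpc)
  tab <- band_table(st)
  # periportal at the lobule inlet, pericentral at the outlet
  expect_true(all(tab$band[tab$layer == 0 & tab$l == 1] == "PP"))
  expect_true(all(tab$band[tab$dCV == 0] == "PC"))
  expect_true(all(tab$band[tab$dPV == 0] == "PP"))
  # vHPC numbers decrease PV-to-CV across layers
  per_layer <- tapply(tab$vhpc_id, tab$layer, length)
  expect_true(all(diff(per_layer) < 0))
})

test_that("edge list export round-trips", {
  set.seed(83)
  g <- build_lobule_graph()
  f <- tempfile(fileext = ".txt")
  edge_list(g, f)
  back <- read.table(f, header = TRUE)
  expect_equal(nrow(back), nrow(g$edges))
  expect_equal(sort(unique(back$type)), c("inter", "intra"))
})
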