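#!/usr/bin/env Rscript
# Bounded calibration of the four unprinted flow parameters.
#
# The transfer fraction (Body->PV = Media->Interface), the core flow rate,
# and the two walk biases are not printed in the main text. This script
# searches a bounded grid around physically plausible values and scores two
# calibration statistics only:
#
#   g    vC1 (fu 1.0) vHuman plateau entry-rate PC/PP fold   (reference 3.6)
#   x    vC2 (fu 0.05) vHuman/vCulture peak entry-rate fold  (reference 4.4)
#
# together with a guard on the vC1 cross-system equivalence (h/c plateau
# ratio must remain within 10% of 1, since equivalence of vC1 entry rates
# is the central validation property of the paired systems).
#
# Every other reported fold ratio is held out. The best point found by this
# search is frozen as the package's flow_params() defaults.
#
# Note on the outcome (documented in the methods vignette): the
# cross-system statistic x is flat (~1.0) across the whole box, because
# with per-TS Bernoulli entry attempts, preserving vC1 equivalence forces
# equal compound-vHPC adjacency time in both systems and hence equal
# window-capture probabilities for vC2. The search therefore effectively
# balances g against the equivalence guard.
#
# Usage: Rscript scripts/calibrate_flow.R [--seed N] [--out results/calibration.csv]

suppressPackageStartupMessages(library(hepasim))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, out = "results/calibration.csv")
i <- 1L
while (i <= length(args)) {
  switch(args[[i]],
         "--seed" = { opt$seed <- as.integer(args[[i + 1L]]); i <- i + 2L },
         "--out" = { opt$out <- args[[i + 1L]]; i <- i + 2L },
         stop("unknown argument: ", args[[i]]))
}

grid <- expand.grid(f = c(0.03, 0.05, 0.10),
                    ss_flow = c(0.5, 0.8),
                    fb = c(0.2, 0.3, 0.4),
                    lb = c(0.2, 0.3))

score_point <- function(f, ss_flow, fb, lb, seed) {
  fl <- flow_params(f_body_to_pv = f, f_media_to_interface = f,
                    ss_flow_rate = ss_flow, forward_bias = fb,
                    lateral_bias = lb)
  run <- function(system, compound, fu, base) {
    run_experiment(experiment_config(
      system, compound, fu, dose_total = 10000L, n_ts = 5000L, n_mc = 2L,
      base_seed = base, flow = fl))
  }
  stat <- function(res, mode, scope = "all") {
    mean(vapply(res$records, function(r) {
      smooth_and_summarize(series_extract(r, "entry_rate", scope),
                           mode = mode)
    }, numeric(1)))
  }
  h1 <- run("vhuman", "vC1", 1.0, seed + 10L)
  c1 <- run("vculture", "vC1", 1.0, seed + 20L)
  h2 <- run("vhuman", "vC2", 0.05, seed + 30L)
  c2 <- run("vculture", "vC2", 0.05, seed + 40L)
  g <- stat(h1, "plateau", "PC") / stat(h1, "plateau", "PP")
  x <- stat(h2, "peak") / stat(c2, "peak")
  eq <- stat(h1, "plateau") / stat(c1, "plateau")
  loss <- abs(log(g / 3.6)) + abs(log(x / 4.4)) +
    10 * max(0, abs(log(eq)) - log(1.1))   # equivalence guard
  c(g = g, x = x, eq = eq, loss = loss)
}

res <- t(apply(grid, 1L, function(p) {
  s <- score_point(p[["f"]], p[["ss_flow"]], p[["fb"]], p[["lb"]], opt$seed)
  cat(sprintf("f %.2f sf %.1f fb %.2f lb %.2f -> g %.2f x %.2f eq %.2f loss %.3f\n",
              p[["f"]], p[["ss_flow"]], p[["fb"]], p[["lb"]],
              s[["g"]], s[["x"]], s[["eq"]], s[["loss"]]))
  s
}))
tab <- cbind(grid, res)
dir.create(dirname(opt$out), showWarnings = FALSE, recursive = TRUE)
write.csv(tab, opt$out, row.names = FALSE)
best <- tab[which.min(tab$loss), ]
cat("\nbest point:\n")
print(best)
cat("frozen defaults in flow_params():",
    "f 0.03, ss_flow_rate 0.8, forward_bias 0.2, lateral_bias 0.3\n")
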