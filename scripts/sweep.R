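#!/usr/bin/env Rscript
# Thin command-line wrapper over the iolbench sweep functions:
#   Rscript scripts/sweep.R --axis both --grid 1024 --out results/sweeps
# Options:
#   --config <yaml>   bench configuration file (default: package defaults)
#   --axis <a>        decenter | tilt | both (default both)
#   --grid <n>        field grid samples per axis (default from config)
#   --out <dir>       output directory (default results/sweeps)
#   --no-mtf          skip the MTF comparison panels

suppressPackageStartupMessages(library(iolbench))
args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
cfg <- if (!is.null(get_opt("--config")))
  read_bench_config(get_opt("--config")) else default_bench_config()
axis <- match.arg(get_opt("--axis", "both"), c("decenter", "tilt", "both"))
out <- get_opt("--out", "results/sweeps")
grid_n <- as.integer(get_opt("--grid", cfg$grid$n))

message("calibrating bench ...")
bench <- build_bench(cfg)
bench <- focus_bench(bench, samples = min(grid_n, 512))
results <- list()
if (axis %in% c("decenter", "both")) {
  message("decentration sweep ...")
  results <- c(results, list(run_decenter_sweep(bench, samples = grid_n)))
  print(results[[length(results)]])
}
if (axis %in% c("tilt", "both")) {
  message("tilt sweep ...")
  results <- c(results, list(run_tilt_sweep(bench, samples = grid_n)))
  print(results[[length(results)]])
}
paths <- render_report(results, out, mtf_panels = !("--no-mtf" %in% args),
                       samples = grid_n)
message("report written to ", out)
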