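#!/usr/bin/env Rscript

# Step 3 — error profiles and contour maps.
# Pure re-plotting of the CSV artifacts written by 02_run_experiments.R:
# per-site median percentage error against distance to the boundary, and
# contour maps of the same fields over the internal square with the cluster
# centers overlaid.

suppressMessages(library(edgebias))

profile_measures <- c("ci", "cp_total", "cp_nearest_3", "d_nearest")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

for (slug in c("urban", "non_urban")) {
  pl_path <- sprintf("results/%s_per_location.csv", slug)
  if (!file.exists(pl_path)) {
    stop("missing ", pl_path, " - run analysis/02_run_experiments.R first")
  }
  pl <- read.csv(pl_path)
  centers <- read.csv(sprintf("results/%s_centers.csv", slug))

  plot_error_profile(pl, measures = profile_measures,
                     path = sprintf("results/figures/%s_profiles.png", slug))
  for (meas in c("ci", "cp_total")) {
    plot_contour(pl, meas, centers = centers,
                 path = sprintf("results/figures/%s_contour_%s.png",
                                slug, meas))
  }
  message("figures written for ", slug)
}
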