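#' Run the Monte Carlo edge-bias experiment for one scenario
#'
#' Orchestrates the full design: cluster centers are drawn once and fixed,
#' the evaluation-site mesh is generated once and fixed, then `replicates`
#' independent outlet realisations are simulated by thinning and compared
#' full-window vs censored at every internal site. Per internal site and
#' measure, the median over replicates of the percentage error and of the
#' absolute bias is retained, and binned min/median/max summaries over sites
#' are tabulated by distance to the internal boundary.
#'
#' All randomness derives from `master_seed`: it seeds the center draw, any
#' mesh jitter, and a vector of per-replicate child seeds, so an identical
#' `master_seed` reproduces the result exactly. Replicate failures are
#' tolerated up to 1\% of `replicates`; beyond that the run aborts.
#'
#' @param scenario A [cluster_scenario()].
#' @param geometry A [study_geometry()] (default [study_geometry()]).
#' @param master_seed Integer seed for the whole run.
#' @param replicates Number of replicates (default: the scenario's).
#' @param jitter Jitter evaluation sites within their subcells
#'   (default `FALSE`: regular lattice).
#' @param k_nearest `k` values for `cp_nearest_k` (default `1:3`).
#' @param buffer_radius Optional radius adding a `cp_buffer` measure.
#' @param progress Print a replicate counter every 100 replicates.
#' @return An object of class `edge_bias_experiment`: a list with
#'   `scenario`, `geometry`, `points`, `centers`, `lambda_max`,
#'   `per_location` (site-level medians: `point_id`, `measure`,
#'   `med_pct_error`, `med_abs_bias`, `n_defined`, plus site coordinates,
#'   distance and bin), `bin_summary` (per bin and measure: min/med/max over
#'   sites of both median statistics), `replicates`, `failures`, and
#'   `seeds` (metadata: master and child seeds).
#' @export
run_experiment <- function(scenario, geometry = study_geometry(),
                           master_seed = 1L,
                           replicates = scenario$replicates,
                           jitter = FALSE, k_nearest = 1:3,
                           buffer_radius = NULL, progress = FALSE) {
  stopifnot(inherits(scenario, "cluster_scenario"),
            inherits(geometry, "study_geometry"), replicates >= 1)
  set.seed(master_seed)
  centers <- draw_cluster_centers(scenario$n_centers)
  points <- generate_location_points(geometry, jitter = jitter)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  lambda_max <- compute_lambda_max(points, centers, scenario$phi)

  internal_pts <- points[points$is_internal, , drop = FALSE]
  n_int <- nrow(internal_pts)
  measure_names <- c("ci", "sqrt_ci", "cp_total",
                     paste0("cp_nearest_", k_nearest),
                     if (!is.null(buffer_radius)) "cp_buffer",
                     "d_nearest")
  n_meas <- length(measure_names)

  pct <- array(NA_real_, c(n_int, n_meas, replicates))
  bia <- array(NA_real_, c(n_int, n_meas, replicates))
  failures <- 0L
  for (r in seq_len(replicates)) {
    rec <- tryCatch({
      outlets <- simulate_outlets(scenario, centers, lambda_max,
                                  seed = rep_seeds[r])
      bias_records_for_replicate(points, outlets, geometry,
                                 k_nearest, buffer_radius)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures <- failures + 1L
      if (failures > max(1L, floor(0.01 * replicates))) {
        stop(sprintf("more than 1%% of replicates failed (last error: %s)",
                     conditionMessage(rec)))
      }
      next
    }
    # rec is ordered site-major within measure blocks in measure_names order
    pct[, , r] <- matrix(rec$pct_error, n_int, n_meas)
    bia[, , r] <- matrix(rec$abs_bias, n_int, n_meas)
    if (progress && r %% 100L == 0L) {
      message(sprintf("  [%s] replicate %d/%d", scenario$label, r, replicates))
    }
  }

  med_pct <- apply(pct, c(1, 2), stats::median, na.rm = TRUE)
  med_bias <- apply(bia, c(1, 2), stats::median, na.rm = TRUE)
  n_defined <- apply(!is.na(pct), c(1, 2), sum)
  # sites where more than 5% of replicates were undefined are flagged missing
  ok <- n_defined >= 0.95 * (replicates - failures)
  med_pct[!ok] <- NA_real_
  med_bias[!ok] <- NA_real_

  per_location <- data.frame(
    point_id = rep(internal_pts$id, times = n_meas),
    x = rep(internal_pts$x, times = n_meas),
    y = rep(internal_pts$y, times = n_meas),
    dist_to_boundary = rep(internal_pts$dist_to_boundary, times = n_meas),
    dist_bin = rep(internal_pts$dist_bin, times = n_meas),
    measure = rep(measure_names, each = n_int),
    med_pct_error = as.vector(med_pct),
    med_abs_bias = as.vector(med_bias),
    n_defined = as.vector(n_defined)
  )

  structure(
    list(scenario = scenario, geometry = geometry, points = points,
         centers = centers, lambda_max = lambda_max,
         per_location = per_location,
         bin_summary = summarize_by_bin(per_location),
         replicates = replicates, failures = failures,
         seeds = list(master = master_seed, replicate = rep_seeds)),
    class = "edge_bias_experiment"
  )
}

#' @export
print.edge_bias_experiment <- function(x, ...) {
  cat(sprintf("Edge-bias experiment: scenario '%s', %d replicates (%d failed)\n",
              x$scenario$label, x$replicates, x$failures))
  cat(sprintf("  %d internal sites, lambda_max = %.3f\n",
              sum(x$points$is_internal), x$lambda_max))
  cat("  bin summary (median absolute bias):\n")
  print(utils::head(bias_table(x, statistic = "med_abs_bias"), 12), ...)
  invisible(x)
}

#' Binned min/median/max summaries of per-site medians
#'
#' Groups internal sites by distance-to-boundary bin and, for every bin and
#' measure, reports the minimum, median and maximum over sites of the
#' per-site median statistics. A bin with no sites would yield a flagged
#' empty row (`n_points = 0`, NA statistics) rather than being dropped.
#'
#' @param per_location Per-site medians, as in the `per_location` element of
#'   [run_experiment()].
#' @param bins Optional vector of bin midpoints to tabulate (default: all
#'   bins present in `per_location`).
#' @return A long data frame: `dist_bin`, `measure`, `stat`
#'   (`min`/`med`/`max`), `med_abs_bias`, `med_pct_error`, `n_points`.
#' @export
summarize_by_bin <- function(per_location, bins = NULL) {
  if (is.null(bins)) bins <- sort(unique(per_location$dist_bin))
  measures <- unique(per_location$measure)
  grid <- expand.grid(dist_bin = bins, measure = measures,
                      stat = c("min", "med", "max"),
                      stringsAsFactors = FALSE)
  fns <- list(min = function(v) min(v, na.rm = TRUE),
              med = function(v) stats::median(v, na.rm = TRUE),
              max = function(v) max(v, na.rm = TRUE))
  summ <- function(i) {
    rows <- per_location$dist_bin == grid$dist_bin[i] &
      per_location$measure == grid$measure[i]
    n <- sum(rows)
    if (n == 0L || all(is.na(per_location$med_abs_bias[rows]))) {
      return(c(NA_real_, NA_real_, n))
    }
    f <- fns[[grid$stat[i]]]
    c(f(per_location$med_abs_bias[rows]),
      f(per_location$med_pct_error[rows]), n)
  }
  vals <- t(vapply(seq_len(nrow(grid)), summ, numeric(3)))
  grid$med_abs_bias <- vals[, 1]
  grid$med_pct_error <- vals[, 2]
  grid$n_points <- as.integer(vals[, 3])
  grid[order(grid$dist_bin, grid$measure), ]
}

#' Bias summary in the wide table layout
#'
#' Reshapes the binned summary into the familiar reporting layout: one row
#' per (distance bin, statistic), one column per measure.
#'
#' @param experiment An `edge_bias_experiment`, or its `bin_summary`.
#' @param statistic `"med_abs_bias"` (default) or `"med_pct_error"`.
#' @return A wide data frame with columns `dist_bin`, `stat`, then one per
#'   measure.
#' @export
bias_table <- function(experiment, statistic = c("med_abs_bias",
                                                 "med_pct_error")) {
  statistic <- match.arg(statistic)
  bs <- if (inherits(experiment, "edge_bias_experiment")) {
    experiment$bin_summary
  } else {
    experiment
  }
  wide <- stats::reshape(
    bs[, c("dist_bin", "stat", "measure", statistic)],
    direction = "wide", idvar = c("dist_bin", "stat"),
    timevar = "measure")
  names(wide) <- sub(paste0("^", statistic, "\\."), "", names(wide))
  wide$stat <- factor(wide$stat, levels = c("min", "med", "max"))
  wide <- wide[order(wide$dist_bin, wide$stat), ]
  rownames(wide) <- NULL
  wide
}

#' Write experiment artifacts to a directory
#'
#' Saves the wide bias tables (absolute bias and percentage error), the raw
#' per-site medians, the evaluation sites, the cluster centers, and a JSON
#' metadata sidecar (scenario, geometry, seeds, failure count) so that all
#' plots can be regenerated without re-simulation.
#'
#' @param experiment An `edge_bias_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "edge_bias_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- gsub("[^a-z0-9]+", "_", tolower(experiment$scenario$label))
  utils::write.csv(bias_table(experiment, "med_abs_bias"),
                   file.path(dir, paste0(lab, "_abs_bias_table.csv")),
                   row.names = FALSE)
  utils::write.csv(bias_table(experiment, "med_pct_error"),
                   file.path(dir, paste0(lab, "_pct_error_table.csv")),
                   row.names = FALSE)
  utils::write.csv(experiment$per_location,
                   file.path(dir, paste0(lab, "_per_location.csv")),
                   row.names = FALSE)
  write_location_points(experiment$points,
                        file.path(dir, paste0(lab, "_points.csv")))
  utils::write.csv(experiment$centers,
                   file.path(dir, paste0(lab, "_centers.csv")),
                   row.names = FALSE)
  meta <- list(
    scenario = unclass(experiment$scenario),
    geometry = unclass(experiment$geometry),
    replicates = experiment$replicates,
    failures = experiment$failures,
    lambda_max = experiment$lambda_max,
    master_seed = experiment$seeds$master
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(meta, file.path(dir, paste0(lab, "_metadata.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
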