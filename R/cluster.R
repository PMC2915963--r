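#' Define a clustered-outlet simulation scenario
#'
#' A scenario fixes the number of outlets \eqn{N}, the number of cluster
#' centers \eqn{J}, the clustering parameter \eqn{\phi} (the variance of the
#' Gaussian dispersal kernel, in squared window units; smaller \eqn{\phi}
#' means tighter clustering), and the number of Monte Carlo replicates.
#'
#' @param label Scenario name, e.g. `"urban"` or `"non-urban"`.
#' @param n_outlets Number of outlets \eqn{N \ge 1} per realisation.
#' @param n_centers Number of cluster centers \eqn{J \ge 1}.
#' @param phi Clustering parameter \eqn{\phi > 0}.
#' @param replicates Number of Monte Carlo replicates (default 500).
#' @return An object of class `cluster_scenario`.
#' @export
cluster_scenario <- function(label, n_outlets, n_centers, phi,
                             replicates = 500L) {
  stopifnot(is.character(label), length(label) == 1L,
            n_outlets >= 1, n_centers >= 1, phi > 0, replicates >= 1)
  structure(
    list(label = label, n_outlets = as.integer(n_outlets),
         n_centers = as.integer(n_centers), phi = phi,
         replicates = as.integer(replicates)),
    class = "cluster_scenario"
  )
}

#' @export
print.cluster_scenario <- function(x, ...) {
  cat(sprintf("Cluster scenario '%s': %d outlets, %d centers, phi = %g, %d replicates\n",
              x$label, x$n_outlets, x$n_centers, x$phi, x$replicates))
  invisible(x)
}

#' The two study scenarios
#'
#' Urban: 2000 outlets around 15 centers with \eqn{\phi = 0.01}.
#' Non-urban: 300 outlets around 5 centers with tighter clustering,
#' \eqn{\phi = 0.005}. Both use 500 replicates.
#'
#' @return A named list with elements `urban` and `non-urban`.
#' @export
scenario_presets <- function() {
  list(
    "urban" = cluster_scenario("urban", 2000L, 15L, 0.01, 500L),
    "non-urban" = cluster_scenario("non-urban", 300L, 5L, 0.005, 500L)
  )
}

#' Draw cluster centers uniformly on the unit square
#'
#' Centers are drawn once per scenario and held fixed across all replicates,
#' so that error concentrations around centers persist in the mapped results.
#'
#' @param n_centers Number of centers \eqn{J \ge 1}.
#' @param seed Optional integer seed.
#' @return A data frame with columns `j` (1-based center index), `x`, `y`.
#' @export
draw_cluster_centers <- function(n_centers, seed = NULL) {
  stopifnot(n_centers >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(j = seq_len(n_centers),
             x = stats::runif(n_centers),
             y = stats::runif(n_centers))
}

#' Gaussian clustering kernel
#'
#' \eqn{h(d) = \exp(-d^2 / (2\phi))}: strictly decreasing in the distance
#' \eqn{d}, equal to 1 at the center, with \eqn{\phi} playing the role of the
#' dispersal variance. Any multiplicative normalisation would cancel in the
#' thinning ratio, so none is applied.
#'
#' @param d Nonnegative distances (vectorised).
#' @param phi Clustering parameter \eqn{\phi > 0}.
#' @return Weights in \eqn{(0, 1]}.
#' @export
clustering_kernel <- function(d, phi) {
  stopifnot(phi > 0, all(d >= 0))
  exp(-d^2 / (2 * phi))
}

#' Cluster intensity at arbitrary locations
#'
#' \eqn{\lambda(s) = \sum_j h(|s - x_j|; \phi)}, the sum of kernel weights
#' over all cluster centers; \eqn{|s - x_j|} is the Euclidean distance.
#'
#' @param x,y Coordinates (vectorised).
#' @param centers Data frame of centers from [draw_cluster_centers()].
#' @param phi Clustering parameter.
#' @return Nonnegative intensities, one per coordinate pair.
#' @export
cluster_intensity <- function(x, y, centers, phi) {
  stopifnot(phi > 0)
  d2 <- outer(x, centers$x, "-")^2 + outer(y, centers$y, "-")^2
  rowSums(exp(-d2 / (2 * phi)))
}

#' Grid maximum of the cluster intensity
#'
#' The thinning normaliser \eqn{\lambda_{max}} is the maximum of
#' \eqn{\lambda(s)} over the predefined evaluation sites, not the continuum
#' maximum; the acceptance ratio is therefore clipped at 1 during thinning.
#'
#' @param points Evaluation-site data frame from
#'   [generate_location_points()].
#' @param centers Cluster centers.
#' @param phi Clustering parameter.
#' @return A single nonnegative value.
#' @export
compute_lambda_max <- function(points, centers, phi) {
  stopifnot(nrow(points) >= 1)
  max(cluster_intensity(points$x, points$y, centers, phi))
}

#' Simulate one clustered outlet realisation by thinning
#'
#' Proposals \eqn{s^*} are drawn uniformly on the unit square and accepted
#' with probability \eqn{\min(1, \lambda(s^*)/\lambda_{max})}; the loop runs
#' until exactly \eqn{N} outlets are accepted. A proposal budget guards
#' against pathological parameter choices.
#'
#' @param scenario A [cluster_scenario()].
#' @param centers Cluster centers for the scenario.
#' @param lambda_max Thinning normaliser, from [compute_lambda_max()].
#' @param seed Optional integer seed.
#' @param max_proposals Proposal budget (default 1e6).
#' @return A data frame of outlet coordinates `x`, `y` with attributes
#'   `label` and `seed`.
#' @export
simulate_outlets <- function(scenario, centers, lambda_max, seed = NULL,
                             max_proposals = 1e6) {
  stopifnot(inherits(scenario, "cluster_scenario"), lambda_max > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_outlets
  ox <- numeric(0)
  oy <- numeric(0)
  proposed <- 0
  # draw in batches sized by the running acceptance rate
  batch <- max(1000L, 4L * n)
  while (length(ox) < n) {
    if (proposed >= max_proposals) {
      stop(sprintf(
        "proposal budget (%g) exceeded simulating scenario '%s'",
        max_proposals, scenario$label))
    }
    batch <- min(batch, max_proposals - proposed)
    px <- stats::runif(batch)
    py <- stats::runif(batch)
    u <- stats::runif(batch)
    ratio <- pmin(1, cluster_intensity(px, py, centers, scenario$phi) / lambda_max)
    keep <- u <= ratio
    ox <- c(ox, px[keep])
    oy <- c(oy, py[keep])
    proposed <- proposed + batch
  }
  out <- data.frame(x = ox[seq_len(n)], y = oy[seq_len(n)])
  attr(out, "label") <- scenario$label
  attr(out, "seed") <- seed
  out
}

#' Read an outlet point set from CSV
#'
#' Accepts any CSV with numeric `x` and `y` columns in window units, so the
#' measure and censoring machinery can be applied to user-supplied (e.g.
#' rescaled real) outlet coordinates as well as to simulated ones.
#'
#' @param path CSV file path.
#' @return A data frame with columns `x`, `y`.
#' @export
read_outlets_csv <- function(path) {
  out <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(out))) {
    stop("outlet CSV must have `x` and `y` columns")
  }
  out[, c("x", "y")]
}
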