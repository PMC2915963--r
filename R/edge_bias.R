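#' Restrict an outlet set to the internal area
#'
#' Edge censoring: retains outlets whose coordinates both lie in the closed
#' internal square \eqn{[\delta, 1-\delta]^2} (an outlet exactly on the
#' internal boundary is kept). Order and attributes are preserved;
#' \eqn{\delta = 0} is the identity.
#'
#' @param outlets Outlet data frame with `x`, `y`.
#' @param geometry A [study_geometry()].
#' @return The censored outlet data frame.
#' @export
censor_outlets <- function(outlets, geometry) {
  stopifnot(inherits(geometry, "study_geometry"))
  delta <- geometry$guard_inset
  keep <- outlets$x >= delta & outlets$x <= 1 - delta &
    outlets$y >= delta & outlets$y <= 1 - delta
  out <- outlets[keep, , drop = FALSE]
  attributes(out)[c("label", "seed")] <- attributes(outlets)[c("label", "seed")]
  out
}

#' Percentage error of a censored measure
#'
#' \eqn{100 \, |full - internal| / |full|}, the full-window value acting as
#' the gold standard. Both arguments zero gives 0; a zero full value with a
#' nonzero internal value is undefined and flagged `NA` (never silently
#' zeroed). Vectorised.
#'
#' @param full Measure computed on the full window.
#' @param internal Measure computed on the censored (internal-only) set.
#' @return Percentage errors (nonnegative, `NA` where undefined).
#' @export
percentage_error <- function(full, internal) {
  out <- 100 * abs(full - internal) / abs(full)
  out[which(full == 0 & internal == 0)] <- 0
  out[which(full == 0 & internal != 0)] <- NA_real_
  out
}

#' Absolute bias of a censored measure
#'
#' \eqn{|full - internal|}, in the measure's own units. Vectorised.
#'
#' @inheritParams percentage_error
#' @return Nonnegative absolute differences.
#' @export
absolute_bias <- function(full, internal) {
  abs(full - internal)
}

#' Full-vs-censored bias records for one outlet realisation
#'
#' For every internal evaluation site and every configured measure, computes
#' the measure twice — on the full outlet set and on the censored set (CI
#' then counts only internal outlets in the site's tract cell, so only cells
#' cut by the internal boundary can differ) — and returns one record per
#' (site, measure) with the percentage error and absolute bias.
#'
#' @param points Evaluation sites from [generate_location_points()].
#' @param outlets One outlet realisation.
#' @param geometry A [study_geometry()].
#' @param k_nearest Integer vector of `k` values for `cp_nearest_k`.
#' @param buffer_radius Optional radius adding a `cp_buffer` measure.
#' @return A long data frame: `point_id`, `measure`, `full`, `internal`,
#'   `pct_error`, `abs_bias`. Undefined values (e.g. nearest-based measures
#'   on an emptied censored set) propagate as `NA`.
#' @export
bias_records_for_replicate <- function(points, outlets, geometry,
                                       k_nearest = 1:3,
                                       buffer_radius = NULL) {
  stopifnot(inherits(geometry, "study_geometry"))
  internal_pts <- points[points$is_internal, , drop = FALSE]
  m <- geometry$tract_grid_dim
  pcell <- .cell_id(internal_pts$tract_row, internal_pts$tract_col, m)

  oc <- tract_cell_of(outlets$x, outlets$y, geometry)
  ocell <- .cell_id(oc$row, oc$col, m)
  D <- .dist_matrix(internal_pts$x, internal_pts$y, outlets$x, outlets$y)

  delta <- geometry$guard_inset
  keep <- outlets$x >= delta & outlets$x <= 1 - delta &
    outlets$y >= delta & outlets$y <= 1 - delta

  full <- .measures_from_dist(D, pcell, ocell, m, k_nearest, buffer_radius)
  internal <- .measures_from_dist(D[, keep, drop = FALSE], pcell,
                                  ocell[keep], m, k_nearest, buffer_radius)

  nm <- colnames(full)
  data.frame(
    point_id = rep(internal_pts$id, times = length(nm)),
    measure = rep(nm, each = nrow(internal_pts)),
    full = as.vector(full),
    internal = as.vector(internal),
    pct_error = percentage_error(as.vector(full), as.vector(internal)),
    abs_bias = absolute_bias(as.vector(full), as.vector(internal))
  )
}
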