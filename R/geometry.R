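#' Study geometry for the unit-square edge-effect design
#'
#' Defines the study window and every spatial convention the experiment relies
#' on: the unit square \eqn{[0,1]^2}, an \eqn{m \times m} tract grid used for
#' availability counts, a \eqn{p \times p} mesh of evaluation sites, an
#' internal guard inset \eqn{\delta}, and the width of the
#' distance-to-boundary bins used when summarising bias.
#'
#' The internal (reporting) area is the square \eqn{[\delta, 1-\delta]^2};
#' the strip between it and the window edge is the guard area whose outlets
#' are discarded under edge censoring. \eqn{\delta} must be an integer
#' multiple of \eqn{1/p} so the internal boundary coincides with mesh lines
#' and the number of internal evaluation sites is deterministic:
#' \eqn{(p - 2\delta p)^2}, i.e. 256 sites for the default
#' \eqn{p = 20, \delta = 0.1}.
#'
#' @param tract_grid_dim Integer \eqn{m \ge 1}: tract grid is \eqn{m \times m}
#'   (default 15, i.e. 225 cells).
#' @param point_mesh_dim Integer \eqn{p \ge 1}: evaluation mesh is
#'   \eqn{p \times p} (default 20, i.e. 400 sites).
#' @param guard_inset Guard width \eqn{\delta} in window units,
#'   \eqn{0 \le \delta < 0.5} and an integer multiple of \eqn{1/p}
#'   (default 0.1).
#' @param bin_width Width of the distance-to-boundary bins (default 0.05).
#' @return An object of class `study_geometry`.
#' @examples
#' geom <- study_geometry()
#' pts <- generate_location_points(geom)
#' sum(pts$is_internal)  # 256
#' @export
study_geometry <- function(tract_grid_dim = 15L, point_mesh_dim = 20L,
                           guard_inset = 0.1, bin_width = 0.05) {
  m <- as.integer(tract_grid_dim)
  p <- as.integer(point_mesh_dim)
  stopifnot(length(m) == 1L, length(p) == 1L, m >= 1L, p >= 1L,
            length(guard_inset) == 1L, is.finite(guard_inset),
            guard_inset >= 0, guard_inset < 0.5,
            length(bin_width) == 1L, bin_width > 0)
  # internal boundary must sit on mesh lines: delta = k/p for integer k
  k <- guard_inset * p
  if (abs(k - round(k)) > 1e-9) {
    stop("`guard_inset` must be an integer multiple of 1/point_mesh_dim")
  }
  structure(
    list(tract_grid_dim = m, point_mesh_dim = p,
         guard_inset = guard_inset, bin_width = bin_width),
    class = "study_geometry"
  )
}

#' @export
print.study_geometry <- function(x, ...) {
  cat("Unit-square study geometry\n")
  cat(sprintf("  tract grid: %d x %d cells\n",
              x$tract_grid_dim, x$tract_grid_dim))
  cat(sprintf("  point mesh: %d x %d sites\n",
              x$point_mesh_dim, x$point_mesh_dim))
  cat(sprintf("  guard inset: %.3f (internal area [%.3f, %.3f]^2)\n",
              x$guard_inset, x$guard_inset, 1 - x$guard_inset))
  cat(sprintf("  distance bin width: %.3f\n", x$bin_width))
  invisible(x)
}

#' Generate the evaluation-site mesh
#'
#' Places exactly one evaluation site in each subcell of the \eqn{p \times p}
#' mesh (stratified layout). With `jitter = TRUE` each site is drawn uniformly
#' within its subcell; with `jitter = FALSE` (default) sites sit at subcell
#' centers, giving a fixed regular lattice. Sites are generated once per
#' experiment and held fixed across all simulation replicates.
#'
#' @param geometry A [study_geometry()].
#' @param seed Optional integer seed used when `jitter = TRUE`.
#' @param jitter Logical; jitter sites uniformly within their subcells.
#' @return A data frame with one row per site: `id`, `x`, `y`, `subcell_row`,
#'   `subcell_col`, `tract_row`, `tract_col` (all 0-based indices),
#'   `is_internal`, `dist_to_boundary` (NA for guard-area sites) and
#'   `dist_bin` (bin midpoint; NA for guard-area sites).
#' @export
generate_location_points <- function(geometry, seed = NULL, jitter = FALSE) {
  stopifnot(inherits(geometry, "study_geometry"))
  p <- geometry$point_mesh_dim
  delta <- geometry$guard_inset
  grid <- expand.grid(subcell_col = 0:(p - 1), subcell_row = 0:(p - 1))
  w <- 1 / p
  if (jitter) {
    if (!is.null(seed)) set.seed(seed)
    x <- (grid$subcell_col + stats::runif(p * p)) * w
    y <- (grid$subcell_row + stats::runif(p * p)) * w
  } else {
    x <- (grid$subcell_col + 0.5) * w
    y <- (grid$subcell_row + 0.5) * w
  }
  cell <- tract_cell_of(x, y, geometry)
  is_internal <- x >= delta & x <= 1 - delta & y >= delta & y <= 1 - delta
  d <- rep(NA_real_, p * p)
  d[is_internal] <- distance_to_internal_boundary(x[is_internal],
                                                  y[is_internal], geometry)
  bin <- rep(NA_real_, p * p)
  bin[is_internal] <- assign_distance_bin(d[is_internal], geometry$bin_width)
  data.frame(
    id = seq_len(p * p),
    x = x, y = y,
    subcell_row = grid$subcell_row, subcell_col = grid$subcell_col,
    tract_row = cell$row, tract_col = cell$col,
    is_internal = is_internal,
    dist_to_boundary = d,
    dist_bin = bin
  )
}

#' Distance from an internal site to the internal boundary
#'
#' Euclidean distance to the nearest edge of the internal square
#' \eqn{[\delta, 1-\delta]^2}: `min(x - delta, 1 - delta - x, y - delta,
#' 1 - delta - y)`. Defined only for internal sites.
#'
#' @param x,y Coordinates (vectorised).
#' @param geometry A [study_geometry()].
#' @return Distances in window units, in \eqn{[0, 0.5 - \delta]}.
#' @export
distance_to_internal_boundary <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "study_geometry"))
  delta <- geometry$guard_inset
  if (any(x < delta | x > 1 - delta | y < delta | y > 1 - delta)) {
    stop("distance_to_internal_boundary() called on a guard-area point")
  }
  pmin(x - delta, 1 - delta - x, y - delta, 1 - delta - y)
}

#' Bin a distance-to-boundary value
#'
#' Half-open bins \eqn{[k w, (k+1) w)} labelled by their midpoint
#' \eqn{(k + 1/2) w}. With the defaults (`bin_width = 0.05`,
#' \eqn{\delta = 0.1}) the midpoints are 0.025, 0.075, ..., 0.375.
#'
#' @param d Nonnegative distances (vectorised).
#' @param bin_width Bin width \eqn{w > 0}.
#' @return Bin midpoints.
#' @export
assign_distance_bin <- function(d, bin_width) {
  stopifnot(bin_width > 0, all(d >= 0))
  (floor(d / bin_width) + 0.5) * bin_width
}

#' Tract cell containing a coordinate
#'
#' Cells are half-open, \eqn{[r/m, (r+1)/m) \times [c/m, (c+1)/m)}, 0-based,
#' closed at the top edge so that the coordinate 1.0 maps to cell
#' \eqn{m - 1}.
#'
#' @param x,y Coordinates in the unit square (vectorised).
#' @param geometry A [study_geometry()].
#' @return A data frame with columns `row` (from `y`) and `col` (from `x`).
#' @export
tract_cell_of <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "study_geometry"))
  if (any(x < 0 | x > 1 | y < 0 | y > 1)) {
    stop("coordinates outside the unit square")
  }
  m <- geometry$tract_grid_dim
  data.frame(
    row = pmin(as.integer(floor(y * m)), m - 1L),
    col = pmin(as.integer(floor(x * m)), m - 1L)
  )
}

# linear 0-based cell id (row-major) used internally for fast counting
.cell_id <- function(row, col, m) row * m + col

#' Write evaluation sites to CSV
#'
#' @param points Data frame from [generate_location_points()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_location_points <- function(points, path) {
  utils::write.csv(
    points[, c("id", "x", "y", "is_internal", "dist_to_boundary",
               "dist_bin", "tract_row", "tract_col")],
    path, row.names = FALSE)
  invisible(path)
}
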