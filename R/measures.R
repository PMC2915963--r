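#' Availability and accessibility measures
#'
#' @description
#' The package evaluates the measures most common in built-food-environment
#' studies, at an evaluation site \eqn{s} against an outlet point set:
#'
#' * **CI** — cumulative index, the count of outlets in the site's tract
#'   cell (the simulation's analog of a Census tract), and its
#'   variance-stabilised form \eqn{\sqrt{CI}}.
#' * **CP** — cumulative opportunity, the sum of reciprocal Euclidean
#'   distances \eqn{\sum_{j \in A} 1/d_{ij}} over outlets in a reference set
#'   \eqn{A}: all outlets (`cp_total`), the \eqn{k} nearest
#'   (`cp_nearest_k`), or outlets within a distance buffer (`cp_buffer`).
#'   Closer outlets contribute more opportunity; the measure grows with both
#'   proximity and outlet numbers.
#' * **D** — distance to the nearest outlet (`d_nearest`), a plain distance
#'   (not a reciprocal), so it is the one measure that *increases* under
#'   censoring.
#'
#' An outlet coincident with the site contributes an infinite reciprocal
#' distance; simulated configurations have zero probability of this, and the
#' value propagates as `Inf` if constructed deliberately.
#'
#' @name measures
NULL

# distance matrix between sites (rows) and outlets (columns)
.dist_matrix <- function(px, py, ox, oy) {
  sqrt(outer(px, ox, "-")^2 + outer(py, oy, "-")^2)
}

#' Outlet count in each site's tract cell (CI)
#'
#' @param points Evaluation sites (data frame with `x`, `y` or precomputed
#'   `tract_row`/`tract_col`).
#' @param outlets Outlet data frame with `x`, `y`.
#' @param geometry A [study_geometry()].
#' @return Integer vector of counts, one per site.
#' @export
ci_count <- function(points, outlets, geometry) {
  stopifnot(inherits(geometry, "study_geometry"))
  m <- geometry$tract_grid_dim
  if (is.null(points$tract_row)) {
    pc <- tract_cell_of(points$x, points$y, geometry)
  } else {
    pc <- points[, c("tract_row", "tract_col")]
    names(pc) <- c("row", "col")
  }
  if (nrow(outlets) == 0L) return(integer(nrow(points)))
  oc <- tract_cell_of(outlets$x, outlets$y, geometry)
  counts <- tabulate(.cell_id(oc$row, oc$col, m) + 1L, nbins = m * m)
  counts[.cell_id(pc$row, pc$col, m) + 1L]
}

#' Variance-stabilised outlet count
#'
#' @param n Nonnegative counts.
#' @return \eqn{\sqrt{n}}.
#' @export
sqrt_ci <- function(n) {
  stopifnot(all(n >= 0))
  sqrt(n)
}

#' k smallest site-to-outlet distances
#'
#' Euclidean distances from one site to its \eqn{k} nearest outlets, sorted
#' ascending; ties are broken by outlet index, so the result is
#' deterministic.
#'
#' @param x,y Site coordinates (scalars).
#' @param outlets Outlet data frame.
#' @param k Number of neighbours, \eqn{0 \le k \le} outlet count.
#' @return Numeric vector of length `k`.
#' @export
knn_distances <- function(x, y, outlets, k) {
  stopifnot(length(x) == 1L, length(y) == 1L, k >= 0)
  if (k == 0L) return(numeric(0))
  if (k > nrow(outlets)) {
    stop(sprintf("k = %d exceeds the number of outlets (%d)", k, nrow(outlets)))
  }
  d <- sqrt((x - outlets$x)^2 + (y - outlets$y)^2)
  # order() is stable, so equal distances resolve by outlet index
  d[order(d)[seq_len(k)]]
}

#' Cumulative opportunity over the k nearest outlets
#'
#' \eqn{\sum_{j=1}^{k} 1/d_{(j)}} with \eqn{d_{(1)} \le \dots \le d_{(k)}}
#' the ordered distances.
#'
#' @inheritParams knn_distances
#' @return A single value (reciprocal window units).
#' @export
cp_nearest_k <- function(x, y, outlets, k) {
  sum(1 / knn_distances(x, y, outlets, k))
}

#' Cumulative opportunity over every outlet
#'
#' \eqn{\sum_j 1/d_{ij}} over the whole outlet set. An empty outlet set gives
#' 0 with a warning (degenerate case).
#'
#' @inheritParams knn_distances
#' @return A single value.
#' @export
cp_total <- function(x, y, outlets) {
  if (nrow(outlets) == 0L) {
    warning("empty outlet set: cp_total defined as 0")
    return(0)
  }
  sum(1 / sqrt((x - outlets$x)^2 + (y - outlets$y)^2))
}

#' Cumulative opportunity within a distance buffer
#'
#' \eqn{\sum_{d_{ij} \le r} 1/d_{ij}}; a buffer of \eqn{\sqrt 2} or more
#' covers the whole window, recovering [cp_total()].
#'
#' @inheritParams knn_distances
#' @param radius Buffer radius \eqn{r > 0}.
#' @return A single value.
#' @export
cp_buffer <- function(x, y, outlets, radius) {
  stopifnot(radius > 0)
  if (nrow(outlets) == 0L) {
    warning("empty outlet set: cp_buffer defined as 0")
    return(0)
  }
  d <- sqrt((x - outlets$x)^2 + (y - outlets$y)^2)
  sum(1 / d[d <= radius])
}

#' Distance to the nearest outlet
#'
#' @inheritParams knn_distances
#' @return A single distance; `NA` (undefined, excluded from summaries) for
#'   an empty outlet set.
#' @export
d_nearest <- function(x, y, outlets) {
  if (nrow(outlets) == 0L) return(NA_real_)
  min(sqrt((x - outlets$x)^2 + (y - outlets$y)^2))
}

# workhorse: all measures for all sites from a precomputed distance matrix.
# D: sites x outlets; pcell/ocell: 0-based linear tract-cell ids.
# Returns a matrix sites x measures.
.measures_from_dist <- function(D, pcell, ocell, m, k_nearest = 1:3,
                                buffer_radius = NULL) {
  n_pts <- nrow(D)
  n_out <- ncol(D)
  k_max <- if (length(k_nearest)) max(k_nearest) else 0L
  nm <- c("ci", "sqrt_ci", "cp_total",
          if (length(k_nearest)) paste0("cp_nearest_", k_nearest),
          if (!is.null(buffer_radius)) "cp_buffer",
          "d_nearest")
  res <- matrix(NA_real_, n_pts, length(nm), dimnames = list(NULL, nm))
  if (n_out == 0L) {
    res[, "ci"] <- 0
    res[, "sqrt_ci"] <- 0
    res[, "cp_total"] <- 0
    if (!is.null(buffer_radius)) res[, "cp_buffer"] <- 0
    return(res)  # nearest-based measures undefined
  }
  counts <- tabulate(ocell + 1L, nbins = m * m)
  res[, "ci"] <- counts[pcell + 1L]
  res[, "sqrt_ci"] <- sqrt(res[, "ci"])
  R <- 1 / D
  res[, "cp_total"] <- rowSums(R)
  if (!is.null(buffer_radius)) {
    res[, "cp_buffer"] <- rowSums(R * (D <= buffer_radius))
  }
  k_eff <- min(k_max, n_out)
  if (k_eff > 0L) {
    ks <- k_nearest[k_nearest <= n_out]
    for (i in seq_len(n_pts)) {
      di <- sort.int(D[i, ], partial = seq_len(k_eff))[seq_len(k_eff)]
      cum <- cumsum(1 / di)
      if (length(ks)) res[i, paste0("cp_nearest_", ks)] <- cum[ks]
      res[i, "d_nearest"] <- di[1L]
    }
  } else {
    res[, "d_nearest"] <- apply(D, 1L, min)
  }
  res
}

#' Compute every configured measure at every site
#'
#' One vectorised pass over a site-by-outlet distance matrix; agrees
#' field-by-field with the individual measure functions and is deterministic
#' given its inputs.
#'
#' @param points Evaluation sites from [generate_location_points()] (any
#'   data frame with `x`, `y` works; tract cells are derived if absent).
#' @param outlets Outlet data frame.
#' @param geometry A [study_geometry()].
#' @param k_nearest Integer vector of `k` values for `cp_nearest_k`
#'   (default `1:3`).
#' @param buffer_radius Optional radius for `cp_buffer`.
#' @return A data frame: `point_id` followed by one column per measure.
#'   Nearest-based measures are `NA` when the outlet set is smaller than
#'   `max(k_nearest)` (or empty).
#' @export
measure_all <- function(points, outlets, geometry, k_nearest = 1:3,
                        buffer_radius = NULL) {
  stopifnot(inherits(geometry, "study_geometry"))
  m <- geometry$tract_grid_dim
  if (is.null(points$tract_row)) {
    pc <- tract_cell_of(points$x, points$y, geometry)
    pcell <- .cell_id(pc$row, pc$col, m)
  } else {
    pcell <- .cell_id(points$tract_row, points$tract_col, m)
  }
  if (nrow(outlets) > 0L) {
    oc <- tract_cell_of(outlets$x, outlets$y, geometry)
    ocell <- .cell_id(oc$row, oc$col, m)
    D <- .dist_matrix(points$x, points$y, outlets$x, outlets$y)
  } else {
    ocell <- integer(0)
    D <- matrix(numeric(0), nrow(points), 0L)
  }
  res <- .measures_from_dist(D, pcell, ocell, m, k_nearest, buffer_radius)
  id <- if (!is.null(points$id)) points$id else seq_len(nrow(points))
  cbind(data.frame(point_id = id), as.data.frame(res))
}
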