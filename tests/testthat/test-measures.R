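geom <- study_geometry()

test_that("k nearest distances match the brute-force sort", {
  for (s in 1:5) {
    outlets <- random_outlets(20, seed = 100 + s)
    set.seed(200 + s)
    x <- runif(1); y <- runif(1)
    oracle <- oracle_sorted_distances(x, y, outlets)
    for (k in c(1L, 3L, 7L, 20L)) {
      expect_equal(knn_distances(x, y, outlets, k), oracle[seq_len(k)])
    }
  }
  expect_equal(knn_distances(0.5, 0.5, random_outlets(5, 1), 0), numeric(0))
  expect_error(knn_distances(0.5, 0.5, random_outlets(5, 1), 6), "exceeds")
})

test_that("nearest-neighbour ties resolve by outlet index", {
  outlets <- data.frame(x = c(0.25, 0.75, 0.25), y = c(0.5, 0.5, 0.5))
  # outlets 1 and 3 are equidistant duplicates; stable order keeps index order
  d <- knn_distances(0.5, 0.5, outlets, 3)
  expect_equal(d, c(0.25, 0.25, 0.25))
})

test_that("cumulative opportunity sums reciprocal distances", {
  for (s in 1:5) {
    outlets <- random_outlets(20, seed = 300 + s)
    set.seed(400 + s)
    x <- runif(1); y <- runif(1)
    expect_equal(cp_total(x, y, outlets), oracle_cp_total(x, y, outlets))
    # monotone in k and capped by the full sum
    cps <- vapply(1:20, function(k) cp_nearest_k(x, y, outlets, k), numeric(1))
    expect_true(all(diff(cps) > 0))
    expect_equal(cps[20], cp_total(x, y, outlets))
    # buffers: nested radii are monotone, sqrt(2) covers the window
    expect_equal(cp_buffer(x, y, outlets, sqrt(2)), cp_total(x, y, outlets))
    expect_lte(cp_buffer(x, y, outlets, 0.2), cp_buffer(x, y, outlets, 0.5))
  }
})

test_that("a buffer smaller than the nearest distance is empty", {
  outlets <- data.frame(x = 0.9, y = 0.9)
  expect_equal(cp_buffer(0.1, 0.1, outlets, 0.2), 0)
})

test_that("distance to nearest outlet is the first order statistic", {
  for (s in 1:3) {
    outlets <- random_outlets(20, seed = 500 + s)
    set.seed(600 + s)
    x <- runif(1); y <- runif(1)
    expect_equal(d_nearest(x, y, outlets),
                 oracle_sorted_distances(x, y, outlets)[1])
  }
  outlets <- data.frame(x = 0.3, y = 0.3)
  expect_equal(d_nearest(0.3, 0.3, outlets), 0)
  expect_true(is.na(d_nearest(0.5, 0.5, outlets[0, ])))
})

test_that("all pairwise distances live on the unit square scale", {
  outlets <- random_outlets(50, seed = 7)
  pts <- generate_location_points(geom, seed = 8, jitter = TRUE)
  D <- edgebias:::.dist_matrix(pts$x, pts$y, outlets$x, outlets$y)
  expect_true(all(D >= 0 & D <= sqrt(2)))
})

test_that("tract-cell counts conserve the outlet total", {
  outlets <- random_outlets(200, seed = 9)
  m <- geom$tract_grid_dim
  # one representative site per tract cell
  reps <- expand.grid(x = (seq_len(m) - 0.5) / m, y = (seq_len(m) - 0.5) / m)
  expect_equal(sum(ci_count(reps, outlets, geom)), 200L)
  expect_equal(ci_count(reps, outlets[0, ], geom), integer(m * m))
})

test_that("counting outlets in a known cell", {
  # 3 outlets in the site's cell, 5 elsewhere
  inside <- data.frame(x = c(0.51, 0.49, 0.50), y = c(0.50, 0.52, 0.48))
  outside <- data.frame(x = rep(0.9, 5), y = rep(0.9, 5))
  outlets <- rbind(inside, outside)
  expect_equal(ci_count(data.frame(x = 0.5, y = 0.5), outlets, geom), 3L)
  expect_equal(ci_count(data.frame(x = 0.1, y = 0.1), outlets, geom), 0L)
  expect_equal(sqrt_ci(4), 2)
  expect_equal(sqrt_ci(0), 0)
})

test_that("measure_all agrees field-by-field with the single-site functions", {
  outlets <- random_outlets(30, seed = 11)
  pts <- generate_location_points(geom, seed = 12, jitter = TRUE)[1:25, ]
  all_m <- measure_all(pts, outlets, geom, k_nearest = 1:3,
                       buffer_radius = 0.3)
  for (i in c(1, 10, 25)) {
    x <- pts$x[i]; y <- pts$y[i]
    expect_equal(all_m$ci[i], ci_count(pts[i, ], outlets, geom))
    expect_equal(all_m$sqrt_ci[i], sqrt(all_m$ci[i]))
    expect_equal(all_m$cp_total[i], cp_total(x, y, outlets))
    for (k in 1:3) {
      expect_equal(all_m[[paste0("cp_nearest_", k)]][i],
                   cp_nearest_k(x, y, outlets, k))
    }
    expect_equal(all_m$cp_buffer[i], cp_buffer(x, y, outlets, 0.3))
    expect_equal(all_m$d_nearest[i], d_nearest(x, y, outlets))
  }
})

test_that("measure_all handles degenerate outlet sets", {
  pts <- data.frame(x = c(0.2, 0.6), y = c(0.2, 0.6))
  # empty set: counts and cumulative sums 0, nearest-based measures undefined
  empty <- measure_all(pts, data.frame(x = numeric(0), y = numeric(0)), geom)
  expect_equal(empty$ci, c(0, 0))
  expect_equal(empty$cp_total, c(0, 0))
  expect_true(all(is.na(empty$d_nearest)))
  expect_true(all(is.na(empty$cp_nearest_3)))
  # one outlet: every CP-family value collapses to the single reciprocal
  one <- data.frame(x = 0.2, y = 0.45)
  m1 <- measure_all(pts[1, ], one, geom, k_nearest = 1L)
  expect_equal(m1$cp_total, 1 / 0.25)
  expect_equal(m1$cp_nearest_1, 1 / 0.25)
  expect_equal(m1$d_nearest, 0.25)
  expect_true(m1$ci %in% c(0, 1))
})

test_that("urban-scale inputs complete in one pass", {
  outlets <- random_outlets(2000, seed = 13)
  pts <- generate_location_points(geom)
  res <- measure_all(pts, outlets, geom)
  expect_equal(nrow(res), 400L)
  expect_false(anyNA(res))
})

test_that("deleting an outlet moves every measure the right way", {
  outlets <- random_outlets(25, seed = 14)
  set.seed(15)
  x <- runif(1); y <- runif(1)
  full_d <- d_nearest(x, y, outlets)
  full_cp <- cp_total(x, y, outlets)
  full_cb <- cp_buffer(x, y, outlets, 0.4)
  full_ci <- ci_count(data.frame(x = x, y = y), outlets, geom)
  for (j in c(1, 13, 25)) {
    rest <- outlets[-j, ]
    expect_gte(d_nearest(x, y, rest), full_d)
    expect_lte(cp_total(x, y, rest), full_cp)
    expect_lte(cp_buffer(x, y, rest, 0.4), full_cb)
    expect_lte(ci_count(data.frame(x = x, y = y), rest, geom), full_ci)
  }
})
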