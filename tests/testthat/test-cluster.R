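test_that("scenario presets match the two study settings", {
  pre <- scenario_presets()
  expect_equal(pre$urban$n_outlets, 2000L)
  expect_equal(pre$urban$n_centers, 15L)
  expect_equal(pre$urban$phi, 0.01)
  expect_equal(pre[["non-urban"]]$n_outlets, 300L)
  expect_equal(pre[["non-urban"]]$n_centers, 5L)
  expect_equal(pre[["non-urban"]]$phi, 0.005)
  expect_equal(pre$urban$replicates, 500L)
  expect_equal(pre[["non-urban"]]$replicates, 500L)
})

test_that("cluster centers are uniform draws inside the window", {
  expect_error(draw_cluster_centers(0))
  c5 <- draw_cluster_centers(5, seed = 9)
  expect_equal(nrow(c5), 5L)
  c15 <- draw_cluster_centers(15, seed = 9)
  expect_equal(nrow(c15), 15L)
  expect_true(all(c15$x >= 0 & c15$x <= 1 & c15$y >= 0 & c15$y <= 1))
  expect_identical(draw_cluster_centers(8, seed = 4),
                   draw_cluster_centers(8, seed = 4))
})

test_that("clustering kernel is a unit-peak Gaussian in the distance", {
  expect_equal(clustering_kernel(0, 0.01), 1)
  expect_equal(clustering_kernel(0, 0.005), 1)
  # closed form at d = sqrt(2 * phi): weight e^-1
  expect_equal(clustering_kernel(sqrt(2 * 0.01), 0.01), exp(-1))
  # smaller phi clusters tighter: lower weight at any positive distance
  d <- c(0.01, 0.05, 0.2, 1)
  expect_true(all(clustering_kernel(d, 0.005) < clustering_kernel(d, 0.01)))
  # strictly decreasing in d
  dd <- seq(0, 1, by = 0.01)
  expect_true(all(diff(clustering_kernel(dd, 0.005)) < 0))
  expect_error(clustering_kernel(0.1, 0))
})

test_that("intensity sums kernel weights over centers", {
  one <- data.frame(j = 1L, x = 0.3, y = 0.7)
  expect_equal(cluster_intensity(0.3, 0.7, one, 0.01), 1)
  two <- data.frame(j = 1:2, x = c(0.3, 0.3), y = c(0.7, 0.7))
  expect_equal(cluster_intensity(0.3, 0.7, two, 0.01), 2)
  # far from every center the intensity decays to ~0
  expect_lt(cluster_intensity(0.99, 0.01, one, 0.001), 1e-10)
})

test_that("lambda_max is the evaluation-grid maximum", {
  geom <- study_geometry()
  pts <- generate_location_points(geom)
  centers <- draw_cluster_centers(15, seed = 3)
  lm <- compute_lambda_max(pts, centers, 0.01)
  expect_lte(lm, 15)
  expect_true(all(cluster_intensity(pts$x, pts$y, centers, 0.01) <= lm))
  # a center sitting exactly on an evaluation site pins the maximum near 1
  at_site <- data.frame(j = 1L, x = pts$x[1], y = pts$y[1])
  expect_gte(compute_lambda_max(pts, at_site, 1e-4), 1)
})

test_that("thinning returns exactly N in-window outlets, reproducibly", {
  geom <- study_geometry()
  pts <- generate_location_points(geom)
  pre <- scenario_presets()
  centers <- draw_cluster_centers(5, seed = 21)
  lm <- compute_lambda_max(pts, centers, 0.005)
  out <- simulate_outlets(pre[["non-urban"]], centers, lm, seed = 31)
  expect_equal(nrow(out), 300L)
  expect_true(all(out$x >= 0 & out$x <= 1 & out$y >= 0 & out$y <= 1))
  expect_identical(out, simulate_outlets(pre[["non-urban"]], centers, lm, seed = 31))
})

test_that("thinning a flat intensity yields a uniform pattern", {
  # one center with enormous dispersal: the intensity is constant to ~1e-5,
  # so accepted points must be indistinguishable from uniform
  sc <- cluster_scenario("flat", 2000L, 1L, 100, 1L)
  centers <- data.frame(j = 1L, x = 0.5, y = 0.5)
  out <- simulate_outlets(sc, centers, lambda_max = 1, seed = 17)
  quad <- table(out$x > 0.5, out$y > 0.5)
  p <- chisq.test(as.vector(quad))$p.value
  expect_gt(p, 0.001)
})

test_that("thinned single-cluster outlets match direct kernel sampling", {
  # oracle: sample the dispersal kernel directly (bivariate normal around the
  # center, rejected to the window) and compare mean distances to the center
  phi <- 0.005
  n <- 10000L
  center <- data.frame(j = 1L, x = 0.5, y = 0.5)
  sc <- cluster_scenario("one", n, 1L, phi, 1L)
  geom <- study_geometry()
  lm <- compute_lambda_max(generate_location_points(geom), center, phi)
  out <- simulate_outlets(sc, center, lm, seed = 5, max_proposals = 5e6)
  d_thin <- sqrt((out$x - 0.5)^2 + (out$y - 0.5)^2)

  set.seed(105)
  ox <- rnorm(3 * n, 0.5, sqrt(phi))
  oy <- rnorm(3 * n, 0.5, sqrt(phi))
  keep <- ox >= 0 & ox <= 1 & oy >= 0 & oy <= 1
  d_oracle <- sqrt((ox[keep] - 0.5)^2 + (oy[keep] - 0.5)^2)[seq_len(n)]

  se <- sqrt(var(d_thin) / n + var(d_oracle) / n)
  expect_lt(abs(mean(d_thin) - mean(d_oracle)), 3 * se)
  # and both agree with the Rayleigh mean sigma * sqrt(pi/2)
  expect_lt(abs(mean(d_thin) - sqrt(phi) * sqrt(pi / 2)), 4 * sd(d_thin) / sqrt(n))
})

test_that("acceptance is monotone in the intensity", {
  # empirical acceptance near a center exceeds acceptance far away
  phi <- 0.005
  center <- data.frame(j = 1L, x = 0.25, y = 0.25)
  sc <- cluster_scenario("one", 2000L, 1L, phi, 1L)
  out <- simulate_outlets(sc, center, lambda_max = 1, seed = 8)
  near <- sum(sqrt((out$x - 0.25)^2 + (out$y - 0.25)^2) < 0.1)
  far <- sum(sqrt((out$x - 0.75)^2 + (out$y - 0.75)^2) < 0.1)
  expect_gt(near, far)
})

test_that("the proposal budget guards pathological parameters", {
  # a center far outside any realistic reach of the window would accept
  # almost nothing; the budget must trip with the scenario named
  sc <- cluster_scenario("needle", 100L, 1L, 1e-8, 1L)
  centers <- data.frame(j = 1L, x = 0.5, y = 0.5)
  expect_error(
    simulate_outlets(sc, centers, lambda_max = 1, seed = 1,
                     max_proposals = 2000),
    "needle")
})
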