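# Shared fixture builders: everything is generated in code at test time.

# a reproducible random outlet set on the unit square
random_outlets <- function(n, seed) {
  set.seed(seed)
  data.frame(x = runif(n), y = runif(n))
}

# brute-force oracle: all site-to-outlet distances, fully sorted
oracle_sorted_distances <- function(x, y, outlets) {
  d <- numeric(nrow(outlets))
  for (j in seq_len(nrow(outlets))) {
    d[j] <- sqrt((x - outlets$x[j])^2 + (y - outlets$y[j])^2)
  }
  sort(d)
}

# brute-force oracle: inverse-distance accumulation by explicit loop
oracle_cp_total <- function(x, y, outlets) {
  acc <- 0
  for (j in seq_len(nrow(outlets))) {
    acc <- acc + 1 / sqrt((x - outlets$x[j])^2 + (y - outlets$y[j])^2)
  }
  acc
}

# a tiny scenario for fast end-to-end runs
tiny_scenario <- function(n_outlets = 40L, n_centers = 3L, phi = 0.01,
                          replicates = 3L) {
  cluster_scenario("tiny", n_outlets, n_centers, phi, replicates)
}
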