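# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

# coarse icosahedral grid (f = 3, 92 cells) used across modules
test_grid <- function() {
  if (is.null(.fixtures$grid)) {
    .fixtures$grid <- build_grid(grid_spec(2000, subdivision_frequency = 3))
  }
  .fixtures$grid
}

# finer grid (f = 6, 362 cells) for world-scale tests
test_grid_fine <- function() {
  if (is.null(.fixtures$grid6)) {
    .fixtures$grid6 <- build_grid(grid_spec(1500, subdivision_frequency = 6))
  }
  .fixtures$grid6
}

# moderate synthetic world shared by pipeline tests
test_world <- function() {
  if (is.null(.fixtures$world)) {
    .fixtures$world <- generate_world(
      world_config(seed = 42, n_languages = 300, n_features_binary = 3,
                   n_features_categorical = 1, categorical_states = 4,
                   n_populations = 60, n_snps = 800),
      test_grid_fine())
  }
  .fixtures$world
}

# great-circle distance oracle (spherical law of cosines, independent of the
# package's chord-based implementation)
gc_dist_oracle <- function(lon1, lat1, lon2, lat2, radius = 6371.0072) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  radius * acos(pmin(1, pmax(-1, d)))
}

# brute-force shortest-window HPDI oracle
hpdi_bruteforce <- function(draws, mass = 0.89) {
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - k)) {
    w <- x[i + k] - x[i]
    if (w < best[1]) best <- c(w, x[i], x[i + k])
  }
  best[2:3]
}

# direct normalized-entropy oracle (plain loop over the formula,
# independent of the package's vectorized implementation)
entropy_oracle <- function(p, J = length(p)) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s / log(J)
}

random_simplex <- function(J) {
  e <- stats::rexp(J)
  e / sum(e)
}
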