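# Sample tibbles with constant ("flat") feature values per class: every band
# value is mu + N(0, sd), clipped to the physical range. Useful for building
# perfectly separable or hand-controlled inputs.
flat_samples <- function(labels, mus, n_each, sd = 0, seed = 1) {
  stopifnot(length(labels) == length(mus))
  set.seed(seed)
  rows <- purrr::map2_dfr(labels, mus, function(lab, mu) {
    vals <- matrix(pmin(pmax(stats::rnorm(n_each * 92, mu, sd), -1), 1),
                   n_each, 92)
    colnames(vals) <- paste0(
      rep(c("ndvi", "evi", "nir", "mir"), each = 23), "_", rep(1:23, 4))
    dplyr::bind_cols(
      tibble::tibble(longitude = 0, latitude = 0,
                     start_date = as.Date("2014-09-01"),
                     end_date = as.Date("2015-08-31"), label = lab),
      tibble::as_tibble(vals)
    )
  })
  validate_samples(rows)
}

# A probability cube with a single dominant class everywhere.
uniform_prob_cube <- function(h, w, k, dominant, p = 0.9, year = 2015,
                              labels = training_classes()[seq_len(k)]) {
  a <- array((1 - p) / (k - 1), dim = c(h, w, k))
  a[, , dominant] <- p
  prob_cube(a, year, labels)
}

# A random valid probability cube (Dirichlet-ish via normalized gammas).
random_prob_cube <- function(h, w, k, seed, year = 2015) {
  set.seed(seed)
  g <- array(stats::rgamma(h * w * k, shape = 1), dim = c(h, w, k))
  tot <- array(rep(apply(g, c(1, 2), sum), k), dim = c(h, w, k))
  prob_cube(g / tot, year, training_classes()[seq_len(k)])
}

# Strip everything but dims, for raster comparisons.
bare <- function(x) array(as.vector(x), dim = dim(x))

# Count local maxima of a discrete curve above a floor value.
n_local_maxima_above <- function(y, floor) {
  n <- length(y)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) y[i - 1] else -Inf
    right <- if (i < n) y[i + 1] else -Inf
    y[i] > left && y[i] > right
  }, logical(1))
  sum(is_max & y > floor)
}

# Trajectory codes from letters, for rule-engine tests.
codes_from_letters <- function(letters) {
  map <- c(F = "forest", C = "cerrado", P = "pasture", S = "soy-corn",
           SV = "secondary-vegetation")
  class_code(unname(map[letters]))
}
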