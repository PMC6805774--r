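# Small geometric phantoms used across the suite (built in code, no fixtures).

ball_mask <- function(r, pad = 4, spacing = c(1, 1, 1)) {
  n <- 2 * r + 1 + 2 * pad
  c0 <- (n - 1) / 2
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  a <- array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2, c(n, n, n))
  roi_mask(a, spacing)
}

cube_mask <- function(s, pad = 4, spacing = c(1, 1, 1)) {
  n <- s + 2 * pad
  a <- array(FALSE, c(n, n, n))
  a[pad + (1:s), pad + (1:s), pad + (1:s)] <- TRUE
  roi_mask(a, spacing)
}

ellipsoid_mask <- function(semi, pad = 4, spacing = c(1, 1, 1)) {
  n <- 2 * semi + 1 + 2 * pad
  ctr <- (n - 1) / 2
  g <- expand.grid(x = 0:(n[1] - 1), y = 0:(n[2] - 1), z = 0:(n[3] - 1))
  a <- array(((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
               ((g$z - ctr[3]) / semi[3])^2 <= 1, n)
  roi_mask(a, spacing)
}

# random discrete-level array with an embedded ROI, for texture oracles
random_levels <- function(dims, ng, seed, roi_frac = 1) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  if (roi_frac < 1) {
    drop <- sample(prod(dims), round((1 - roi_frac) * prod(dims)))
    lev[drop] <- NA_integer_
  }
  lev
}

# one small preprocessed synthetic patient (cached per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_patients = 6, prevalence = 1 / 3, n_train = 4,
                          n_test = 2, image_shape = c(48, 48, 16), seed = 7)
      cache <<- generate_cohort(spec)
    }
    cache
  }
})
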