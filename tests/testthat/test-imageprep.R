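test_that("resampling is the identity on an already-isotropic grid", {
  img <- image_volume(array(stats::rnorm(8 * 8 * 8), c(8, 8, 8)), c(1, 1, 1))
  out <- resample_isotropic(img, NULL, prep_config())
  expect_identical(out$image$data, img$data)
})

test_that("resampling a constant stays constant and a ramp stays linear", {
  cfg <- prep_config()
  const <- image_volume(array(7, c(10, 10, 6)), c(0.5, 0.5, 3.0))
  out <- resample_isotropic(const, NULL, cfg)
  expect_equal(dim(out$image$data), c(5, 5, 18))
  expect_true(all(abs(out$image$data - 7) < 1e-12))
  expect_equal(out$image$spacing, c(1, 1, 1))
  # physical extent preserved within one voxel
  expect_lt(abs(prod(dim(out$image$data)) - prod(c(10, 10, 6) * c(.5, .5, 3))),
            prod(dim(out$image$data)) * 0.2 + 1)

  # f(z) = z in mm: trilinear interpolation reproduces a linear field
  nz <- 10
  zmm <- (0:(nz - 1)) * 3
  ramp <- image_volume(array(rep(zmm, each = 16), c(4, 4, nz)),
                       c(0.5, 0.5, 3.0))
  out <- resample_isotropic(ramp, NULL, cfg)
  zq <- ramp$origin[3] - 1.5 + 0.5 + (seq_len(dim(out$image$data)[3]) - 1)
  expected <- pmin(pmax(zq, 0), max(zmm))  # clamped at the input's edges
  expect_equal(out$image$data[2, 2, ], expected, tolerance = 1e-12)
})

test_that("mask resampling is nearest-neighbour and preserves volume", {
  m <- ellipsoid_mask(c(6, 6, 2), pad = 3, spacing = c(0.5, 0.5, 3.0))
  img <- image_volume(array(0, dim(m$data)), c(0.5, 0.5, 3.0))
  out <- resample_isotropic(img, m, prep_config())
  expect_type(out$mask$data, "logical")
  vol_in <- mask_size(m) * prod(m$spacing)
  vol_out <- mask_size(out$mask) * 1
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.15)
})

test_that("missing spacing is rejected", {
  expect_error(image_volume(array(0, c(4, 4, 4)), c(1, 0, 1)), "positive")
})

test_that("bias correction leaves clean images alone and removes shading", {
  flat <- image_volume(array(100, c(16, 16, 12)), c(1, 1, 1))
  out <- correct_bias_field(flat)
  expect_equal(out$data, flat$data, tolerance = 0.01)

  # phantom x smooth low-order multiplicative field
  set.seed(1)
  d <- c(24, 24, 16)
  clean <- array(100 + stats::rnorm(prod(d), 0, 2), d)
  xs <- seq(-1, 1, length.out = d[1])
  field <- exp(outer(outer(0.3 * xs, 0.2 * seq(-1, 1, length.out = d[2]), "+"),
                     0.25 * seq(-1, 1, length.out = d[3]), "+"))
  img <- image_volume(clean * field, c(1, 1, 1))
  corr <- correct_bias_field(img)
  roi <- array(TRUE, d)
  cv <- function(a) stats::sd(a[roi]) / mean(a[roi])
  expect_lt(cv(corr$data), cv(img$data))
  # mean preserved
  expect_lt(abs(mean(corr$data) - mean(img$data)) / mean(img$data), 0.05)
  # approximate idempotence: second pass changes much less than the first
  corr2 <- correct_bias_field(corr)
  l2 <- function(a, b) sqrt(sum((a - b)^2))
  expect_lt(l2(corr2$data, corr$data), l2(corr$data, img$data))
  expect_error(correct_bias_field(
    image_volume(array(c(NA, rep(1, 7)), c(2, 2, 2)), c(1, 1, 1))),
    "finite")
})

test_that("reference normalization maps to mean 0 / SD scale and is affine invariant", {
  set.seed(2)
  d <- c(12, 12, 8)
  img <- image_volume(array(stats::rnorm(prod(d), 50, 12), d), c(1, 1, 1))
  ref <- array(FALSE, d); ref[2:5, 2:5, 2:4] <- TRUE
  ref <- roi_mask(ref, c(1, 1, 1), role = "reference")
  cfg <- prep_config()
  out <- normalize_by_reference(img, ref, cfg)
  v <- out$data[ref$data]
  expect_equal(mean(v), 0, tolerance = 1e-10)
  expect_equal(stats::sd(v), 100, tolerance = 1e-8)
  # a voxel at mu_ref maps to 0, at mu_ref + 2 sd_ref maps to 200
  mu <- mean(img$data[ref$data]); sd_ <- stats::sd(img$data[ref$data])
  probe <- img
  probe$data[1, 1, 1] <- mu
  probe$data[1, 1, 2] <- mu + 2 * sd_
  po <- normalize_by_reference(probe, ref, cfg)
  expect_equal(po$data[1, 1, 1], 0, tolerance = 1e-8)
  expect_equal(po$data[1, 1, 2], 200, tolerance = 1e-8)
  # invariance to affine rescaling a*I + b
  scaled <- image_volume(3.7 * img$data + 11, c(1, 1, 1))
  so <- normalize_by_reference(scaled, ref, cfg)
  expect_equal(so$data, out$data, tolerance = 1e-9)
  # errors
  empty <- roi_mask(array(FALSE, d), c(1, 1, 1))
  expect_error(normalize_by_reference(img, empty, cfg), "empty")
  flat <- image_volume(array(5, d), c(1, 1, 1))
  expect_error(normalize_by_reference(flat, ref, cfg), "zero variance")
})

test_that("discretization follows the fixed-bin-width formula", {
  d <- c(2, 2, 1)
  img <- image_volume(array(c(0, 4.9, 5.0, 14.9), d), c(1, 1, 1))
  roi <- roi_mask(array(TRUE, d), c(1, 1, 1))
  out <- discretize(img, roi, prep_config(bin_width = 5))
  expect_equal(sort(unique(as.vector(out$levels))), c(1L, 2L, 3L))
  expect_equal(as.vector(out$levels), c(1L, 1L, 2L, 3L))
  expect_equal(out$n_levels, 3L)

  flat <- image_volume(array(9, d), c(1, 1, 1))
  fo <- discretize(flat, roi, prep_config())
  expect_true(all(fo$levels == 1L))
  expect_equal(fo$n_levels, 1L)

  # normalized-scale ROI: level count tracks realized range / bin width
  set.seed(3)
  dd <- c(10, 10, 10)
  nimg <- image_volume(array(stats::rnorm(1000, 0, 100), dd), c(1, 1, 1))
  nroi <- roi_mask(array(TRUE, dd), c(1, 1, 1))
  no <- discretize(nimg, nroi, prep_config(bin_width = 5))
  expect_equal(no$n_levels,
               floor(diff(range(nimg$data)) / 5) + 1)
  expect_error(discretize(nimg, roi_mask(array(FALSE, dd), c(1, 1, 1)),
                          prep_config()), "empty")
})

test_that("LoG filter kills constants and linear ramps and finds blob scale", {
  cfg <- prep_config()
  const <- image_volume(array(5, c(24, 24, 24)), c(1, 1, 1))
  expect_lt(max(abs(log_filter(const, 2)$data)), 1e-10)

  d <- c(40, 40, 40)
  ramp <- image_volume(array(rep(0:39, each = 1600), d), c(1, 1, 1))
  lr <- log_filter(ramp, 2)
  interior <- lr$data[15:26, 15:26, 15:26]
  expect_lt(max(abs(interior)), 1e-8)

  # centred Gaussian blob of scale s, filtered at sigma: extremum at the
  # blob centre, magnitude given by the analytic convolution of Gaussians
  s <- 5; sigma <- 3
  ctr <- (d - 1) / 2
  g <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  blob <- image_volume(array(exp(-r2 / (2 * s^2)), d), c(1, 1, 1))
  lb <- log_filter(blob, sigma)
  idx <- which(lb$data == min(lb$data), arr.ind = TRUE)[1, ]
  expect_true(all(abs(idx - (ctr + 1)) <= 1))
  # analytic: smoothing the blob gives (s^3/t^3) exp(-r^2/2t^2) with
  # t^2 = s^2 + sigma^2, whose Laplacian at the centre is -3 s^3 / t^5
  t2 <- s^2 + sigma^2
  expected_centre <- -3 * s^3 / t2^(5 / 2)
  expect_equal(min(lb$data), expected_centre, tolerance = 0.03)
  expect_error(log_filter(const, -1), "sigma")
})

test_that("the preprocessing chain keeps grid geometry after resampling", {
  p <- small_cohort()[[1]]
  prep <- preprocess_image(p$images$CET1, p$tumor_mask, p$reference_mask,
                           prep_config())
  dims <- lapply(prep$images, function(i) dim(i$data))
  expect_true(all(vapply(dims, identical, logical(1), dims[[1]])))
  expect_identical(dim(prep$tumor$data), dims[[1]])
  expect_equal(prep$images$original$spacing, c(1, 1, 1))
  expect_named(prep$images, c("original", "log-sigma-2-0", "log-sigma-3-0",
                              "log-sigma-4-0", "log-sigma-5-0"))
  # normalization holds inside the (resampled) reference region
  v <- prep$images$original$data[prep$reference$data]
  expect_equal(mean(v), 0, tolerance = 1e-8)
  expect_equal(stats::sd(v), 100, tolerance = 1e-6)
})

test_that("prep_config reads from YAML and validates", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("target_spacing: 2.0", "bin_width: 10",
               "log_sigmas: [1.0, 2.0]", "bias_correction: no"), path)
  cfg <- prep_config_from_yaml(path)
  expect_equal(cfg$target_spacing, 2.0)
  expect_equal(cfg$bin_width, 10)
  expect_equal(cfg$log_sigmas, c(1, 2))
  expect_false(cfg$bias_correction)
  expect_error(prep_config(bin_width = 0), "bin_width")
  expect_error(prep_config(log_sigmas = c(2, 2)), "distinct")
})
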