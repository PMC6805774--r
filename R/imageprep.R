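#' Preprocessing configuration
#'
#' Houses every tunable of the image preprocessing chain: the isotropic
#' target spacing, the fixed discretization bin width, the
#' Laplacian-of-Gaussian scales, whether bias-field correction runs, and the
#' multiplier applied after reference-region z-scoring.
#'
#' Defaults follow the study protocol this pipeline reproduces: resampling to
#' 1 x 1 x 1 mm, a fixed bin width of 5, and LoG sigmas of 2, 3, 4 and 5 mm.
#' The normalization scale of 100 makes the bin width of 5 correspond to one
#' twentieth of the reference-region standard deviation, so discretization
#' stays meaningful on arbitrarily scaled synthetic intensities.
#'
#' @param target_spacing isotropic voxel size in mm (> 0).
#' @param bin_width discretization bin width, in normalized intensity units.
#' @param log_sigmas LoG scales in mm; strictly positive and distinct.
#' @param bias_correction logical; run N4-style bias-field correction.
#' @param normalization_scale multiplier applied after reference z-scoring.
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(target_spacing = 1.0, bin_width = 5,
                        log_sigmas = c(2, 3, 4, 5),
                        bias_correction = TRUE,
                        normalization_scale = 100) {
  if (!is.numeric(target_spacing) || target_spacing <= 0)
    stop("`target_spacing` must be > 0")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be > 0")
  if (length(log_sigmas) && (any(log_sigmas <= 0) || anyDuplicated(log_sigmas)))
    stop("`log_sigmas` must be strictly positive and distinct")
  structure(
    list(target_spacing = target_spacing, bin_width = bin_width,
         log_sigmas = as.numeric(log_sigmas),
         bias_correction = isTRUE(bias_correction),
         normalization_scale = normalization_scale),
    class = "prep_config"
  )
}

#' Read a preprocessing configuration from YAML
#'
#' @param path YAML file; keys matching the arguments of [prep_config()].
#' @return A `prep_config`.
#' @export
prep_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(prep_config)))
  do.call(prep_config, vals[keep])
}

# ---- separable convolution with symmetric (reflect) padding ----------------

# 1-D convolution of `arr` along `axis` with kernel `k` (odd length),
# symmetric boundary handling.  Vectorized as a sum over kernel taps.
.conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(k) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dim(x) <- c(n, prod(d[perm[2:3]]))
  # symmetric (half-sample mirror) padding indices
  pre <- pmin(pmax(rev(seq_len(r)), 1L), n)
  post <- pmin(pmax(n + 1L - seq_len(r), 1L), n)
  xp <- x[c(pre, seq_len(n), post), , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) {
    if (k[j] != 0)
      out <- out + k[j] * xp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

.gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  # second derivative of a Gaussian, zero-DC so constants map to 0
  k <- (x^2 / sigma^4 - 1 / sigma^2) * g
  k - mean(k)
}

# Gaussian smoothing of a plain 3-D array, per-axis sigma in voxels.
.gaussian_smooth3 <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0)
      arr <- .conv_axis(arr, .gauss_kernel(sigma_vox[ax]), ax)
  }
  arr
}

# ---- resampling ------------------------------------------------------------

.axis_centers <- function(n, sp, orig) orig + (seq_len(n) - 1) * sp

# Trilinear interpolation of `arr` (grid centers given per axis) at the
# cartesian product of query coordinates qx, qy, qz.  Clamped at the edges.
.trilinear <- function(arr, centers, qx, qy, qz) {
  d <- dim(arr)
  locate <- function(q, cen) {
    n <- length(cen)
    if (n == 1L) return(list(i0 = rep(1L, length(q)), w = rep(0, length(q))))
    t <- (q - cen[1]) / (cen[2] - cen[1])
    i0 <- floor(t) + 1
    i0 <- pmin(pmax(i0, 1), n - 1)
    w <- pmin(pmax(t - (i0 - 1), 0), 1)
    list(i0 = as.integer(i0), w = w)
  }
  lx <- locate(qx, centers[[1]]); ly <- locate(qy, centers[[2]])
  lz <- locate(qz, centers[[3]])
  nx <- length(qx); ny <- length(qy); nz <- length(qz)
  ix <- array(lx$i0, c(nx, ny, nz)); wx <- array(lx$w, c(nx, ny, nz))
  iy <- array(rep(ly$i0, each = nx), c(nx, ny, nz))
  wy <- array(rep(ly$w, each = nx), c(nx, ny, nz))
  iz <- array(rep(lz$i0, each = nx * ny), c(nx, ny, nz))
  wz <- array(rep(lz$w, each = nx * ny), c(nx, ny, nz))
  at <- function(ax, ay, az) arr[cbind(c(ax), c(ay), c(az))]
  ix1 <- pmin(ix + 1L, d[1]); iy1 <- pmin(iy + 1L, d[2]); iz1 <- pmin(iz + 1L, d[3])
  v <- (1 - wz) * ((1 - wy) * ((1 - wx) * at(ix, iy, iz) + wx * at(ix1, iy, iz)) +
                     wy * ((1 - wx) * at(ix, iy1, iz) + wx * at(ix1, iy1, iz))) +
    wz * ((1 - wy) * ((1 - wx) * at(ix, iy, iz1) + wx * at(ix1, iy, iz1)) +
            wy * ((1 - wx) * at(ix, iy1, iz1) + wx * at(ix1, iy1, iz1)))
  array(v, c(nx, ny, nz))
}

#' Resample an image and its mask to isotropic spacing
#'
#' The image is resampled by trilinear interpolation, the mask by
#' nearest-neighbour interpolation, onto a grid with `cfg$target_spacing` on
#' every axis.  The output grid covers the same physical extent as the input
#' (voxel edges aligned, extent preserved to within one voxel).  When the
#' input is already on the target grid the data are returned untouched.
#'
#' @param img an [image_volume()].
#' @param mask an [roi_mask()] on the same grid (may be `NULL`).
#' @param cfg a [prep_config()].
#' @return list with elements `image` and `mask`.
#' @export
resample_isotropic <- function(img, mask = NULL, cfg = prep_config()) {
  sp <- img$spacing
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("missing or zero voxel spacing")
  if (!is.null(mask)) .check_grid(img, mask)
  t <- cfg$target_spacing
  if (isTRUE(all.equal(sp, rep(t, 3), tolerance = 1e-9))) {
    return(list(image = img, mask = mask))
  }
  d <- dim(img$data)
  extent <- d * sp
  nd <- pmax(1L, as.integer(round(extent / t)))
  # align physical corners: first output centre sits half a target voxel
  # inside the input's physical edge
  new_origin <- img$origin - sp / 2 + t / 2
  centers <- lapply(1:3, function(a) .axis_centers(d[a], sp[a], img$origin[a]))
  q <- lapply(1:3, function(a) .axis_centers(nd[a], t, new_origin[a]))
  out_img <- .trilinear(img$data, centers, q[[1]], q[[2]], q[[3]])
  res_img <- image_volume(out_img, rep(t, 3), new_origin,
                          channel = img$channel, filter = img$filter)
  res_mask <- NULL
  if (!is.null(mask)) {
    nn <- lapply(1:3, function(a) {
      i <- as.integer(round((q[[a]] - img$origin[a]) / sp[a])) + 1L
      pmin(pmax(i, 1L), d[a])
    })
    md <- mask$data[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
    dim(md) <- nd
    res_mask <- roi_mask(md, rep(t, 3), new_origin, role = mask$role)
  }
  list(image = res_img, mask = res_mask)
}

# ---- bias-field correction -------------------------------------------------

#' Correct a smooth multiplicative bias field
#'
#' N4-style correction: the log-intensity is fitted with a low-order 3-D
#' polynomial by iteratively reweighted least squares, the exponential of the
#' (mean-centred) fit is taken as the multiplicative field, and the image is
#' divided by it.  The output is rescaled to preserve the input mean.  This
#' removes slowly varying shading while leaving anatomy-scale contrast alone.
#'
#' @param img an [image_volume()]; intensities must be finite.  Non-positive
#'   intensities are shifted up before taking logs.
#' @param degree total polynomial degree of the field model.
#' @param n_iter reweighting iterations.
#' @return Bias-corrected [image_volume()].
#' @export
correct_bias_field <- function(img, degree = 2L, n_iter = 3L) {
  x <- img$data
  if (any(!is.finite(x))) stop("non-finite voxel intensities")
  shift <- 0
  mn <- min(x)
  if (mn <= 0) shift <- 1 - mn
  lx <- log(x + shift)
  d <- dim(x)
  cc <- lapply(1:3, function(a) {
    if (d[a] == 1L) rep(0, d[a]) else seq(-1, 1, length.out = d[a])
  })
  X1 <- rep(cc[[1]], times = d[2] * d[3])
  X2 <- rep(rep(cc[[2]], each = d[1]), times = d[3])
  X3 <- rep(cc[[3]], each = d[1] * d[2])
  terms <- list()
  for (i in 0:degree) for (j in 0:(degree - i)) for (k in 0:(degree - i - j))
    terms[[length(terms) + 1L]] <- X1^i * X2^j * X3^k
  B <- do.call(cbind, terms)
  y <- as.numeric(lx)
  w <- rep(1, length(y))
  for (it in seq_len(n_iter)) {
    fit <- stats::lm.wfit(B, y, w)
    r <- y - fit$fitted.values
    s <- stats::mad(r) + 1e-12
    w <- 1 / (1 + (r / (2.5 * s))^2)  # downweight anatomy, keep shading
  }
  field <- fit$fitted.values - mean(fit$fitted.values)
  corrected <- (x + shift) / exp(array(field, d)) - shift
  corrected <- corrected * (mean(x) / mean(corrected))
  image_volume(corrected, img$spacing, img$origin,
               channel = img$channel, filter = img$filter)
}

# ---- reference-region normalization ----------------------------------------

#' Normalize intensities against a reference region
#'
#' Maps the image to `(I - mu_ref) / sd_ref * normalization_scale`, where
#' `mu_ref` and `sd_ref` are the mean and standard deviation inside the
#' reference ROI (brainstem surrogate).  Inside the reference region the
#' output therefore has mean 0 and SD `normalization_scale`.  The transform
#' is invariant to affine rescaling `a*I + b` (a > 0) of the input.
#'
#' @param img an [image_volume()].
#' @param ref a non-empty [roi_mask()] with `role = "reference"`.
#' @param cfg a [prep_config()].
#' @return Normalized [image_volume()].
#' @export
normalize_by_reference <- function(img, ref, cfg = prep_config()) {
  .check_grid(img, ref)
  v <- img$data[ref$data]
  if (length(v) == 0L) stop("empty reference ROI")
  mu <- mean(v)
  sd_ref <- stats::sd(v)
  if (!is.finite(sd_ref) || sd_ref == 0) stop("reference ROI has zero variance")
  out <- (img$data - mu) / sd_ref * cfg$normalization_scale
  image_volume(out, img$spacing, img$origin,
               channel = img$channel, filter = img$filter)
}

# ---- discretization --------------------------------------------------------

#' Discretize ROI intensities with a fixed bin width
#'
#' `level(x) = floor((x - min_roi) / bin_width) + 1` for voxels inside the
#' ROI; voxels outside are `NA`.  Applied independently per (channel, filter)
#' image, so LoG outputs with negative values are handled by the min shift.
#'
#' @param img an [image_volume()].
#' @param roi a non-empty [roi_mask()].
#' @param cfg a [prep_config()]; `cfg$bin_width` is used.
#' @return list with `levels` (integer 3-D array, `NA` outside the ROI) and
#'   `n_levels` (maximum level).
#' @export
discretize <- function(img, roi, cfg = prep_config()) {
  .check_grid(img, roi)
  inroi <- roi$data
  if (!any(inroi)) stop("empty ROI")
  v <- img$data[inroi]
  lev <- as.integer(floor((v - min(v)) / cfg$bin_width)) + 1L
  out <- array(NA_integer_, dim(img$data))
  out[inroi] <- lev
  list(levels = out, n_levels = max(lev))
}

# ---- Laplacian of Gaussian -------------------------------------------------

#' Multi-scale Laplacian-of-Gaussian filter
#'
#' Gaussian smoothing at scale `sigma` (mm) followed by the Laplacian,
#' implemented as a separable sum of second-derivative-of-Gaussian kernels.
#' Boundaries are handled by symmetric reflection.  The response to a
#' constant or linear field is zero (away from edges); the operator is
#' linear and shift invariant.
#'
#' @param img an [image_volume()]; resample first so `sigma` in mm maps onto
#'   voxels correctly (anisotropic spacing is honoured per axis).
#' @param sigma filter scale in mm (> 0).
#' @return Filtered [image_volume()] with an updated `filter` tag.
#' @export
log_filter <- function(img, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  sv <- sigma / img$spacing
  g <- lapply(1:3, function(a) .gauss_kernel(sv[a]))
  out <- 0
  for (ax in 1:3) {
    tmp <- img$data
    for (a in 1:3) {
      k <- if (a == ax) .gauss_kernel(sv[a], order = 2L) / img$spacing[a]^2 else g[[a]]
      tmp <- .conv_axis(tmp, k, a)
    }
    out <- out + tmp
  }
  tag <- sprintf("log-sigma-%s-0", gsub("[.]", "-", format(sigma)))
  image_volume(out, img$spacing, img$origin, channel = img$channel, filter = tag)
}

# ---- full preprocessing chain ----------------------------------------------

#' Run the fixed preprocessing chain on one image/mask set
#'
#' Order is fixed: resample to isotropic spacing, bias-correct, normalize
#' against the reference region, then produce the original plus one LoG image
#' per configured sigma.  Discretization happens later, per filtered image,
#' inside the feature extractor.
#'
#' @param img an [image_volume()].
#' @param tumor tumor [roi_mask()] on the same grid.
#' @param reference reference [roi_mask()] on the same grid.
#' @param cfg a [prep_config()].
#' @return list with `images` (named list: `original`, `log-sigma-...`),
#'   `tumor`, and `reference`, all on the isotropic grid.
#' @export
preprocess_image <- function(img, tumor, reference, cfg = prep_config()) {
  r1 <- resample_isotropic(img, tumor, cfg)
  rr <- resample_isotropic(img, reference, cfg)
  img_i <- r1$image
  if (cfg$bias_correction) img_i <- correct_bias_field(img_i)
  img_n <- normalize_by_reference(img_i, rr$mask, cfg)
  images <- list(original = img_n)
  for (s in cfg$log_sigmas) {
    f <- log_filter(img_n, s)
    images[[f$filter]] <- f
  }
  list(images = images, tumor = r1$mask, reference = rr$mask)
}
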