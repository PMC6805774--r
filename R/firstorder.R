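#' Extract the 18 first-order intensity features
#'
#' Histogram-based entropy and uniformity use the same fixed bin width as the
#' texture discretization; all other statistics work on the raw ROI
#' intensities.  Moments are population moments; kurtosis is non-excess
#' (a Gaussian gives 3).  On a constant ROI, skewness and kurtosis are
#' undefined and are returned as 0 (documented degenerate-value policy), so
#' the feature vector stays finite.
#'
#' @param img an [image_volume()].
#' @param roi a non-empty [roi_mask()] on the same grid.
#' @param cfg a [prep_config()]; `bin_width` feeds the histogram features.
#' @return named numeric vector of length 18.
#' @export
extract_firstorder <- function(img, roi, cfg = prep_config()) {
  .check_grid(img, roi)
  x <- img$data[roi$data]
  n <- length(x)
  if (n == 0L) stop("empty ROI")
  vox <- prod(img$spacing)

  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skewness <- if (m2 > 0) m3 / m2^1.5 else 0
  kurtosis <- if (m2 > 0) m4 / m2^2 else 0

  # fixed-bin-width histogram for entropy / uniformity
  lev <- floor((x - min(x)) / cfg$bin_width)
  p <- tabulate(as.integer(lev) + 1L)
  p <- p[p > 0] / n
  entropy <- -sum(p * log2(p))
  uniformity <- sum(p^2)

  qs <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  rmad_vals <- x[x >= qs[1] & x <= qs[5]]

  c(Energy = sum(x^2),
    TotalEnergy = vox * sum(x^2),
    Entropy = entropy,
    Minimum = min(x),
    P10 = qs[1],
    P90 = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rmad_vals - mean(rmad_vals))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skewness,
    Kurtosis = kurtosis,
    Variance = m2,
    Uniformity = uniformity)
}
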