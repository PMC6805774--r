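# Texture feature formulas (24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
# 5 NGTDM), following the standard 2019-era radiomics definitions.
# Directional families (GLCM, GLRLM) are computed per direction and averaged.
# Degenerate inputs (single gray level, single voxel) return defined values:
# correlation-type features fall back to 1, entropy-type features to 0.

.safe_log2 <- function(p) ifelse(p > 0, log2(p), 0)

.glcm_features_one <- function(C) {
  ng <- nrow(C)
  N <- sum(C)
  if (N == 0) { C <- matrix(0, ng, ng); C[1, 1] <- 1; N <- 1 }
  p <- C / N
  iv <- seq_len(ng)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sigx <- sqrt(sum((iv - mux)^2 * px)); sigy <- sqrt(sum((iv - muy)^2 * py))
  I <- matrix(iv, ng, ng); J <- t(I)
  # sum / difference distributions
  dvals <- 0:(ng - 1)
  pdiff <- vapply(dvals, function(k) sum(p[abs(I - J) == k]), numeric(1))
  svals <- 2:(2 * ng)
  psum <- vapply(svals, function(k) sum(p[(I + J) == k]), numeric(1))

  contrast <- sum((I - J)^2 * p)
  autocorr <- sum(I * J * p)
  joint_avg <- mux
  cl <- I + J - mux - muy
  cluster_tend <- sum(cl^2 * p)
  cluster_shade <- sum(cl^3 * p)
  cluster_prom <- sum(cl^4 * p)
  correlation <- if (sigx > 0 && sigy > 0)
    (autocorr - mux * muy) / (sigx * sigy) else 1
  diff_avg <- sum(dvals * pdiff)
  diff_ent <- -sum(pdiff * .safe_log2(pdiff))
  diff_var <- sum((dvals - diff_avg)^2 * pdiff)
  joint_energy <- sum(p^2)
  joint_ent <- -sum(p * .safe_log2(p))
  hx <- -sum(px * .safe_log2(px)); hy <- -sum(py * .safe_log2(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * .safe_log2(pxpy))
  hxy2 <- -sum(pxpy * .safe_log2(pxpy))
  imc1 <- if (max(hx, hy) > 0) (joint_ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - joint_ent)), 0))
  idm <- sum(p / (1 + (I - J)^2))
  idmn <- sum(p / (1 + ((I - J) / ng)^2))
  id <- sum(p / (1 + abs(I - J)))
  idn <- sum(p / (1 + abs(I - J) / ng))
  off <- I != J
  inv_var <- sum(p[off] / (I[off] - J[off])^2)
  max_prob <- max(p)
  sum_avg <- sum(svals * psum)
  sum_ent <- -sum(psum * .safe_log2(psum))
  sum_squares <- sum((I - mux)^2 * p)

  pres <- which(px > 0)
  mcc <- if (length(pres) < 2) 1 else {
    pp <- p[pres, pres, drop = FALSE]
    pxp <- px[pres]; pyp <- py[pres]
    Q <- (pp / pxp) %*% (t(pp) / pyp)
    ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }

  c(Autocorrelation = autocorr, ClusterProminence = cluster_prom,
    ClusterShade = cluster_shade, ClusterTendency = cluster_tend,
    Contrast = contrast, Correlation = correlation,
    DifferenceAverage = diff_avg, DifferenceEntropy = diff_ent,
    DifferenceVariance = diff_var, Id = id, Idm = idm, Idmn = idmn,
    Idn = idn, Imc1 = imc1, Imc2 = imc2, InverseVariance = inv_var,
    JointAverage = joint_avg, JointEnergy = joint_energy,
    JointEntropy = joint_ent, MCC = mcc, MaximumProbability = max_prob,
    SumAverage = sum_avg, SumEntropy = sum_ent, SumSquares = sum_squares)
}

.rl_type_features <- function(M, n_roi, prefix = c("run", "zone")) {
  prefix <- match.arg(prefix)
  ng <- nrow(M); nl <- ncol(M)
  Nr <- sum(M)
  if (Nr == 0) { M <- matrix(0, ng, nl); M[1, 1] <- 1; Nr <- 1 }
  p <- M / Nr
  iv <- seq_len(ng); jv <- seq_len(nl)
  I <- matrix(iv, ng, nl); J <- matrix(jv, ng, nl, byrow = TRUE)
  ri <- rowSums(M); rj <- colSums(M)
  mu_i <- sum(I * p); mu_j <- sum(J * p)
  vals <- c(
    ShortEmphasis = sum(p / J^2),
    LongEmphasis = sum(p * J^2),
    GrayLevelNonUniformity = sum(ri^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / Nr^2,
    LengthNonUniformity = sum(rj^2) / Nr,
    LengthNonUniformityNormalized = sum(rj^2) / Nr^2,
    Percentage = Nr / n_roi,
    GrayLevelVariance = sum((I - mu_i)^2 * p),
    LengthVariance = sum((J - mu_j)^2 * p),
    Entropy = -sum(p * .safe_log2(p)),
    LowGrayLevelEmphasis = sum(p / I^2),
    HighGrayLevelEmphasis = sum(p * I^2),
    ShortLowGrayLevelEmphasis = sum(p / (I^2 * J^2)),
    ShortHighGrayLevelEmphasis = sum(p * I^2 / J^2),
    LongLowGrayLevelEmphasis = sum(p * J^2 / I^2),
    LongHighGrayLevelEmphasis = sum(p * I^2 * J^2)
  )
  if (prefix == "run") {
    names(vals) <- c("ShortRunEmphasis", "LongRunEmphasis",
                     "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                     "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                     "RunPercentage", "GrayLevelVariance", "RunVariance",
                     "RunEntropy", "LowGrayLevelRunEmphasis",
                     "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                     "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                     "LongRunHighGrayLevelEmphasis")
  } else {
    names(vals) <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                     "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                     "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                     "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                     "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                     "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                     "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
                     "LargeAreaHighGrayLevelEmphasis")
  }
  vals
}

.gldm_features <- function(M) {
  ng <- nrow(M); nd <- ncol(M)
  Nz <- sum(M)
  if (Nz == 0) { M <- matrix(0, ng, nd); M[1, 1] <- 1; Nz <- 1 }
  p <- M / Nz
  I <- matrix(seq_len(ng), ng, nd); J <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
  ri <- rowSums(M); rj <- colSums(M)
  mu_i <- sum(I * p); mu_j <- sum(J * p)
  c(SmallDependenceEmphasis = sum(p / J^2),
    LargeDependenceEmphasis = sum(p * J^2),
    GrayLevelNonUniformity = sum(ri^2) / Nz,
    DependenceNonUniformity = sum(rj^2) / Nz,
    DependenceNonUniformityNormalized = sum(rj^2) / Nz^2,
    GrayLevelVariance = sum((I - mu_i)^2 * p),
    DependenceVariance = sum((J - mu_j)^2 * p),
    DependenceEntropy = -sum(p * .safe_log2(p)),
    LowGrayLevelEmphasis = sum(p / I^2),
    HighGrayLevelEmphasis = sum(p * I^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (I^2 * J^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * I^2 / J^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * J^2 / I^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * I^2 * J^2))
}

.ngtdm_features <- function(nt) {
  s <- nt$s; n <- nt$n
  N <- sum(n)
  if (N == 0) return(c(Busyness = 0, Coarseness = 1e6, Complexity = 0,
                       Contrast = 0, Strength = 0))
  p <- n / N
  pres <- which(p > 0)
  ngp <- length(pres)
  iv <- seq_along(p)
  denom_coarse <- sum(p * s)
  coarseness <- if (denom_coarse > 0) 1 / denom_coarse else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p[pres], p[pres]) * outer(iv[pres], iv[pres], "-")^2) /
      (ngp * (ngp - 1)) * sum(s) / N
  } else 0
  busy_den <- sum(abs(outer(iv[pres] * p[pres], iv[pres] * p[pres], "-")))
  busyness <- if (busy_den > 0) denom_coarse / busy_den else 0
  pi_ <- p[pres]; si_ <- s[pres]; ii_ <- iv[pres]
  complexity <- sum(abs(outer(ii_, ii_, "-")) *
                      (outer(pi_ * si_, pi_ * si_, "+")) /
                      outer(pi_, pi_, "+")) / N
  strength_num <- sum(outer(pi_, pi_, "+") * outer(ii_, ii_, "-")^2)
  strength <- if (sum(s) > 0) strength_num / sum(s) else 0
  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}

#' Compute the 75 texture features from a set of texture matrices
#'
#' @param tm a `texture_matrices` object from [build_texture_matrices()].
#' @return named numeric vector of 75 features with family prefixes
#'   (`glcm_`, `glrlm_`, `glszm_`, `gldm_`, `ngtdm_`).
#' @export
texture_features <- function(tm) {
  glcm <- rowMeans(vapply(tm$glcm, .glcm_features_one, numeric(24)))
  glrlm <- rowMeans(vapply(tm$glrlm, .rl_type_features, numeric(16),
                           n_roi = tm$n_roi, prefix = "run"))
  glszm <- .rl_type_features(tm$glszm, tm$n_roi, prefix = "zone")
  gldm <- .gldm_features(tm$gldm)
  ngtdm <- .ngtdm_features(tm$ngtdm)
  out <- c(stats::setNames(glcm, paste0("glcm_", names(glcm))),
           stats::setNames(glrlm, paste0("glrlm_", names(glrlm))),
           stats::setNames(glszm, paste0("glszm_", names(glszm))),
           stats::setNames(gldm, paste0("gldm_", names(gldm))),
           stats::setNames(ngtdm, paste0("ngtdm_", names(ngtdm))))
  stopifnot(length(out) == 75L, all(is.finite(out)))
  out
}
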