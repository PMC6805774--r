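# Independent brute-force oracles: naive loop implementations of every
# feature family, kept deliberately separate from the vectorized package
# code paths.  All follow the same conventions the package documents
# (13 directions, symmetric GLCM, runs broken by the ROI boundary,
# 26-connected zones, dependence size = neighbours-within-alpha + 1).

oracle_dirs <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

.o_in <- function(lev, i, j, k) {
  d <- dim(lev)
  i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3] &&
    !is.na(lev[i, j, k])
}

oracle_glcm <- function(lev, ng, d) {
  m <- matrix(0, ng, ng)
  dm <- dim(lev)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lev[i, j, k])) next
    i2 <- i + d[1]; j2 <- j + d[2]; k2 <- k + d[3]
    if (.o_in(lev, i2, j2, k2)) {
      a <- lev[i, j, k]; b <- lev[i2, j2, k2]
      m[a, b] <- m[a, b] + 1
      m[b, a] <- m[b, a] + 1
    }
  }
  m
}

oracle_glrlm <- function(lev, ng, d) {
  dm <- dim(lev)
  runs <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lev[i, j, k])) next
    v <- lev[i, j, k]
    # run start: predecessor along -d is outside ROI or a different level
    ip <- i - d[1]; jp <- j - d[2]; kp <- k - d[3]
    if (.o_in(lev, ip, jp, kp) && lev[ip, jp, kp] == v) next
    len <- 1
    i2 <- i + d[1]; j2 <- j + d[2]; k2 <- k + d[3]
    while (.o_in(lev, i2, j2, k2) && lev[i2, j2, k2] == v) {
      len <- len + 1
      i2 <- i2 + d[1]; j2 <- j2 + d[2]; k2 <- k2 + d[3]
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  maxlen <- max(vapply(runs, `[`, numeric(1), 2))
  m <- matrix(0, ng, maxlen)
  for (r in runs) m[r[1], r[2]] <- m[r[1], r[2]] + 1
  m
}

oracle_glszm <- function(lev, ng) {
  dm <- dim(lev)
  seen <- array(FALSE, dm)
  dirs <- rbind(oracle_dirs(), -oracle_dirs())
  zones <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lev[i, j, k]) || seen[i, j, k]) next
    v <- lev[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(dirs))) {
        nb <- cur + dirs[r, ]
        if (.o_in(lev, nb[1], nb[2], nb[3]) && !seen[nb[1], nb[2], nb[3]] &&
            lev[nb[1], nb[2], nb[3]] == v) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
    zones[[length(zones) + 1]] <- c(v, size)
  }
  maxsize <- max(vapply(zones, `[`, numeric(1), 2))
  m <- matrix(0, ng, maxsize)
  for (z in zones) m[z[1], z[2]] <- m[z[1], z[2]] + 1
  m
}

oracle_gldm <- function(lev, ng, alpha = 0) {
  dm <- dim(lev)
  dirs <- rbind(oracle_dirs(), -oracle_dirs())
  entries <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lev[i, j, k])) next
    v <- lev[i, j, k]
    dep <- 0
    for (r in seq_len(nrow(dirs))) {
      nb <- c(i, j, k) + dirs[r, ]
      if (.o_in(lev, nb[1], nb[2], nb[3]) &&
          abs(lev[nb[1], nb[2], nb[3]] - v) <= alpha) dep <- dep + 1
    }
    entries[[length(entries) + 1]] <- c(v, dep + 1)
  }
  nd <- max(vapply(entries, `[`, numeric(1), 2))
  m <- matrix(0, ng, nd)
  for (e in entries) m[e[1], e[2]] <- m[e[1], e[2]] + 1
  m
}

oracle_ngtdm <- function(lev, ng) {
  dm <- dim(lev)
  dirs <- rbind(oracle_dirs(), -oracle_dirs())
  s <- numeric(ng); n <- numeric(ng)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lev[i, j, k])) next
    v <- lev[i, j, k]
    nb <- c()
    for (r in seq_len(nrow(dirs))) {
      q <- c(i, j, k) + dirs[r, ]
      if (.o_in(lev, q[1], q[2], q[3])) nb <- c(nb, lev[q[1], q[2], q[3]])
    }
    if (!length(nb)) next
    s[v] <- s[v] + abs(v - mean(nb))
    n[v] <- n[v] + 1
  }
  list(s = s, n = n)
}

# ---- direct-formula feature oracles ---------------------------------------

oracle_glcm_features <- function(C) {
  ng <- nrow(C)
  N <- sum(C)
  if (N == 0) { C <- matrix(0, ng, ng); C[1, 1] <- 1; N <- 1 }
  p <- C / N
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sigy <- sqrt(sum(((1:ng) - muy)^2 * py))
  f <- c(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
         ClusterTendency = 0, Contrast = 0, Correlation = 0,
         DifferenceAverage = 0, DifferenceEntropy = 0, DifferenceVariance = 0,
         Id = 0, Idm = 0, Idmn = 0, Idn = 0, Imc1 = 0, Imc2 = 0,
         InverseVariance = 0, JointAverage = mux, JointEnergy = 0,
         JointEntropy = 0, MCC = 0, MaximumProbability = max(p),
         SumAverage = 0, SumEntropy = 0, SumSquares = 0)
  pdiff <- numeric(ng); psum <- numeric(2 * ng - 1)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * pij
    cl <- i + j - mux - muy
    f["ClusterTendency"] <- f["ClusterTendency"] + cl^2 * pij
    f["ClusterShade"] <- f["ClusterShade"] + cl^3 * pij
    f["ClusterProminence"] <- f["ClusterProminence"] + cl^4 * pij
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * pij
    f["Id"] <- f["Id"] + pij / (1 + abs(i - j))
    f["Idm"] <- f["Idm"] + pij / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + pij / (1 + ((i - j) / ng)^2)
    f["Idn"] <- f["Idn"] + pij / (1 + abs(i - j) / ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] + pij / (i - j)^2
    f["JointEnergy"] <- f["JointEnergy"] + pij^2
    if (pij > 0) f["JointEntropy"] <- f["JointEntropy"] - pij * log2(pij)
    f["SumSquares"] <- f["SumSquares"] + (i - mux)^2 * pij
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + pij
    psum[i + j - 1] <- psum[i + j - 1] + pij
    if (px[i] * py[j] > 0) {
      if (pij > 0) hxy1 <- hxy1 - pij * log2(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  for (kk in 0:(ng - 1)) {
    f["DifferenceAverage"] <- f["DifferenceAverage"] + kk * pdiff[kk + 1]
    if (pdiff[kk + 1] > 0)
      f["DifferenceEntropy"] <- f["DifferenceEntropy"] -
        pdiff[kk + 1] * log2(pdiff[kk + 1])
  }
  for (kk in 0:(ng - 1))
    f["DifferenceVariance"] <- f["DifferenceVariance"] +
      (kk - f[["DifferenceAverage"]])^2 * pdiff[kk + 1]
  for (ss in 2:(2 * ng)) {
    f["SumAverage"] <- f["SumAverage"] + ss * psum[ss - 1]
    if (psum[ss - 1] > 0)
      f["SumEntropy"] <- f["SumEntropy"] - psum[ss - 1] * log2(psum[ss - 1])
  }
  f["Correlation"] <- if (sigx > 0 && sigy > 0)
    (f[["Autocorrelation"]] - mux * muy) / (sigx * sigy) else 1
  hx <- -sum(ifelse(px > 0, px * log2(px), 0))
  hy <- -sum(ifelse(py > 0, py * log2(py), 0))
  f["Imc1"] <- if (max(hx, hy) > 0)
    (f[["JointEntropy"]] - hxy1) / max(hx, hy) else 0
  f["Imc2"] <- sqrt(max(1 - exp(-2 * (hxy2 - f[["JointEntropy"]])), 0))
  pres <- which(px > 0)
  f["MCC"] <- if (length(pres) < 2) 1 else {
    Q <- matrix(0, length(pres), length(pres))
    for (a in seq_along(pres)) for (b in seq_along(pres)) {
      for (kk in seq_along(pres)) {
        Q[a, b] <- Q[a, b] + p[pres[a], pres[kk]] * p[pres[b], pres[kk]] /
          (px[pres[a]] * py[pres[kk]])
      }
    }
    ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  f
}

oracle_rl_features <- function(M, n_roi) {
  ng <- nrow(M); nl <- ncol(M)
  Nr <- sum(M)
  p <- M / Nr
  out <- numeric(16)
  names(out) <- c("se", "le", "gln", "glnn", "lnu", "lnun", "pct", "glv",
                  "lv", "ent", "lgl", "hgl", "slgl", "shgl", "llgl", "lhgl")
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:nl) {
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  for (i in 1:ng) for (j in 1:nl) {
    pij <- p[i, j]
    out["se"] <- out["se"] + pij / j^2
    out["le"] <- out["le"] + pij * j^2
    out["glv"] <- out["glv"] + (i - mu_i)^2 * pij
    out["lv"] <- out["lv"] + (j - mu_j)^2 * pij
    if (pij > 0) out["ent"] <- out["ent"] - pij * log2(pij)
    out["lgl"] <- out["lgl"] + pij / i^2
    out["hgl"] <- out["hgl"] + pij * i^2
    out["slgl"] <- out["slgl"] + pij / (i^2 * j^2)
    out["shgl"] <- out["shgl"] + pij * i^2 / j^2
    out["llgl"] <- out["llgl"] + pij * j^2 / i^2
    out["lhgl"] <- out["lhgl"] + pij * i^2 * j^2
  }
  out["gln"] <- sum(rowSums(M)^2) / Nr
  out["glnn"] <- sum(rowSums(M)^2) / Nr^2
  out["lnu"] <- sum(colSums(M)^2) / Nr
  out["lnun"] <- sum(colSums(M)^2) / Nr^2
  out["pct"] <- Nr / n_roi
  out
}

oracle_gldm_features <- function(M) {
  ng <- nrow(M); nd <- ncol(M)
  Nz <- sum(M)
  p <- M / Nz
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:nd) {
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  out <- c(sde = 0, lde = 0, gln = sum(rowSums(M)^2) / Nz,
           dn = sum(colSums(M)^2) / Nz, dnn = sum(colSums(M)^2) / Nz^2,
           glv = 0, dv = 0, de = 0, lgl = 0, hgl = 0, sdlgl = 0, sdhgl = 0,
           ldlgl = 0, ldhgl = 0)
  for (i in 1:ng) for (j in 1:nd) {
    pij <- p[i, j]
    out["sde"] <- out["sde"] + pij / j^2
    out["lde"] <- out["lde"] + pij * j^2
    out["glv"] <- out["glv"] + (i - mu_i)^2 * pij
    out["dv"] <- out["dv"] + (j - mu_j)^2 * pij
    if (pij > 0) out["de"] <- out["de"] - pij * log2(pij)
    out["lgl"] <- out["lgl"] + pij / i^2
    out["hgl"] <- out["hgl"] + pij * i^2
    out["sdlgl"] <- out["sdlgl"] + pij / (i^2 * j^2)
    out["sdhgl"] <- out["sdhgl"] + pij * i^2 / j^2
    out["ldlgl"] <- out["ldlgl"] + pij * j^2 / i^2
    out["ldhgl"] <- out["ldhgl"] + pij * i^2 * j^2
  }
  out
}

oracle_ngtdm_features <- function(s, n) {
  N <- sum(n)
  p <- n / N
  pres <- which(p > 0)
  ngp <- length(pres)
  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else 1e6
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  for (i in pres) for (j in pres) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    complexity <- complexity + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
      (p[i] + p[j])
    strength <- strength + (p[i] + p[j]) * (i - j)^2
  }
  contrast <- if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(s) / N else 0
  busyness <- if (busy_den > 0) ps / busy_den else 0
  complexity <- complexity / N
  strength <- if (sum(s) > 0) strength / sum(s) else 0
  c(busyness = busyness, coarseness = coarse, complexity = complexity,
    contrast = contrast, strength = strength)
}

# naive first-order oracle (direct formulas on the ROI values)
oracle_firstorder <- function(x, bin_width, vox) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  lev <- floor((x - min(x)) / bin_width)
  p <- table(lev) / n
  qs <- stats::quantile(x, c(.1, .25, .5, .75, .9), names = FALSE)
  rv <- x[x >= qs[1] & x <= qs[5]]
  c(Energy = sum(x^2), TotalEnergy = vox * sum(x^2),
    Entropy = -sum(p * log2(p)), Minimum = min(x), P10 = qs[1], P90 = qs[5],
    Maximum = max(x), Mean = mu, Median = qs[3],
    InterquartileRange = qs[4] - qs[2], Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = mean(abs(rv - mean(rv))),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) (sum((x - mu)^3) / n) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) (sum((x - mu)^4) / n) / m2^2 else 0,
    Variance = m2, Uniformity = sum(p^2))
}

# brute-force greedy correlation pruning (mirrors the documented rule)
oracle_prune <- function(X, thr) {
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2) break
    R <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(R) <- 0
    if (max(R) < thr) break
    hit <- which(R == max(R), arr.ind = TRUE)
    hit <- hit[order(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2])), ,
               drop = FALSE][1, ]
    a <- min(hit); b <- max(hit)
    ma <- mean(R[a, -a]); mb <- mean(R[b, -b])
    drop_name <- if (ma > mb) keep[a] else keep[b]
    keep <- setdiff(keep, drop_name)
  }
  keep
}

# pairwise concordance enumeration AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
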