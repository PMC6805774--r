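# Texture matrices over the discretized ROI: GLCM and GLRLM per direction
# (13 unique 3-D directions at distance 1), GLSZM with 26-connected zones,
# GLDM with an alpha = 0 dependence criterion over the 26-neighbourhood, and
# NGTDM over the 26-neighbourhood.  All builders work on an integer level
# array that is NA outside the ROI (output of [discretize()]).

.directions13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# paired sub-array views of `lev` shifted by offset d; returns the two
# aligned level arrays (may contain NA)
.shift_pair <- function(lev, d) {
  dm <- dim(lev)
  rng <- function(n, s) {
    lo <- max(1L, 1L - s); hi <- min(n, n - s)
    if (lo > hi) integer(0) else lo:hi
  }
  xs <- rng(dm[1], d[1]); ys <- rng(dm[2], d[2]); zs <- rng(dm[3], d[3])
  a <- lev[xs, ys, zs, drop = FALSE]
  b <- lev[xs + d[1], ys + d[2], zs + d[3], drop = FALSE]
  list(a = a, b = b)
}

.glcm_one <- function(lev, ng, d) {
  p <- .shift_pair(lev, d)
  ok <- !is.na(p$a) & !is.na(p$b)
  a <- p$a[ok]; b <- p$b[ok]
  counts <- tabulate(a + (b - 1L) * ng, nbins = ng * ng)
  m <- matrix(counts, ng, ng)
  m + t(m)  # symmetrize
}

.glrlm_one <- function(lev, ng, d) {
  idx <- which(!is.na(lev), arr.ind = TRUE)
  v <- lev[!is.na(lev)]
  I <- idx[, 1]; J <- idx[, 2]; K <- idx[, 3]
  c1 <- J * d[3] - K * d[2]
  c2 <- K * d[1] - I * d[3]
  c3 <- I * d[2] - J * d[1]
  t <- I * d[1] + J * d[2] + K * d[3]
  step <- sum(d^2)
  o <- order(c1, c2, c3, t)
  c1 <- c1[o]; c2 <- c2[o]; c3 <- c3[o]; t <- t[o]; v <- v[o]
  n <- length(v)
  if (n == 0L) return(matrix(0, ng, 1))
  new_run <- c(TRUE,
               c1[-1] != c1[-n] | c2[-1] != c2[-n] | c3[-1] != c3[-n] |
                 t[-1] != t[-n] + step | v[-1] != v[-n])
  starts <- which(new_run)
  lens <- diff(c(starts, n + 1L))
  levels_run <- v[starts]
  maxlen <- max(lens)
  counts <- tabulate(levels_run + (lens - 1L) * ng, nbins = ng * maxlen)
  matrix(counts, ng, maxlen)
}

.glszm <- function(lev, ng) {
  roi_lin <- which(!is.na(lev))
  nroi <- length(roi_lin)
  vid <- array(NA_integer_, dim(lev))
  vid[roi_lin] <- seq_len(nroi)
  dirs <- .directions13()
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    p <- .shift_pair(lev, dirs[r, ])
    q <- .shift_pair(vid, dirs[r, ])
    ok <- !is.na(p$a) & !is.na(p$b) & p$a == p$b
    efrom <- c(efrom, q$a[ok]); eto <- c(eto, q$b[ok])
  }
  g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nroi - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  # level of each zone = level of any member voxel
  first_member <- match(seq_len(comp$no), comp$membership)
  zone_level <- lev[roi_lin][first_member]
  maxsize <- max(sizes)
  counts <- tabulate(zone_level + (sizes - 1L) * ng, nbins = ng * maxsize)
  matrix(counts, ng, maxsize)
}

.gldm <- function(lev, ng, alpha = 0L) {
  dm <- dim(lev)
  dep <- array(0L, dm)
  dirs <- .directions13()
  rng <- function(n, s) {
    lo <- max(1L, 1L - s); hi <- min(n, n - s)
    if (lo > hi) integer(0) else lo:hi
  }
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    xs <- rng(dm[1], d[1]); ys <- rng(dm[2], d[2]); zs <- rng(dm[3], d[3])
    a <- lev[xs, ys, zs, drop = FALSE]
    b <- lev[xs + d[1], ys + d[2], zs + d[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    inc <- array(0L, dim(a)); inc[ok] <- 1L
    dep[xs, ys, zs] <- dep[xs, ys, zs, drop = FALSE] + inc
    dep[xs + d[1], ys + d[2], zs + d[3]] <-
      dep[xs + d[1], ys + d[2], zs + d[3], drop = FALSE] + inc
  }
  inroi <- !is.na(lev)
  # dependence size includes the centre voxel, so j >= 1
  j <- dep[inroi] + 1L
  i <- lev[inroi]
  nd <- max(j)
  counts <- tabulate(i + (j - 1L) * ng, nbins = ng * nd)
  matrix(counts, ng, nd)
}

.ngtdm <- function(lev, ng) {
  dm <- dim(lev)
  nb_sum <- array(0, dm)
  nb_cnt <- array(0L, dm)
  dirs <- .directions13()
  rng <- function(n, s) {
    lo <- max(1L, 1L - s); hi <- min(n, n - s)
    if (lo > hi) integer(0) else lo:hi
  }
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    xs <- rng(dm[1], d[1]); ys <- rng(dm[2], d[2]); zs <- rng(dm[3], d[3])
    a <- lev[xs, ys, zs, drop = FALSE]
    b <- lev[xs + d[1], ys + d[2], zs + d[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    bv <- b; bv[!ok] <- 0L
    av <- a; av[!ok] <- 0L
    okl <- array(0L, dim(a)); okl[ok] <- 1L
    nb_sum[xs, ys, zs] <- nb_sum[xs, ys, zs, drop = FALSE] + bv
    nb_cnt[xs, ys, zs] <- nb_cnt[xs, ys, zs, drop = FALSE] + okl
    nb_sum[xs + d[1], ys + d[2], zs + d[3]] <-
      nb_sum[xs + d[1], ys + d[2], zs + d[3], drop = FALSE] + av
    nb_cnt[xs + d[1], ys + d[2], zs + d[3]] <-
      nb_cnt[xs + d[1], ys + d[2], zs + d[3], drop = FALSE] + okl
  }
  inroi <- !is.na(lev) & nb_cnt > 0
  i <- lev[inroi]
  diffs <- abs(i - nb_sum[inroi] / nb_cnt[inroi])
  s <- vapply(seq_len(ng), function(l) sum(diffs[i == l]), numeric(1))
  n_i <- tabulate(i, nbins = ng)
  list(s = s, n = n_i)
}

#' Build all texture matrices for a discretized ROI
#'
#' @param levels integer level array (`NA` outside the ROI), as produced by
#'   [discretize()].
#' @param n_levels number of gray levels (maximum level).
#' @return list of class `texture_matrices` with per-direction `glcm` and
#'   `glrlm` count matrices (13 each), a `glszm` and `gldm` matrix, the
#'   `ngtdm` sums, the gray-level count and the ROI voxel count.  Single-voxel
#'   ROIs yield degenerate (but well-defined) matrices, flagged via
#'   `degenerate`.
#' @export
build_texture_matrices <- function(levels, n_levels) {
  if (!any(!is.na(levels))) stop("empty ROI")
  ng <- as.integer(n_levels)
  dirs <- .directions13()
  glcm <- lapply(seq_len(nrow(dirs)), function(r) .glcm_one(levels, ng, dirs[r, ]))
  glrlm <- lapply(seq_len(nrow(dirs)), function(r) .glrlm_one(levels, ng, dirs[r, ]))
  n_roi <- sum(!is.na(levels))
  structure(
    list(glcm = glcm, glrlm = glrlm,
         glszm = .glszm(levels, ng),
         gldm = .gldm(levels, ng),
         ngtdm = .ngtdm(levels, ng),
         n_levels = ng, n_roi = n_roi,
         degenerate = n_roi < 2L || ng < 2L),
    class = "texture_matrices"
  )
}
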