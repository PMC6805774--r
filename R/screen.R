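#' Screening configuration
#'
#' Tunables of the two-step frequency-of-occurrence LASSO screen and the
#' Pearson redundancy pruning around it.  Defaults: prune at |r| >= 0.9
#' before screening, 500 screening models per step on stratified 80%
#' subsamples, keep features whose selection frequency exceeds the median of
#' the nonzero frequencies (two passes), then prune survivors at |r| >= 0.8.
#'
#' @param prune_r_primary correlation threshold for the initial prune.
#' @param prune_r_final correlation threshold for the final prune.
#' @param n_screen_models L1 models per screening step (>= 100).
#' @param subsample_frac fraction of training patients per screening model.
#' @param keep_frequency_quantile quantile of nonzero frequencies a feature
#'   must exceed to survive a screening step.
#' @param n_lambda,lambda_min_ratio geometry of the L1 path (lambda_max down
#'   to `lambda_min_ratio * lambda_max`).
#' @param seed integer seed.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(prune_r_primary = 0.9, prune_r_final = 0.8,
                          n_screen_models = 500L, subsample_frac = 0.8,
                          keep_frequency_quantile = 0.5,
                          n_lambda = 100L, lambda_min_ratio = 1e-4,
                          seed = 1L) {
  if (!(prune_r_primary > 0 && prune_r_primary < 1) ||
      !(prune_r_final > 0 && prune_r_final < 1))
    stop("correlation thresholds must be in (0,1)")
  if (n_screen_models < 100L) stop("n_screen_models must be >= 100")
  structure(
    list(prune_r_primary = prune_r_primary, prune_r_final = prune_r_final,
         n_screen_models = as.integer(n_screen_models),
         subsample_frac = subsample_frac,
         keep_frequency_quantile = keep_frequency_quantile,
         n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio, seed = as.integer(seed)),
    class = "screen_config"
  )
}

#' z-score every feature column
#'
#' Centres and scales each column to mean 0, SD 1 (sample SD, n - 1).  The
#' transformation parameters are stored as attributes so held-out patients
#' can be transformed with the training parameters via [apply_zscore()]
#' rather than their own (the no-leakage contract).
#'
#' @param table a [feature_table()].
#' @return The transformed [feature_table()] with attributes `center` and
#'   `scale`.
#' @export
zscore_features <- function(table) {
  X <- table$features
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  const <- which(!is.finite(scl) | scl == 0)
  if (length(const))
    stop("constant feature(s): ", paste(colnames(X)[const], collapse = ", "))
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  out <- feature_table(Z, table$label, table$provenance)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Apply stored z-score parameters to held-out patients
#'
#' @param table a [feature_table()] of held-out patients.
#' @param trained the output of [zscore_features()] on the training cohort,
#'   or a list with `center` and `scale` vectors.
#' @return The transformed [feature_table()].
#' @export
apply_zscore <- function(table, trained) {
  ctr <- if (!is.null(attr(trained, "center"))) attr(trained, "center") else trained$center
  scl <- if (!is.null(attr(trained, "scale"))) attr(trained, "scale") else trained$scale
  X <- table$features
  ctr <- ctr[colnames(X)]; scl <- scl[colnames(X)]
  if (any(is.na(ctr)) || any(is.na(scl)))
    stop("training parameters missing for some features")
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  feature_table(Z, table$label, table$provenance)
}

#' Greedy Pearson redundancy pruning
#'
#' Repeatedly finds the remaining feature pair with the largest absolute
#' Pearson correlation at or above `r_threshold` and drops the member with
#' the larger mean absolute correlation against all remaining features.
#' Ties (in pair choice and in mean absolute correlation) are broken so the
#' earlier column is retained, making the procedure deterministic given
#' column order.
#'
#' @param table a [feature_table()] (training patients only).
#' @param r_threshold absolute correlation threshold.
#' @return The pruned [feature_table()] with attribute `removals`, a
#'   data.frame audit log of (dropped, partner, r, mean_abs_r).
#' @export
prune_correlated <- function(table, r_threshold = 0.9) {
  X <- table$features
  if (ncol(X) < 2L) return(table)
  R <- abs(stats::cor(X))
  diag(R) <- 0
  keep <- seq_len(ncol(X))
  removals <- list()
  repeat {
    sub <- R[keep, keep, drop = FALSE]
    m <- max(sub)
    if (!is.finite(m) || m < r_threshold) break
    hit <- which(sub == m, arr.ind = TRUE)
    hit <- hit[order(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2])), ,
               drop = FALSE][1, ]
    a <- keep[min(hit)]; b <- keep[max(hit)]
    mean_abs <- function(j) mean(R[j, setdiff(keep, j)])
    ma <- mean_abs(a); mb <- mean_abs(b)
    drop_j <- if (ma > mb) a else b  # tie: drop the later column (b)
    removals[[length(removals) + 1L]] <- data.frame(
      dropped = colnames(X)[drop_j],
      partner = colnames(X)[if (drop_j == a) b else a],
      r = m, mean_abs_r = if (drop_j == a) ma else mb,
      stringsAsFactors = FALSE)
    keep <- setdiff(keep, drop_j)
    if (length(keep) < 2L) break
  }
  out <- subset_table(table, features = keep)
  attr(out, "removals") <- if (length(removals)) do.call(rbind, removals)
  else data.frame(dropped = character(0), partner = character(0),
                  r = numeric(0), mean_abs_r = numeric(0))
  out
}

# ---- shared LASSO helpers --------------------------------------------------

# rank-based Mann-Whitney AUC of scores against binary y
.auc_rank <- function(scores, y) {
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# stratified fold assignment (ids in canonical order for reproducibility)
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# stratified subsample of round(frac * n) patients, at least one per class
.stratified_subsample <- function(y, frac) {
  take <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_take <- max(1L, .round_half_up(frac * length(idx)))
    take <- c(take, sample(idx, min(n_take, length(idx))))
  }
  sort(take)
}

# fit an L1 logistic path; returns NULL when glmnet cannot fit
.lasso_path <- function(X, y, n_lambda, lambda_min_ratio, lambda = NULL) {
  if (length(unique(y)) < 2L) return(NULL)
  tryCatch(
    glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                   nlambda = n_lambda, lambda.min.ratio = lambda_min_ratio,
                   lambda = lambda, standardize = FALSE),
    error = function(e) NULL
  )
}

# inner stratified k-fold CV over a fixed lambda sequence; returns the mean
# held-fold AUC per lambda (NA-safe) or NULL on degenerate folds
.cv_lambda_auc <- function(X, y, lambda_seq, n_folds, n_lambda,
                           lambda_min_ratio, max_redraw = 10L) {
  for (attempt in seq_len(max_redraw)) {
    fold <- .stratified_folds(y, n_folds)
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[fold == f])) == 2L, logical(1)))
    if (ok) break
    if (attempt == max_redraw) return(NULL)
  }
  aucs <- matrix(NA_real_, n_folds, length(lambda_seq))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- .lasso_path(X[tr, , drop = FALSE], y[tr], n_lambda,
                       lambda_min_ratio, lambda = lambda_seq)
    if (is.null(fit)) return(NULL)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE], s = lambda_seq)
    aucs[f, ] <- apply(pred, 2, .auc_rank, y = y[!tr])
  }
  colMeans(aucs, na.rm = TRUE)
}

# ---- frequency screening ---------------------------------------------------

.screen_step <- function(X, y, cfg, n_folds = 3L) {
  p <- ncol(X)
  counts <- stats::setNames(numeric(p), colnames(X))
  n_redraw <- 0L
  model_rows <- vector("list", cfg$n_screen_models)
  for (m in seq_len(cfg$n_screen_models)) {
    repeat {
      sub <- .stratified_subsample(y, cfg$subsample_frac)
      if (length(unique(y[sub])) == 2L) break
      n_redraw <- n_redraw + 1L
    }
    model_rows[[m]] <- rownames(X)[sub]
    Xs <- X[sub, , drop = FALSE]; ys <- y[sub]
    fit <- .lasso_path(Xs, ys, cfg$n_lambda, cfg$lambda_min_ratio)
    if (is.null(fit)) next
    cv_auc <- .cv_lambda_auc(Xs, ys, fit$lambda, n_folds, cfg$n_lambda,
                             cfg$lambda_min_ratio)
    if (is.null(cv_auc)) next
    lam <- fit$lambda[which.max(cv_auc)]
    cf <- as.matrix(stats::coef(fit, s = lam))[-1, 1]
    counts[cf != 0] <- counts[cf != 0] + 1
  }
  freq <- counts / cfg$n_screen_models
  nz <- freq[freq > 0]
  thr <- if (length(nz)) stats::quantile(nz, cfg$keep_frequency_quantile,
                                         names = FALSE) else Inf
  survivors <- names(freq)[freq > thr]
  # degenerate case: all nonzero frequencies equal (e.g. few, always-selected
  # features) -- keep everything at the threshold rather than nothing
  if (!length(survivors)) survivors <- names(freq)[freq >= thr & freq > 0]
  list(frequency = freq, survivors = survivors,
       model_ids = model_rows, n_redraw = n_redraw)
}

#' Frequency-of-occurrence LASSO screening
#'
#' Parts I and II of the three-step screen: for each of `n_screen_models`
#' iterations, draw a class-stratified subsample of the training cohort, fit
#' an L1-penalized logistic regression with the penalty chosen by internal
#' stratified 3-fold cross-validated AUC, and record which features enter
#' the model.  Features whose selection frequency exceeds the configured
#' quantile of nonzero frequencies survive; the procedure runs twice
#' (step 2 on step-1 survivors), after which the survivors are pruned at
#' `prune_r_final` to give the final candidate pool.
#'
#' @param table a z-scored [feature_table()] of training patients only.
#' @param cfg a [screen_config()].
#' @return An object of class `screening_result` with per-step frequencies,
#'   survivor lists, absolute label correlations (for downstream ranking
#'   tie-breaks), and an audit log (subsample ids per model, redraw counts,
#'   prune removals).
#' @export
frequency_screen <- function(table, cfg = screen_config()) {
  X <- table$features
  y <- table$label
  if (length(unique(y)) < 2L) stop("both classes must be present")
  # canonical patient order so frequencies are invariant to row order
  o <- order(rownames(X))
  X <- X[o, , drop = FALSE]; y <- y[o]
  set.seed(cfg$seed)
  s1 <- .screen_step(X, y, cfg)
  if (!length(s1$survivors)) stop("no features survived screening step 1")
  s2 <- .screen_step(X[, s1$survivors, drop = FALSE], y, cfg)
  if (!length(s2$survivors)) stop("no features survived screening step 2")
  tab2 <- feature_table(X[, s2$survivors, drop = FALSE], y)
  pruned <- prune_correlated(tab2, cfg$prune_r_final)
  survivors_final <- colnames(pruned$features)
  label_cor <- abs(stats::cor(X, y))[, 1]
  structure(
    list(frequency = s2$frequency,
         frequency_step1 = s1$frequency,
         survivors_step1 = s1$survivors,
         survivors_step2 = s2$survivors,
         survivors_final = survivors_final,
         label_cor = label_cor,
         audit = list(model_ids_step1 = s1$model_ids,
                      model_ids_step2 = s2$model_ids,
                      n_redraw = s1$n_redraw + s2$n_redraw,
                      prune_removals = attr(pruned, "removals")),
         config = cfg),
    class = "screening_result"
  )
}

#' @exportS3Method base::print
print.screening_result <- function(x, ...) {
  cat(sprintf(paste0("<screening_result> %d -> %d -> %d -> %d features ",
                     "(final after |r| >= %.2f prune)\n"),
              length(x$frequency_step1), length(x$survivors_step1),
              length(x$survivors_step2), length(x$survivors_final),
              x$config$prune_r_final))
  invisible(x)
}

#' Serialize a screening result to JSON
#'
#' @param x a `screening_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_screening_result <- function(x, path) {
  jsonlite::write_json(
    list(frequency = as.list(x$frequency),
         frequency_step1 = as.list(x$frequency_step1),
         survivors_step1 = x$survivors_step1,
         survivors_step2 = x$survivors_step2,
         survivors_final = x$survivors_final,
         n_redraw = x$audit$n_redraw,
         config_hash = rlang::hash(x$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
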