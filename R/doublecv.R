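#' Double cross-validation configuration
#'
#' Part III of the screening methodology: `n_resamples` class-balanced
#' resamples of the training cohort, each tuned by `n_repeats` repetitions of
#' stratified `n_folds`-fold cross-validation over the L1 path, evaluated
#' for every candidate feature-set size in `set_sizes`.  The defaults
#' (100 x 20, 3 folds, sizes 3..10) yield 2,000 final models per candidate
#' feature set and 8 candidate sets.
#'
#' @param n_resamples outer balanced resamples.
#' @param n_repeats nested-CV repetitions per resample.
#' @param n_folds folds of the nested cross-validation.
#' @param set_sizes increasing vector of candidate feature-set sizes.
#' @param build_frac fraction of the training cohort in the model-building
#'   part of each resample (2:1 split by default).
#' @param n_lambda,lambda_min_ratio geometry of the L1 path.
#' @param plateau_delta AUC-gain threshold of the plateau rule used by
#'   [select_optimal_set()].
#' @param seed integer seed.
#' @return list of class `doublecv_config`.
#' @export
doublecv_config <- function(n_resamples = 100L, n_repeats = 20L,
                            n_folds = 3L, set_sizes = 3:10,
                            build_frac = 2 / 3,
                            n_lambda = 100L, lambda_min_ratio = 1e-4,
                            plateau_delta = 0.01, seed = 1L) {
  set_sizes <- as.integer(set_sizes)
  if (!length(set_sizes) || is.unsorted(set_sizes, strictly = TRUE))
    stop("`set_sizes` must be non-empty and increasing")
  structure(
    list(n_resamples = as.integer(n_resamples),
         n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
         set_sizes = set_sizes, build_frac = build_frac,
         n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio,
         plateau_delta = plateau_delta, seed = as.integer(seed)),
    class = "doublecv_config"
  )
}

#' Order screened features for top-k candidate sets
#'
#' Final survivors ordered by descending selection frequency; ties broken by
#' descending absolute point-biserial correlation with the label, then by
#' name.  The top-k prefixes of this ordering define the candidate feature
#' sets of the double cross-validation.
#'
#' @param screening a `screening_result` from [frequency_screen()].
#' @return character vector of ordered feature names.
#' @export
rank_features <- function(screening) {
  feats <- screening$survivors_final
  if (!length(feats)) stop("no surviving features to rank")
  freq <- screening$frequency[feats]
  lc <- screening$label_cor[feats]
  feats[order(-freq, -lc, feats)]
}

#' Class-balanced resample of the training cohort
#'
#' Stratified random split of the training cohort into a model-building part
#' (`build_frac`, default 2/3) and an internal-validation part, keeping each
#' part's class proportion within one patient of the cohort's.
#'
#' @param train_labels named binary vector of training-cohort labels.
#' @param build_frac model-building fraction.
#' @param n_folds folds of the downstream nested CV (each class must have at
#'   least this many members in the building part).
#' @return list with id vectors `build` and `internal`.
#' @export
balanced_resample <- function(train_labels, build_frac = 2 / 3, n_folds = 3L) {
  y <- train_labels
  if (length(unique(y)) < 2L) stop("both classes required")
  build <- character(0)
  for (cls in c(0L, 1L)) {
    ids <- sort(names(y)[y == cls])
    n_take <- .round_half_up(build_frac * length(ids))
    n_take <- min(max(n_take, 1L), length(ids) - 1L)
    if (n_take < n_folds)
      stop("class ", cls, " has fewer than n_folds members in the ",
           "model-building part; use a smaller n_folds")
    build <- c(build, sample(ids, n_take))
  }
  build <- sort(build)
  list(build = build, internal = sort(setdiff(names(y), build)))
}

#' Nested lambda tuning on a model-building part
#'
#' One repetition: stratified `n_folds`-fold CV over the L1 path, choosing
#' the lambda that maximizes the mean held-fold AUC, then one final model at
#' that lambda fitted on the whole model-building part.  Degenerate folds
#' are redrawn (and counted).
#'
#' @param X z-scored predictor matrix (model-building patients).
#' @param y binary labels.
#' @param cfg a [doublecv_config()].
#' @return list with `lambda`, the fitted glmnet path `fit`, and the CV AUC
#'   curve `cv_auc`; `NULL` if no valid fit was possible.
#' @export
tune_lambda_nested <- function(X, y, cfg = doublecv_config()) {
  fit <- .lasso_path(X, y, cfg$n_lambda, cfg$lambda_min_ratio)
  if (is.null(fit)) return(NULL)
  cv_auc <- .cv_lambda_auc(X, y, fit$lambda, cfg$n_folds, cfg$n_lambda,
                           cfg$lambda_min_ratio)
  if (is.null(cv_auc)) return(NULL)
  best <- which.max(cv_auc)  # ties: first index = largest lambda = sparsest
  list(lambda = fit$lambda[best], fit = fit, cv_auc = cv_auc)
}

#' Run the class-balanced double cross-validation
#'
#' For each candidate set size k, restricts the predictors to the top-k
#' ranked features, then for each of `n_resamples` balanced resamples and
#' `n_repeats` nested-CV repetitions fits one final L1 logistic model and
#' scores its AUC on (a) the full training cohort and (b) the untouched
#' testing cohort.  Exactly `n_resamples * n_repeats` models are trained per
#' set size.  The testing cohort never enters any fit, fold, or lambda
#' choice; the audit log records the model-building ids of every resample so
#' this is checkable.
#'
#' @param table a z-scored [feature_table()] covering training and testing
#'   patients (testing rows transformed with training parameters).
#' @param ranking ordered feature names (from [rank_features()], or any
#'   character vector).
#' @param train_ids,test_ids disjoint patient id vectors.
#' @param cfg a [doublecv_config()].
#' @return An object of class `cv_result`: long-format `models` data.frame
#'   (set_size, resample, repetition, lambda, auc_train, auc_test), per-size
#'   `summary` with means and 95% CIs, the ranking used, and an `audit` list.
#' @export
run_double_cv <- function(table, ranking, train_ids, test_ids,
                          cfg = doublecv_config()) {
  if (length(intersect(train_ids, test_ids)))
    stop("train and test cohorts overlap")
  if (max(cfg$set_sizes) > length(ranking))
    stop("ranking has fewer features than max(set_sizes)")
  X <- table$features
  y <- stats::setNames(table$label, rownames(X))
  if (length(unique(y[test_ids])) < 2L)
    stop("testing cohort must contain both classes for AUC")
  ytr <- y[train_ids]
  set.seed(cfg$seed)
  rows <- vector("list", length(cfg$set_sizes))
  build_log <- list()
  for (si in seq_along(cfg$set_sizes)) {
    k <- cfg$set_sizes[si]
    feats <- ranking[seq_len(k)]
    out <- vector("list", cfg$n_resamples * cfg$n_repeats)
    pos <- 0L
    for (r in seq_len(cfg$n_resamples)) {
      rs <- balanced_resample(ytr, cfg$build_frac, cfg$n_folds)
      build_log[[length(build_log) + 1L]] <-
        list(set_size = k, resample = r, build = rs$build)
      Xb <- X[rs$build, feats, drop = FALSE]
      yb <- y[rs$build]
      for (rep in seq_len(cfg$n_repeats)) {
        tune <- tune_lambda_nested(Xb, yb, cfg)
        pos <- pos + 1L
        if (is.null(tune)) {
          out[[pos]] <- data.frame(set_size = k, resample = r,
                                   repetition = rep, lambda = NA_real_,
                                   auc_train = NA_real_, auc_test = NA_real_)
          next
        }
        pr_train <- stats::predict(tune$fit, X[train_ids, feats, drop = FALSE],
                                   s = tune$lambda)[, 1]
        pr_test <- stats::predict(tune$fit, X[test_ids, feats, drop = FALSE],
                                  s = tune$lambda)[, 1]
        out[[pos]] <- data.frame(
          set_size = k, resample = r, repetition = rep, lambda = tune$lambda,
          auc_train = .auc_rank(pr_train, y[train_ids]),
          auc_test = .auc_rank(pr_test, y[test_ids]))
      }
    }
    rows[[si]] <- do.call(rbind, out)
  }
  models <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(models, models$set_size), function(d) {
    tr <- summarize_ci(d$auc_train[!is.na(d$auc_train)])
    te <- summarize_ci(d$auc_test[!is.na(d$auc_test)])
    data.frame(set_size = d$set_size[1], n_models = nrow(d),
               mean_auc_train = tr[["mean"]], ci_lo_train = tr[["lo95"]],
               ci_hi_train = tr[["hi95"]], mean_auc_test = te[["mean"]],
               ci_lo_test = te[["lo95"]], ci_hi_test = te[["hi95"]])
  }))
  rownames(summary) <- NULL
  leakage_free <- !any(vapply(build_log, function(b)
    length(intersect(b$build, test_ids)) > 0, logical(1)))
  structure(
    list(models = models, summary = summary, ranking = ranking,
         train_ids = train_ids, test_ids = test_ids,
         audit = list(build_log = build_log,
                      n_models_per_size = table(models$set_size),
                      leakage_free = leakage_free),
         config = cfg),
    class = "cv_result"
  )
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat("<cv_result>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Plateau-based optimal feature-set size
#'
#' The optimal size is the smallest k such that adding one more feature
#' improves the mean testing AUC by less than `delta` while the 95% CIs of k
#' and k+1 overlap.  Without any plateau the size with the maximal mean
#' testing AUC is returned and flagged.
#'
#' @param result a `cv_result`.
#' @param delta AUC-gain threshold (defaults to the config's
#'   `plateau_delta`).
#' @return list with `k`, the selected `features`, and `plateau` (logical;
#'   `FALSE` means the fallback argmax branch fired).
#' @export
select_optimal_set <- function(result, delta = NULL) {
  s <- result$summary[order(result$summary$set_size), ]
  if (nrow(s) < 2L) stop("need at least two set sizes")
  if (is.null(delta)) delta <- result$config$plateau_delta
  k_star <- NA_integer_
  for (i in seq_len(nrow(s) - 1L)) {
    gain <- s$mean_auc_test[i + 1L] - s$mean_auc_test[i]
    overlap <- s$ci_lo_test[i + 1L] <= s$ci_hi_test[i] &&
      s$ci_lo_test[i] <= s$ci_hi_test[i + 1L]
    if (gain < delta && overlap) { k_star <- s$set_size[i]; break }
  }
  plateau <- !is.na(k_star)
  if (!plateau) k_star <- s$set_size[which.max(s$mean_auc_test)]
  list(k = k_star, features = result$ranking[seq_len(k_star)],
       plateau = plateau)
}

#' Write a cv_result to CSV (long format) and JSON summary
#'
#' @param x a `cv_result`.
#' @param prefix output path prefix; writes `<prefix>_models.csv` and
#'   `<prefix>_summary.csv`.
#' @return character vector of the written paths, invisibly.
#' @export
write_cv_result <- function(x, prefix) {
  p1 <- paste0(prefix, "_models.csv")
  p2 <- paste0(prefix, "_summary.csv")
  utils::write.csv(x$models, p1, row.names = FALSE)
  utils::write.csv(x$summary, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
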