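# small screened table shared by the double-CV tests
dcv_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- generate_feature_table(70, 24, 4, 1.5, seed = 33)
      sp <- split_cohort(tab, 51, seed = 33)
      z <- zscore_features(subset_table(tab, patients = sp$train))
      zt <- apply_zscore(subset_table(tab, patients = sp$test), z)
      zall <- feature_table(rbind(z$features, zt$features),
                           c(z$label, zt$label))
      cache <<- list(tab = tab, sp = sp, zall = zall,
                     ranking = colnames(tab$features))
    }
    cache
  }
})

test_that("rank_features sorts by frequency with documented tie-breaks", {
  scr <- structure(
    list(survivors_final = c("A", "B", "C"),
         frequency = c(A = 0.9, B = 0.4, C = 0.7),
         label_cor = c(A = 0.2, B = 0.1, C = 0.3)),
    class = "screening_result")
  expect_identical(rank_features(scr), c("A", "C", "B"))
  # tie on frequency resolved by label correlation, then name
  scr$frequency <- c(A = 0.5, B = 0.5, C = 0.5)
  scr$label_cor <- c(A = 0.1, B = 0.3, C = 0.2)
  expect_identical(rank_features(scr), c("B", "C", "A"))
  scr$label_cor <- c(A = 0.1, B = 0.1, C = 0.1)
  expect_identical(rank_features(scr), c("A", "B", "C"))
  expect_identical(rank_features(scr), rank_features(scr))
})

test_that("balanced resamples keep stratified 2:1 arithmetic", {
  y <- stats::setNames(c(rep(0L, 41), rep(1L, 10)), sprintf("P%02d", 1:51))
  set.seed(1)
  rs <- balanced_resample(y)
  expect_length(rs$build, 27 + 7)
  expect_true(sum(y[rs$build]) %in% c(6, 7))
  expect_identical(sort(c(rs$build, rs$internal)), sort(names(y)))
  # same seed, same split
  set.seed(99); r1 <- balanced_resample(y)
  set.seed(99); r2 <- balanced_resample(y)
  expect_identical(r1, r2)
  # coverage: over 100 resamples every patient appears in building parts
  set.seed(3)
  seen <- character(0)
  for (i in 1:100) seen <- union(seen, balanced_resample(y)$build)
  expect_setequal(seen, names(y))
  # too-small class errors with advice
  tiny <- stats::setNames(c(rep(0L, 10), rep(1L, 3)), sprintf("Q%02d", 1:13))
  expect_error(balanced_resample(tiny, n_folds = 3), "n_folds")
})

test_that("nested tuning recovers a separating feature and lambda_max is null", {
  set.seed(41)
  n <- 36
  y <- rep_len(c(0L, 1L), n)
  X <- cbind(sig = y * 3 + stats::rnorm(n, 0, 0.4),
             n1 = stats::rnorm(n), n2 = stats::rnorm(n))
  rownames(X) <- sprintf("P%02d", 1:n)
  hits <- 0
  for (rep in 1:20) {
    tune <- tune_lambda_nested(X, y, doublecv_config())
    cf <- as.matrix(stats::coef(tune$fit, s = tune$lambda))[-1, 1]
    if (cf[["sig"]] != 0) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% of repetitions select the true feature
  # at the head of the path (lambda_max) every coefficient is zero
  fit <- tune$fit
  expect_equal(sum(as.matrix(stats::coef(fit, s = fit$lambda[1]))[-1, 1] != 0), 0)
})

test_that("pure-noise tuning gives chance-level nested CV AUC", {
  set.seed(43)
  aucs <- vapply(1:10, function(i) {
    n <- 40
    y <- rep_len(c(0L, 1L), n)
    X <- matrix(stats::rnorm(n * 6), n, 6,
                dimnames = list(sprintf("P%02d", 1:n), paste0("f", 1:6)))
    tune <- tune_lambda_nested(X, y, doublecv_config())
    max(tune$cv_auc)
  }, numeric(1))
  # optimistically biased by the max, but still near chance on average
  expect_lt(mean(aucs), 0.72)
  expect_gt(mean(aucs), 0.4)
})

test_that("double CV trains the exact model count and scales exactly", {
  fx <- dcv_fixture()
  cfg <- doublecv_config(n_resamples = 10, n_repeats = 2, set_sizes = 3:10,
                         seed = 44)
  cv <- suppressWarnings(run_double_cv(fx$zall, fx$ranking, fx$sp$train,
                                       fx$sp$test, cfg))
  expect_equal(length(unique(cv$models$set_size)), 8)
  counts <- table(cv$models$set_size)
  expect_true(all(counts == 10 * 2))
  expect_equal(nrow(cv$models), 8 * 20)
  expect_true(all(cv$models$auc_train >= 0 & cv$models$auc_train <= 1,
                  na.rm = TRUE))
  expect_true(all(cv$summary$ci_lo_test <= cv$summary$ci_hi_test))
  # determinism under a fixed seed
  cv2 <- suppressWarnings(run_double_cv(fx$zall, fx$ranking, fx$sp$train,
                                        fx$sp$test, cfg))
  expect_equal(cv$models, cv2$models)
  # guards
  expect_error(run_double_cv(fx$zall, fx$ranking[1:5], fx$sp$train,
                             fx$sp$test, cfg), "fewer features")
  expect_error(run_double_cv(fx$zall, fx$ranking, fx$sp$train,
                             fx$sp$train[1:5], cfg), "overlap")
})

test_that("the testing cohort never enters any fit (leakage audit)", {
  fx <- dcv_fixture()
  cfg <- doublecv_config(n_resamples = 5, n_repeats = 2, set_sizes = c(3, 5),
                         seed = 45)
  cv <- suppressWarnings(run_double_cv(fx$zall, fx$ranking, fx$sp$train,
                                       fx$sp$test, cfg))
  expect_true(cv$audit$leakage_free)
  for (b in cv$audit$build_log) {
    expect_length(intersect(b$build, fx$sp$test), 0)
    expect_true(all(b$build %in% fx$sp$train))
  }
})

test_that("signal-free cohorts stay at chance-level testing AUC", {
  aucs <- c()
  for (s in 1:6) {
    tab <- generate_feature_table(60, 30, 0, 0, prevalence = 0.25,
                                  seed = 500 + s)
    sp <- split_cohort(tab, 44, seed = s)
    z <- zscore_features(subset_table(tab, patients = sp$train))
    zt <- apply_zscore(subset_table(tab, patients = sp$test), z)
    zall <- feature_table(rbind(z$features, zt$features), c(z$label, zt$label))
    cv <- suppressWarnings(run_double_cv(
      zall, colnames(tab$features)[1:6], sp$train, sp$test,
      doublecv_config(n_resamples = 5, n_repeats = 2, set_sizes = c(3, 5),
                      seed = s)))
    aucs <- c(aucs, cv$summary$mean_auc_test)
  }
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("the plateau rule selects the documented k*", {
  mk <- function(means, half = 0.02) {
    structure(list(
      summary = data.frame(
        set_size = seq(3, by = 1, length.out = length(means)),
        mean_auc_test = means,
        ci_lo_test = means - half, ci_hi_test = means + half),
      ranking = letters[1:15],
      config = doublecv_config()), class = "cv_result")
  }
  # gain < delta with overlapping CIs at 5 -> 6: k* = 5
  r <- select_optimal_set(mk(c(0.70, 0.80, 0.85, 0.851, 0.852)))
  expect_equal(r$k, 5)
  expect_true(r$plateau)
  expect_identical(r$features, letters[1:5])
  # strictly increasing, non-overlapping CIs: fallback to argmax, flagged
  r2 <- select_optimal_set(mk(c(0.6, 0.7, 0.8, 0.9), half = 0.001))
  expect_equal(r2$k, 6)
  expect_false(r2$plateau)
  # flat from the start: k* = 3
  r3 <- select_optimal_set(mk(c(0.8, 0.8, 0.8)))
  expect_equal(r3$k, 3)
})

test_that("cv results serialize to long-format CSV", {
  fx <- dcv_fixture()
  cv <- suppressWarnings(run_double_cv(
    fx$zall, fx$ranking, fx$sp$train, fx$sp$test,
    doublecv_config(n_resamples = 3, n_repeats = 2, set_sizes = c(3, 4),
                    seed = 46)))
  prefix <- file.path(withr::local_tempdir(), "cv")
  paths <- write_cv_result(cv, prefix)
  models <- utils::read.csv(paste0(prefix, "_models.csv"))
  expect_identical(names(models),
                   c("set_size", "resample", "repetition", "lambda",
                     "auc_train", "auc_test"))
  expect_equal(nrow(models), 2 * 6)
})
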