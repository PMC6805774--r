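test_that("z-scoring centres and scales with the sample-SD convention", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  rownames(X) <- c("P1", "P2", "P3")
  tab <- feature_table(X, c(0, 1, 0),
                       provenance = parse_feature_names(colnames(X)))
  z <- zscore_features(tab)
  expect_equal(unname(z$features[, "a"]), c(-1, 0, 1))  # sample SD of 1:3 is 1
  expect_true(all(abs(colMeans(z$features)) < 1e-10))
  expect_equal(unname(apply(z$features, 2, stats::sd)), c(1, 1))
  # idempotence
  z2 <- zscore_features(z)
  expect_equal(z2$features, z$features, tolerance = 1e-12)
  # constant column errors by name
  Xc <- cbind(X, cst = c(5, 5, 5))
  expect_error(zscore_features(feature_table(Xc, c(0, 1, 0),
                                             parse_feature_names(colnames(Xc)))),
               "cst")
})

test_that("held-out patients are transformed with training parameters", {
  tab <- generate_feature_table(30, 6, 2, 1, seed = 8)
  sp <- split_cohort(tab, 20, seed = 8)
  ztr <- zscore_features(subset_table(tab, patients = sp$train))
  zte <- apply_zscore(subset_table(tab, patients = sp$test), ztr)
  # reconstruct manually from stored parameters
  ctr <- attr(ztr, "center"); scl <- attr(ztr, "scale")
  raw <- subset_table(tab, patients = sp$test)$features
  manual <- sweep(sweep(raw, 2, ctr, "-"), 2, scl, "/")
  expect_equal(zte$features, manual)
  # and *not* with its own parameters
  expect_gt(max(abs(colMeans(zte$features))), 1e-6)
})

test_that("correlation pruning matches a brute-force oracle and is stable", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 40
    f <- stats::rnorm(n)
    X <- cbind(a = f + stats::rnorm(n, 0, 0.1),
               b = f + stats::rnorm(n, 0, 0.1),
               c = f + stats::rnorm(n, 0, 0.3),
               d = stats::rnorm(n),
               e = stats::rnorm(n))
    rownames(X) <- sprintf("P%02d", 1:n)
    tab <- feature_table(X, rep_len(c(0, 1), n),
                         provenance = parse_feature_names(colnames(X)))
    pruned <- prune_correlated(tab, 0.9)
    expect_identical(colnames(pruned$features), oracle_prune(X, 0.9))
  }
  # identical columns: exactly one of the duplicates dropped
  X <- cbind(x1 = 1:10 + 0, x2 = 1:10 + 0, y = stats::rnorm(10))
  rownames(X) <- sprintf("P%02d", 1:10)
  tab <- feature_table(X, rep_len(c(0, 1), 10),
                       provenance = parse_feature_names(colnames(X)))
  pruned <- prune_correlated(tab, 0.9)
  expect_length(intersect(colnames(pruned$features), c("x1", "x2")), 1)
  expect_true("y" %in% colnames(pruned$features))
  # all below threshold: identity
  set.seed(9)
  Xu <- matrix(stats::rnorm(200), 50, 4,
               dimnames = list(sprintf("P%02d", 1:50), letters[1:4]))
  tabu <- feature_table(Xu, rep_len(c(0, 1), 50),
                        provenance = parse_feature_names(colnames(Xu)))
  expect_identical(colnames(prune_correlated(tabu, 0.9)$features),
                   colnames(Xu))
})

test_that("screening finds planted informative features", {
  tab <- generate_feature_table(70, 105, 5, 1.5, seed = 11)
  sp <- split_cohort(tab, 51, seed = 11)
  z <- zscore_features(subset_table(tab, patients = sp$train))
  pr <- prune_correlated(z, 0.9)
  cfg <- screen_config(n_screen_models = 120, seed = 5)
  scr <- suppressWarnings(frequency_screen(pr, cfg))
  top10 <- names(sort(scr$frequency_step1, decreasing = TRUE))[1:10]
  expect_equal(sum(grepl("informative", top10)), 5)
  # survivors nest and no surviving pair is correlated at >= 0.8
  expect_true(all(scr$survivors_step2 %in% scr$survivors_step1))
  expect_true(all(scr$survivors_final %in% scr$survivors_step2))
  R <- abs(stats::cor(z$features[, scr$survivors_final, drop = FALSE]))
  diag(R) <- 0
  expect_lt(max(R), 0.8)
  # frequencies in [0,1], reproducible bit-for-bit under the same seed
  expect_true(all(scr$frequency >= 0 & scr$frequency <= 1))
  scr2 <- suppressWarnings(frequency_screen(pr, cfg))
  expect_identical(scr$frequency, scr2$frequency)
  expect_identical(scr$survivors_final, scr2$survivors_final)
})

test_that("screening frequencies are invariant to patient row order", {
  tab <- generate_feature_table(40, 30, 3, 1.5, prevalence = 0.3, seed = 13)
  z <- zscore_features(tab)
  cfg <- screen_config(n_screen_models = 100, seed = 3)
  s1 <- suppressWarnings(frequency_screen(z, cfg))
  perm <- sample(nrow(z$features))
  zp <- subset_table(z, patients = perm)
  s2 <- suppressWarnings(frequency_screen(zp, cfg))
  expect_identical(s1$frequency, s2$frequency)
})

test_that("permuted labels give no stable frequency signal", {
  tab <- generate_feature_table(60, 40, 4, 1.5, prevalence = 0.25, seed = 17)
  z <- zscore_features(tab)
  cfg <- screen_config(n_screen_models = 100, seed = 1)
  real <- suppressWarnings(frequency_screen(z, cfg))
  real_top <- max(real$frequency_step1)
  null_top <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    zperm <- feature_table(z$features, sample(z$label), z$provenance)
    sp <- suppressWarnings(tryCatch(
      frequency_screen(zperm, screen_config(n_screen_models = 100,
                                            seed = 2000 + s)),
      error = function(e) NULL))
    if (is.null(sp)) 0 else max(sp$frequency_step1)
  }, numeric(1))
  # the real top frequency beats the permutation-null band
  expect_gt(real_top, stats::quantile(null_top, 0.95) - 0.05)
  expect_gt(real_top, mean(null_top))
})

test_that("duplicated informative features collapse to one after the final prune", {
  blk <- list(list(features = c(1, 2), rho = 1))  # duplicate informative pair
  tab <- generate_feature_table(60, 30, 2, 1.8, block_correlation = blk,
                                prevalence = 0.3, seed = 19)
  # the duplicate block makes columns 1 and 2 identical; re-inject the effect
  z <- zscore_features(tab)
  scr <- suppressWarnings(
    frequency_screen(z, screen_config(n_screen_models = 100, seed = 4)))
  dup <- intersect(scr$survivors_final,
                   colnames(tab$features)[1:2])
  expect_lte(length(dup), 1)
})

test_that("no test-set patient enters any screening fit (audit)", {
  tab <- generate_feature_table(50, 20, 3, 1.5, prevalence = 0.3, seed = 23)
  sp <- split_cohort(tab, 36, seed = 23)
  z <- zscore_features(subset_table(tab, patients = sp$train))
  scr <- suppressWarnings(
    frequency_screen(z, screen_config(n_screen_models = 100, seed = 6)))
  used <- unique(unlist(c(scr$audit$model_ids_step1,
                          scr$audit$model_ids_step2)))
  expect_length(intersect(used, sp$test), 0)
  expect_true(all(used %in% sp$train))
})

test_that("screening result serializes to JSON", {
  tab <- generate_feature_table(40, 12, 2, 1.5, prevalence = 0.3, seed = 29)
  z <- zscore_features(tab)
  scr <- suppressWarnings(
    frequency_screen(z, screen_config(n_screen_models = 100, seed = 7)))
  path <- withr::local_tempfile(fileext = ".json")
  write_screening_result(scr, path)
  back <- jsonlite::read_json(path)
  expect_identical(unlist(back$survivors_final), scr$survivors_final)
  expect_equal(back$frequency[[scr$survivors_step1[1]]],
               unname(scr$frequency[scr$survivors_step1[1]]))
})
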