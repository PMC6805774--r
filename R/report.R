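#' Area under the ROC curve by rank concordance
#'
#' Mann-Whitney statistic: the probability a random positive scores above a
#' random negative, with ties counting one half.
#'
#' @param scores numeric prediction scores (finite).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  .auc_rank(scores, labels)
}

#' Mean and normal-approximation 95% confidence interval
#'
#' `mean +- 1.96 * SD / sqrt(n)` with the population SD (n divisor),
#' clipped to \[0, 1\] (AUC scale).
#'
#' @param auc_vector numeric vector of at least 2 AUC values.
#' @return named vector (mean, lo95, hi95).
#' @export
summarize_ci <- function(auc_vector) {
  if (length(auc_vector) < 2L) stop("need at least 2 values")
  m <- mean(auc_vector)
  half <- 1.96 * sqrt(mean((auc_vector - m)^2) / length(auc_vector))
  c(mean = m, lo95 = max(m - half, 0), hi95 = min(m + half, 1))
}

#' Pipeline run configuration
#'
#' Ties all stage configurations together with the model variant and a
#' single global seed.  The variant selects which channel's features enter
#' the analysis; `joint` concatenates both channels' feature columns before
#' any pruning (958 columns with the default extractor).
#'
#' @param variant one of `"CET1"`, `"T2"`, `"joint"`.
#' @param cohort a [cohort_spec()] for the synthetic image path, or `NULL`
#'   when `feature_csv` is given.
#' @param feature_csv optional path of a pre-computed feature table CSV
#'   (layout of [write_feature_table()]).
#' @param prep a [prep_config()].
#' @param screen a [screen_config()].
#' @param doublecv a [doublecv_config()].
#' @param seed global seed; stage seeds are derived from it.
#' @param output_dir directory for artifacts; `NULL` disables writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(variant = c("joint", "CET1", "T2"),
                       cohort = cohort_spec(), feature_csv = NULL,
                       prep = prep_config(), screen = screen_config(),
                       doublecv = doublecv_config(), seed = 1L,
                       output_dir = NULL) {
  variant <- match.arg(variant)
  seed <- as.integer(seed)
  # derived per-stage seeds, kept below 2^31
  cohort$seed <- seed
  screen$seed <- (seed * 1000L + 1L) %% .Machine$integer.max
  doublecv$seed <- (seed * 1000L + 2L) %% .Machine$integer.max
  structure(
    list(variant = variant, cohort = cohort, feature_csv = feature_csv,
         prep = prep, screen = screen, doublecv = doublecv, seed = seed,
         output_dir = output_dir),
    class = "run_config"
  )
}

.variant_channels <- function(variant) {
  switch(variant, CET1 = "CET1", T2 = "T2", joint = c("CET1", "T2"))
}

#' Run the full pipeline
#'
#' Executes cohort generation (or feature-table loading), preprocessing and
#' extraction (image path only), the train/test split, training-side
#' z-scoring, redundancy pruning, frequency screening, the double
#' cross-validation over the candidate set sizes, and the plateau selection
#' of the optimal feature set.  When `cfg$output_dir` is set, writes the
#' feature table (CSV), screening result (JSON), model-level and summary CV
#' tables (CSV) and a provenance manifest (JSON with the config hash); every
#' artifact is reproducible byte-for-byte from the global seed.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return list with the feature table, split, screening result, ranking,
#'   `cv` (a `cv_result`), `optimal` (from [select_optimal_set()]), and the
#'   config hash.
#' @export
run_pipeline <- function(cfg = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  channels <- .variant_channels(cfg$variant)

  table <- stage("input", {
    if (!is.null(cfg$feature_csv)) {
      say("loading feature table ", cfg$feature_csv)
      tab <- read_feature_table(cfg$feature_csv)
      keep <- tab$provenance$channel %in% channels
      # tables without per-channel provenance (e.g. synthetic ones) are
      # used whole regardless of variant
      if (any(keep)) tab <- subset_table(tab, features = which(keep))
      tab
    } else {
      say("generating synthetic cohort (n=", cfg$cohort$n_patients, ")")
      cohort <- generate_cohort(cfg$cohort)
      say("preprocessing and extracting features")
      extract_cohort(cohort, cfg$prep, channels = channels, verbose = verbose)
    }
  })

  split <- stage("split", {
    n_train <- if (!is.null(cfg$cohort)) cfg$cohort$n_train
    else .round_half_up(0.73 * nrow(table$features))
    split_cohort(table, n_train = n_train, seed = cfg$seed)
  })

  screened <- stage("screen", {
    train_tab <- subset_table(table, patients = split$train)
    ztrain <- zscore_features(train_tab)
    pruned <- prune_correlated(ztrain, cfg$screen$prune_r_primary)
    say("pruned at |r| >= ", cfg$screen$prune_r_primary, ": ",
        ncol(pruned$features), " features remain")
    scr <- frequency_screen(pruned, cfg$screen)
    say("screening survivors: ", length(scr$survivors_final))
    list(zscore = ztrain, pruned = pruned, screening = scr)
  })

  cv <- stage("doublecv", {
    ranking <- rank_features(screened$screening)
    dcfg <- cfg$doublecv
    dcfg$set_sizes <- dcfg$set_sizes[dcfg$set_sizes <= length(ranking)]
    if (length(dcfg$set_sizes) < 2L)
      stop("fewer than two candidate set sizes are supported by the ",
           length(ranking), " surviving features")
    ztest <- apply_zscore(subset_table(table, patients = split$test),
                          screened$zscore)
    zall <- feature_table(
      rbind(screened$zscore$features, ztest$features),
      c(screened$zscore$label, ztest$label))
    run_double_cv(zall, ranking, split$train, split$test, dcfg)
  })
  optimal <- select_optimal_set(cv)

  # hash the scientific configuration only, not where artifacts land
  cfg_hashed <- cfg
  cfg_hashed$output_dir <- NULL
  config_hash <- rlang::hash(cfg_hashed)
  result <- list(table = table, split = split,
                 screening = screened$screening,
                 ranking = cv$ranking, cv = cv, optimal = optimal,
                 config_hash = config_hash)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(cfg$output_dir, f)
    write_feature_table(table, out("features.csv"))
    write_screening_result(screened$screening, out("screening.json"))
    write_cv_result(cv, out("cv"))
    summary_tab <- cbind(variant = cfg$variant, cv$summary,
                         config_hash = config_hash)
    utils::write.csv(summary_tab, out("summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(variant = cfg$variant, seed = cfg$seed,
           config_hash = config_hash,
           n_patients = nrow(table$features),
           n_features = ncol(table$features),
           optimal_k = optimal$k, optimal_features = optimal$features,
           plateau = optimal$plateau,
           leakage_free = cv$audit$leakage_free,
           r_version = as.character(getRversion())),
      out("manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}
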