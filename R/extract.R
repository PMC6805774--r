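#' Extract the full 479-feature vector for one channel of one patient
#'
#' Shape features are computed once on the (resampled) tumor mask geometry;
#' first-order and texture features are computed on the original normalized
#' image and on each of the four LoG-filtered images, each discretized
#' independently with the fixed bin width.  With the default configuration
#' this yields 14 shape + 5 x 18 first-order + 5 x 75 texture = 479 features,
#' named `<channel>_<filter>_<family>_<feature>`.
#'
#' @param prep output of [preprocess_image()] (filtered images + masks).
#' @param cfg a [prep_config()].
#' @return named numeric vector of 479 features (under defaults).
#' @export
extract_channel_features <- function(prep, cfg = prep_config()) {
  channel <- prep$images[[1]]$channel
  tumor <- prep$tumor
  out <- numeric(0)
  shp <- extract_shape(tumor)
  names(shp) <- sprintf("%s_original_shape_%s", channel, names(shp))
  out <- c(out, shp)
  for (tag in names(prep$images)) {
    img <- prep$images[[tag]]
    fo <- extract_firstorder(img, tumor, cfg)
    names(fo) <- sprintf("%s_%s_firstorder_%s", channel, tag, names(fo))
    disc <- discretize(img, tumor, cfg)
    tm <- build_texture_matrices(disc$levels, disc$n_levels)
    tx <- texture_features(tm)
    names(tx) <- sprintf("%s_%s_%s", channel, tag, names(tx))
    out <- c(out, fo, tx)
  }
  if (any(!is.finite(out))) stop("non-finite feature values produced")
  out
}

#' Extract features for one synthetic patient
#'
#' Runs preprocessing and extraction for the requested channels and
#' concatenates the per-channel 479-feature vectors.
#'
#' @param patient a `synthetic_patient` from [generate_cohort()].
#' @param cfg a [prep_config()].
#' @param channels channels to extract (default both).
#' @return named numeric vector (479 per channel).
#' @export
extract_all <- function(patient, cfg = prep_config(),
                        channels = c("CET1", "T2")) {
  out <- numeric(0)
  for (ch in channels) {
    img <- patient$images[[ch]]
    if (is.null(img)) stop("patient has no channel ", ch)
    prep <- preprocess_image(img, patient$tumor_mask, patient$reference_mask, cfg)
    out <- c(out, extract_channel_features(prep, cfg))
  }
  out
}

#' Extract a cohort-level feature table
#'
#' @param cohort list of `synthetic_patient` objects.
#' @param cfg a [prep_config()].
#' @param channels channels to extract.
#' @param verbose print per-patient progress.
#' @return A [feature_table()] with one row per patient.
#' @export
extract_cohort <- function(cohort, cfg = prep_config(),
                           channels = c("CET1", "T2"), verbose = FALSE) {
  rows <- lapply(cohort, function(p) {
    if (verbose) message("extracting ", p$id)
    extract_all(p, cfg, channels)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(cohort, `[[`, character(1), "id")
  labels <- vapply(cohort, `[[`, integer(1), "label")
  feature_table(m, labels)
}
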