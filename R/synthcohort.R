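# Synthetic phantom cohorts with the statistical structure the analysis
# assumes: two co-registered MR-like channels, an ellipsoidal tumor whose
# shape and texture depend on the re-plan label, a homogeneous reference box
# (brainstem surrogate), anisotropic source spacing so resampling does real
# work, and a gentle multiplicative shading field so bias correction does.

.round_half_up <- function(x) floor(x + 0.5)

#' Cohort generation settings
#'
#' Defaults reproduce the study constants this pipeline emulates: 70
#' patients with 13 positives (18.6% prevalence), split 51/19, on an
#' anisotropic 0.5 x 0.5 x 3.0 mm source grid.
#'
#' @param n_patients cohort size.
#' @param prevalence positive-class fraction in (0,1); the positive count is
#'   `round-half-up(prevalence * n_patients)` and must be at least 2.
#' @param n_train,n_test stratified split sizes (`n_train + n_test` must
#'   equal `n_patients`).
#' @param image_shape voxel grid dimensions.
#' @param voxel_spacing per-axis spacing in mm.
#' @param signal_effect standardized effect size of the class-dependent
#'   shape/texture differences; 0 removes all label signal.
#' @param noise_sd background intensity noise SD.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 70L, prevalence = 13 / 70,
                        n_train = 51L, n_test = 19L,
                        image_shape = c(64L, 64L, 24L),
                        voxel_spacing = c(0.5, 0.5, 3.0),
                        signal_effect = 1.5, noise_sd = 10, seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 4L) stop("cohort too small")
  if (!(prevalence > 0 && prevalence < 1)) stop("prevalence must be in (0,1)")
  n_pos <- .round_half_up(prevalence * n_patients)
  if (n_pos < 2L || n_pos > n_patients - 2L)
    stop("prevalence must give at least 2 patients in each class")
  if (as.integer(n_train) + as.integer(n_test) != n_patients)
    stop("n_train + n_test must equal n_patients")
  if (any(image_shape < 8L)) stop("degenerate image shape")
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
  structure(
    list(n_patients = n_patients, prevalence = prevalence,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         image_shape = as.integer(image_shape),
         voxel_spacing = as.numeric(voxel_spacing),
         signal_effect = signal_effect, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# physical coordinate arrays (mm, voxel centres, origin at 0)
.coord_arrays <- function(shape, spacing) {
  cx <- (seq_len(shape[1]) - 1) * spacing[1]
  cy <- (seq_len(shape[2]) - 1) * spacing[2]
  cz <- (seq_len(shape[3]) - 1) * spacing[3]
  list(
    x = array(cx, shape),
    y = array(rep(cy, each = shape[1]), shape),
    z = array(rep(cz, each = shape[1] * shape[2]), shape)
  )
}

.correlated_field <- function(shape, spacing, corr_len_mm) {
  w <- array(stats::rnorm(prod(shape)), shape)
  .gaussian_smooth3(w, corr_len_mm / spacing)
}

.simulate_patient <- function(id, label, spec) {
  shape <- spec$image_shape
  sp <- spec$voxel_spacing
  ext <- shape * sp
  co <- .coord_arrays(shape, sp)

  # tumor geometry: ellipsoid at the image centre (z slightly below middle
  # so the elongated positive-class axis stays clear of the reference box)
  elong <- 1 + 0.4 * spec$signal_effect
  semi <- stats::runif(3, 5, 8)
  if (label == 1L) semi[3] <- semi[3] * elong
  ctr <- c(ext[1] / 2, ext[2] / 2, ext[3] * 0.6)
  tumor <- ((co$x - ctr[1]) / semi[1])^2 + ((co$y - ctr[2]) / semi[2])^2 +
    ((co$z - ctr[3]) / semi[3])^2 <= 1

  # reference box: fixed physical slab near the z = 0 face, centred in xy
  ref <- co$x >= ext[1] / 2 - 6 & co$x <= ext[1] / 2 + 6 &
    co$y >= ext[2] / 2 - 6 & co$y <= ext[2] / 2 + 6 &
    co$z >= 2 & co$z <= 11

  # texture regime: positives carry longer-range spatially correlated noise
  tex_len <- 0.8 * (1 + (if (label == 1L) 0.8 * spec$signal_effect else 0))
  tex_amp <- 25

  mk_channel <- function(channel, bg_mean, tumor_base, ref_mean) {
    img <- bg_mean + array(stats::rnorm(prod(shape), 0, spec$noise_sd), shape)
    tex <- .correlated_field(shape, sp, tex_len)
    tex_sd <- stats::sd(tex[tumor])
    if (is.finite(tex_sd) && tex_sd > 0) tex <- tex / tex_sd * tex_amp
    img[tumor] <- tumor_base + tex[tumor]
    img[ref] <- stats::rnorm(sum(ref), ref_mean, 4)
    # gentle multiplicative shading so bias correction has work to do
    a <- stats::runif(3, -0.08, 0.08)
    bias <- exp(a[1] * (co$x / ext[1] - 0.5) + a[2] * (co$y / ext[2] - 0.5) +
                  a[3] * (co$z / ext[3] - 0.5))
    image_volume(img * bias, sp, channel = channel)
  }

  images <- list(
    CET1 = mk_channel("CET1", bg_mean = 60, tumor_base = 140, ref_mean = 200),
    T2 = mk_channel("T2", bg_mean = 80, tumor_base = 120, ref_mean = 200)
  )
  structure(
    list(id = id, label = label, images = images,
         tumor_mask = roi_mask(tumor, sp, role = "tumor"),
         reference_mask = roi_mask(ref, sp, role = "reference"),
         ground_truth = list(semi_axes = semi, texture_corr_len = tex_len)),
    class = "synthetic_patient"
  )
}

#' Generate a synthetic phantom cohort
#'
#' Exactly `round-half-up(prevalence * n_patients)` patients carry label 1.
#' Positive-class tumors are more elongated (one semi-axis scaled by
#' `1 + 0.4 * signal_effect`) and carry spatially correlated intensity noise
#' of longer correlation length; with `signal_effect = 0` the label is
#' statistically independent of all image content.  Both channels share
#' geometry but have independent noise.  Fully reproducible from the seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of `synthetic_patient` objects.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  n_pos <- .round_half_up(spec$prevalence * n)
  labels <- integer(n)
  labels[sample.int(n, n_pos)] <- 1L
  lapply(seq_len(n), function(i)
    .simulate_patient(sprintf("P%03d", i), labels[i], spec))
}

#' Generate a synthetic feature table directly
#'
#' Tabular stand-in for the extracted 479-feature matrix: standard-normal
#' noise features, `n_informative` features whose class means differ by
#' `effect` (in within-class SD units), and optional blocks of
#' inter-correlated features to exercise the correlation pruning.
#'
#' @param n_patients number of patients.
#' @param n_features total number of features.
#' @param n_informative number of label-associated features (first columns).
#' @param effect class-mean shift of informative features, in SD units.
#' @param block_correlation optional list of blocks, each a list with
#'   `features` (column indices) and `rho` (common pairwise correlation;
#'   `rho = 1` duplicates the block members exactly).
#' @param prevalence positive-class fraction.
#' @param seed integer seed.
#' @return A [feature_table()]; informative columns are named with family
#'   `informative`, the rest `noise`.
#' @export
generate_feature_table <- function(n_patients = 70L, n_features = 479L,
                                   n_informative = 5L, effect = 1.5,
                                   block_correlation = NULL,
                                   prevalence = 13 / 70, seed = 1L) {
  if (n_informative > n_features) stop("n_informative exceeds n_features")
  set.seed(as.integer(seed))
  n_pos <- .round_half_up(prevalence * n_patients)
  if (n_pos < 1L || n_pos >= n_patients) stop("degenerate prevalence")
  label <- integer(n_patients)
  label[sample.int(n_patients, n_pos)] <- 1L
  X <- matrix(stats::rnorm(n_patients * n_features), n_patients, n_features)
  for (blk in block_correlation) {
    rho <- blk$rho
    f <- stats::rnorm(n_patients)
    for (j in blk$features)
      X[, j] <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n_patients)
  }
  if (n_informative > 0)
    X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] + effect * label
  fam <- c(rep("informative", n_informative),
           rep("noise", n_features - n_informative))
  colnames(X) <- sprintf("SYN_original_%s_F%03d", fam, seq_len(n_features))
  rownames(X) <- sprintf("P%03d", seq_len(n_patients))
  feature_table(X, label)
}

#' Stratified train/test split
#'
#' Class proportions in each part stay within one patient of the cohort
#' proportion (round-half-up allocation of positives to the training part).
#' Sampling is done within each class on id-sorted patients, so the split is
#' invariant to the row order of the input.
#'
#' @param labels named binary vector (names = patient ids), or a
#'   [feature_table()], or a list of `synthetic_patient`s.
#' @param n_train number of training patients.
#' @param seed integer seed.
#' @return list with character vectors `train` and `test`.
#' @export
split_cohort <- function(labels, n_train = 51L, seed = 1L) {
  if (inherits(labels, "feature_table")) {
    labels <- stats::setNames(labels$label, rownames(labels$features))
  } else if (is.list(labels) && inherits(labels[[1]], "synthetic_patient")) {
    labels <- stats::setNames(vapply(labels, `[[`, integer(1), "label"),
                              vapply(labels, `[[`, character(1), "id"))
  }
  n <- length(labels)
  if (n_train >= n) stop("n_train must be smaller than the cohort")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to stratify")
  ids_pos <- sort(names(labels)[labels == 1L])
  ids_neg <- sort(names(labels)[labels == 0L])
  n_train_pos <- .round_half_up(n_train * length(ids_pos) / n)
  n_train_pos <- min(max(n_train_pos, 1L), length(ids_pos) - 1L)
  n_train_neg <- n_train - n_train_pos
  set.seed(as.integer(seed))
  tr_pos <- sample(ids_pos, n_train_pos)
  tr_neg <- sample(ids_neg, n_train_neg)
  train <- sort(c(tr_pos, tr_neg))
  list(train = train, test = sort(setdiff(names(labels), train)))
}

#' Write a phantom cohort to NIfTI files plus a manifest CSV
#'
#' @param cohort list of `synthetic_patient`s.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(p) {
    paths <- c(
      CET1 = file.path(dir, paste0(p$id, "_CET1.nii.gz")),
      T2 = file.path(dir, paste0(p$id, "_T2.nii.gz")),
      tumor = file.path(dir, paste0(p$id, "_tumor.nii.gz")),
      reference = file.path(dir, paste0(p$id, "_reference.nii.gz"))
    )
    write_nifti_volume(p$images$CET1, paths["CET1"])
    write_nifti_volume(p$images$T2, paths["T2"])
    write_nifti_volume(p$tumor_mask, paths["tumor"])
    write_nifti_volume(p$reference_mask, paths["reference"])
    data.frame(id = p$id, label = p$label, cet1 = paths["CET1"],
               t2 = paths["T2"], tumor = paths["tumor"],
               reference = paths["reference"], stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest path to the manifest CSV.
#' @return list of `synthetic_patient` objects.
#' @export
read_cohort <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(id = df$id[i], label = as.integer(df$label[i]),
           images = list(
             CET1 = read_nifti_volume(df$cet1[i], "image", channel = "CET1"),
             T2 = read_nifti_volume(df$t2[i], "image", channel = "T2")),
           tumor_mask = read_nifti_volume(df$tumor[i], "mask", role = "tumor"),
           reference_mask = read_nifti_volume(df$reference[i], "mask",
                                              role = "reference"),
           ground_truth = NULL),
      class = "synthetic_patient")
  })
}
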