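#' Patients-by-features table with provenance and labels
#'
#' The central tabular container of the pipeline: a numeric matrix of
#' patients (rows) by named features (columns), a binary re-plan label per
#' patient, and per-feature provenance (channel, filter, family) parsed from
#' the column naming scheme `<channel>_<filter>_<family>_<feature>`.
#'
#' @param features numeric matrix with rownames (patient ids) and colnames
#'   (feature names).
#' @param label integer 0/1 vector, one per row (1 = re-planned).
#' @param provenance optional data.frame with columns `feature`, `channel`,
#'   `filter`, `family`; derived from the column names when omitted.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, label, provenance = NULL) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("feature columns must be named")
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("P%03d", seq_len(nrow(features)))
  label <- as.integer(label)
  if (length(label) != nrow(features)) stop("one label per patient required")
  if (!all(label %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (is.null(provenance)) provenance <- parse_feature_names(colnames(features))
  structure(list(features = features, label = label, provenance = provenance),
            class = "feature_table")
}

#' Parse provenance from feature names
#'
#' @param x character vector of names `<channel>_<filter>_<family>_<feature>`.
#' @return data.frame with columns feature, channel, filter, family.
#' @export
parse_feature_names <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  bad <- lengths(parts) < 4L
  get <- function(p, i) vapply(p, `[`, character(1), i)
  out <- data.frame(
    feature = x,
    channel = ifelse(bad, NA_character_, get(parts, 1L)),
    filter = ifelse(bad, NA_character_, get(parts, 2L)),
    family = ifelse(bad, NA_character_, get(parts, 3L)),
    stringsAsFactors = FALSE
  )
  out
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features (%d positive)\n",
              nrow(x$features), ncol(x$features), sum(x$label)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(patient_id = rownames(x$features), label = x$label,
             x$features, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Subset a feature table
#'
#' @param x a [feature_table()].
#' @param patients row selector (indices, ids or logical).
#' @param features column selector (indices, names or logical).
#' @return A [feature_table()].
#' @export
subset_table <- function(x, patients = NULL, features = NULL) {
  f <- x$features
  if (!is.null(patients)) {
    f <- f[patients, , drop = FALSE]
    lab <- x$label[if (is.character(patients))
      match(patients, rownames(x$features)) else patients]
  } else lab <- x$label
  if (!is.null(features)) f <- f[, features, drop = FALSE]
  prov <- x$provenance[match(colnames(f), x$provenance$feature), , drop = FALSE]
  feature_table(f, lab, prov)
}

#' Write a feature table to CSV
#'
#' @param x a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Expects the layout written by [write_feature_table()]: `patient_id`,
#' `label`, then one column per feature.
#'
#' @param path CSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("patient_id", "label")), drop = FALSE])
  rownames(m) <- df$patient_id
  feature_table(m, df$label)
}
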