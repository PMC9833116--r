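#' Assemble a feature table
#'
#' A `feature_table` holds an untargeted LC-MS intensity matrix together with
#' feature metadata (m/z, retention time, ionisation mode) and sample metadata
#' (subject, burn/control condition, time fraction, QC flag, tissue weight).
#' It is the common currency of the discriminant and lipidomics pipelines.
#'
#' @param intensities numeric matrix, samples x features, non-negative and
#'   finite; dimnames are taken as sample/feature identifiers if the metadata
#'   tables do not name them.
#' @param features data.frame with one row per feature; must contain
#'   `feature_id`, and may carry `mz`, `rt_s`, `ion_mode`.
#' @param samples data.frame with one row per sample; must contain
#'   `sample_id`; may carry `subject`, `condition` ("burn"/"control"),
#'   `fraction` (minute offset of the microdialysate bin or NA), `qc`
#'   (logical), `weight_mg`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(intensities, features, samples) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  stopifnot(is.data.frame(features), is.data.frame(samples))
  if (!"feature_id" %in% names(features)) stop("features needs a feature_id column")
  if (!"sample_id" %in% names(samples)) stop("samples needs a sample_id column")
  if (nrow(features) != ncol(intensities))
    stop("features rows must match intensity columns")
  if (nrow(samples) != nrow(intensities))
    stop("samples rows must match intensity rows")
  if (anyDuplicated(features$feature_id)) stop("duplicate feature ids")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  rownames(intensities) <- as.character(samples$sample_id)
  colnames(intensities) <- as.character(features$feature_id)
  if (!"qc" %in% names(samples)) samples$qc <- FALSE
  non_qc <- !samples$qc
  if ("condition" %in% names(samples) &&
      any(non_qc & (is.na(samples$condition) |
                    !samples$condition %in% c("burn", "control"))))
    stop("every non-QC sample must have condition burn or control")
  structure(list(intensities = intensities,
                 features = features,
                 samples = samples),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%d QC)\n",
              nrow(x$intensities), ncol(x$intensities), sum(x$samples$qc)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table by sample and/or feature
#'
#' @param table a `feature_table`.
#' @param samples logical/integer/character index over samples.
#' @param features logical/integer/character index over features.
#' @return the subset `feature_table`.
#' @export
subset_feature_table <- function(table, samples = NULL, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  si <- if (is.null(samples)) seq_len(nrow(table$intensities)) else samples
  fi <- if (is.null(features)) seq_len(ncol(table$intensities)) else features
  if (is.character(si)) si <- match(si, table$samples$sample_id)
  if (is.character(fi)) fi <- match(fi, table$features$feature_id)
  feature_table(table$intensities[si, fi, drop = FALSE],
                table$features[fi, , drop = FALSE],
                table$samples[si, , drop = FALSE])
}

#' Write a feature table as a tidy CSV pair
#'
#' Long-format intensities (`feature_id, mz, rt_s, ion_mode, sample_id,
#' intensity`) plus a sample-metadata CSV, the interchange format used by all
#' pipelines here.
#'
#' @param table a `feature_table`.
#' @param intensities_csv,samples_csv output paths.
#' @return invisibly, the two paths.
#' @export
write_feature_table <- function(table, intensities_csv, samples_csv) {
  stopifnot(inherits(table, "feature_table"))
  ft <- table$features
  if (!"mz" %in% names(ft)) ft$mz <- NA_real_
  if (!"rt_s" %in% names(ft)) ft$rt_s <- NA_real_
  if (!"ion_mode" %in% names(ft)) ft$ion_mode <- NA_character_
  long <- data.frame(
    feature_id = rep(ft$feature_id, each = nrow(table$intensities)),
    mz = rep(ft$mz, each = nrow(table$intensities)),
    rt_s = rep(ft$rt_s, each = nrow(table$intensities)),
    ion_mode = rep(ft$ion_mode, each = nrow(table$intensities)),
    sample_id = rep(table$samples$sample_id, times = nrow(ft)),
    intensity = as.vector(table$intensities)
  )
  utils::write.csv(long, intensities_csv, row.names = FALSE)
  utils::write.csv(table$samples, samples_csv, row.names = FALSE)
  invisible(c(intensities_csv, samples_csv))
}

#' Read a feature table from a tidy CSV pair
#'
#' @param intensities_csv long-format intensity CSV as written by
#'   [write_feature_table()].
#' @param samples_csv sample-metadata CSV.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(intensities_csv, samples_csv) {
  long <- utils::read.csv(intensities_csv, stringsAsFactors = FALSE)
  samples <- utils::read.csv(samples_csv, stringsAsFactors = FALSE)
  fids <- unique(long$feature_id)
  sids <- samples$sample_id
  m <- matrix(NA_real_, nrow = length(sids), ncol = length(fids),
              dimnames = list(sids, fids))
  m[cbind(match(long$sample_id, sids), match(long$feature_id, fids))] <-
    long$intensity
  feats <- long[!duplicated(long$feature_id),
                c("feature_id", "mz", "rt_s", "ion_mode")]
  rownames(feats) <- NULL
  if ("qc" %in% names(samples)) samples$qc <- as.logical(samples$qc)
  feature_table(m, feats, samples)
}
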