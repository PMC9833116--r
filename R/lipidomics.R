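#' Normalise intensities by tissue weight
#'
#' Each biological sample's intensities are divided by its tissue weight in
#' mg; QC samples (pooled aliquots, which have no weight of their own) are
#' divided by the arithmetic mean weight of the biological samples.
#'
#' @param table a [feature_table()] with `weight_mg` on biological samples.
#' @return the weight-normalised `feature_table`.
#' @export
normalize_by_weight <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  s <- table$samples
  bio <- !s$qc
  if (any(is.na(s$weight_mg[bio])))
    stop("missing weight on a biological sample")
  if (any(s$weight_mg[bio] <= 0)) stop("weights must be > 0")
  w <- s$weight_mg
  w[!bio] <- mean(s$weight_mg[bio])
  out <- table
  out$intensities <- table$intensities / w
  out
}

#' QC coefficient-of-variation filter
#'
#' Computes each feature's CV (sd/mean) across the pooled-QC injections and
#' discards features whose QC CV exceeds the threshold (default 30%), i.e.
#' features the platform did not measure reproducibly. Features whose QC
#' mean is zero have undefined CV and are discarded.
#'
#' @param table a [feature_table()] with >= 2 QC samples.
#' @param threshold CV threshold as a proportion (default 0.30).
#' @return list with `table` (filtered) and `report` data.frame
#'   (`feature_id`, `qc_cv`, `kept`, `threshold`).
#' @export
qc_cv_filter <- function(table, threshold = 0.30) {
  stopifnot(inherits(table, "feature_table"))
  qc <- table$samples$qc
  if (sum(qc) < 2) stop("need at least 2 QC samples")
  m <- table$intensities[qc, , drop = FALSE]
  mu <- colMeans(m)
  cv <- apply(m, 2, stats::sd) / mu
  kept <- !is.na(cv) & is.finite(cv) & cv <= threshold
  report <- data.frame(feature_id = table$features$feature_id,
                       qc_cv = cv, kept = kept, threshold = threshold,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(table = subset_feature_table(table, features = which(kept)),
       report = report)
}

#' Generalised logarithm
#'
#' `glog(x) = log2((x + sqrt(x^2 + lambda^2)) / 2)`, a variance-stabilising
#' transform that behaves like log2 for large x and stays defined at 0.
#'
#' @param x numeric.
#' @param lambda transform parameter (intensity-squared units scale), > 0.
#' @return transformed values.
#' @export
glog <- function(x, lambda) {
  if (lambda <= 0) stop("lambda must be > 0")
  log2((x + sqrt(x^2 + lambda^2)) / 2)
}

#' Median normalisation, glog transform and autoscaling
#'
#' The fixed transform stack applied after weight normalisation and QC
#' filtering: (1) each sample is rescaled so its median intensity equals the
#' grand median (median of per-sample medians over biological samples);
#' (2) intensities are glog-transformed; (3) each feature column is centred
#' and scaled to unit variance. After step 3 every non-constant feature
#' column has mean 0 and variance 1.
#'
#' @param table a [feature_table()] (weight-normalised, QC-filtered).
#' @param glog_lambda glog parameter; default is the minimum positive
#'   intensity in the table.
#' @return the transformed `feature_table`; the per-sample scale factors and
#'   lambda used are attached as attributes `scale_factors` and
#'   `glog_lambda`.
#' @export
transform_stack <- function(table, glog_lambda = NULL) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$intensities
  bio <- !table$samples$qc
  med <- apply(m, 1, stats::median)
  target <- stats::median(med[bio])
  sf <- target / med
  m <- m * sf
  if (is.null(glog_lambda)) {
    pos <- m[m > 0]
    if (length(pos) == 0) stop("no positive intensities to set lambda")
    glog_lambda <- min(pos)
  }
  m <- glog(m, glog_lambda)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv == 0] <- 1                     # constant columns map to all-zero
  m <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  out <- table
  out$intensities <- m
  attr(out, "scale_factors") <- sf
  attr(out, "glog_lambda") <- glog_lambda
  out
}

#' Per-feature Welch t tests with Holm adjustment
#'
#' Unpaired unequal-variance t tests (Welch-Satterthwaite degrees of
#' freedom) of burn versus control for every feature, followed by
#' Holm-Bonferroni step-down adjustment across features. The log2 fold
#' change is computed from a companion table on the unstandardised
#' (weight-normalised) scale when supplied.
#'
#' @param table a [feature_table()] (typically the [transform_stack()]
#'   output).
#' @param alpha family-wise significance level (default 0.05) applied to the
#'   adjusted q values.
#' @param fc_table optional `feature_table` on the pre-transform scale used
#'   for the burn/control mean-ratio fold change; defaults to `table`.
#' @return data.frame `feature_id`, `t`, `df`, `p`, `q`, `log2_fc`,
#'   `significant`.
#' @export
welch_holm <- function(table, alpha = 0.05, fc_table = table) {
  stopifnot(inherits(table, "feature_table"))
  s <- table$samples
  g1 <- !s$qc & s$condition == "burn"
  g2 <- !s$qc & s$condition == "control"
  if (sum(g1) < 2 || sum(g2) < 2) stop("need >= 2 samples per group")
  res <- welch_t_matrix(table$intensities[g1, , drop = FALSE],
                        table$intensities[g2, , drop = FALSE])
  q <- holm_adjust(res$p)
  fb <- colMeans(fc_table$intensities[g1, , drop = FALSE])
  fcon <- colMeans(fc_table$intensities[g2, , drop = FALSE])
  data.frame(feature_id = table$features$feature_id,
             t = res$t, df = res$df, p = res$p, q = q,
             log2_fc = log2(fb / fcon),
             significant = q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

# vectorised Welch t over the columns of two group matrices;
# cross-checked against stats::t.test in the test suite
welch_t_matrix <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, stats::var); v2 <- apply(x2, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  tt[zero] <- 0; p[zero] <- 1; df[zero] <- n1 + n2 - 2
  list(t = tt, df = df, p = p)
}

#' Run the full lipidomics preprocessing and univariate chain
#'
#' Fixed order: weight normalisation, QC CV filter, median normalisation,
#' glog, autoscaling, per-feature Welch tests with Holm adjustment. Fold
#' changes are computed on the weight-normalised (pre-glog) scale.
#'
#' @param table raw [feature_table()] with QC samples and tissue weights.
#' @param qc_cv QC CV threshold (default 0.30).
#' @param alpha significance level on Holm-adjusted q (default 0.05).
#' @param glog_lambda optional glog parameter (default: minimum positive
#'   weight-normalised intensity).
#' @return list: `table` (transformed), `qc_report`, `results` (univariate
#'   table), `steps` (the pipeline order actually run).
#' @export
lipidomics_pipeline <- function(table, qc_cv = 0.30, alpha = 0.05,
                                glog_lambda = NULL) {
  wn <- normalize_by_weight(table)
  qcf <- qc_cv_filter(wn, threshold = qc_cv)
  tr <- transform_stack(qcf$table, glog_lambda = glog_lambda)
  res <- welch_holm(tr, alpha = alpha, fc_table = qcf$table)
  list(table = tr, qc_report = qcf$report, results = res,
       steps = c("weight_normalisation", "qc_cv_filter",
                 "median_normalisation", "glog", "autoscale",
                 "welch_holm"))
}
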