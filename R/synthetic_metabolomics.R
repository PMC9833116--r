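#' Synthetic paired microdialysate time course
#'
#' Emulates a dermal microdialysis experiment: each subject contributes one
#' burn and one control limb sampled in 30-minute fractions from 30 minutes
#' before to 3 hours after injury. A chosen subset of features is planted with
#' a multiplicative burn effect that follows an increase-then-plateau temporal
#' profile starting at the first post-injury fraction; everything else is
#' exchangeable noise. Intensity noise is multiplicative log-normal, the
#' conventional model for untargeted LC-MS peak areas.
#'
#' @param n_subjects number of subjects (paired limbs).
#' @param n_features number of LC-MS features.
#' @param n_planted number of features carrying the burn effect.
#' @param fractions minute offsets of the collection bins; the default is the
#'   standard -30..180 min grid in 30-min steps. Fractions <= 0 are
#'   pre-injury and never carry the effect.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise (0 = deterministic).
#' @param seed integer seed; identical seed and parameters give identical
#'   output.
#' @param effect_size multiplicative effect at plateau (>= 1).
#' @param rise_fractions number of post-injury fractions over which the
#'   effect rises linearly from 1 to `effect_size` before the plateau.
#' @param temporal_profile optional explicit per-fraction multiplicative
#'   profile (length `length(fractions)`, non-decreasing then constant);
#'   overrides `effect_size`/`rise_fractions`.
#' @param ion_mode ionisation mode label stamped on the features.
#' @return list with `table` (a [feature_table()]) and `truth` (class
#'   `metabolomics_truth`: `planted_feature_ids`, `temporal_profile`,
#'   `effect_onset_fraction`, `noise_cv`).
#' @export
gen_metabolomics_timecourse <- function(n_subjects, n_features, n_planted,
                                        fractions = seq(-30, 180, by = 30),
                                        noise_cv = 0.2, seed = 1,
                                        effect_size = 2, rise_fractions = 3,
                                        temporal_profile = NULL,
                                        ion_mode = "ESI+") {
  if (n_subjects < 1 || n_features < 1 || n_planted < 0)
    stop("counts must be positive")
  if (n_planted > n_features) stop("n_planted must not exceed n_features")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  post <- which(fractions > 0)
  if (is.null(temporal_profile)) {
    temporal_profile <- rep(1, length(fractions))
    if (length(post) > 0) {
      rise <- seq_len(min(rise_fractions, length(post)))
      temporal_profile[post[rise]] <-
        1 + (effect_size - 1) * rise / min(rise_fractions, length(post))
      if (length(post) > length(rise))
        temporal_profile[post[-rise]] <- effect_size
    }
  }
  if (length(temporal_profile) != length(fractions))
    stop("temporal_profile must have one entry per fraction")
  if (any(diff(temporal_profile) < -1e-12))
    stop("temporal_profile must be non-decreasing")
  onset <- if (any(temporal_profile > 1)) min(which(temporal_profile > 1)) else NA_integer_

  set.seed(seed)
  fid <- sprintf("F%04d", seq_len(n_features))
  planted <- if (n_planted > 0) sort(sample(fid, n_planted)) else character(0)
  feats <- data.frame(
    feature_id = fid,
    mz = round(stats::runif(n_features, 100, 1200), 4),
    rt_s = round(stats::runif(n_features, 30, 700), 1),
    ion_mode = ion_mode,
    stringsAsFactors = FALSE
  )
  base <- exp(stats::rnorm(n_features, log(1e4), 1))          # feature abundance
  subj_eff <- matrix(exp(stats::rnorm(n_subjects * n_features, 0, 0.1)),
                     n_subjects, n_features)                   # shared in pairs

  grid <- expand.grid(fraction = fractions,
                      condition = c("burn", "control"),
                      subject = sprintf("S%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject, grid$condition, grid$fraction), ]
  samples <- data.frame(
    sample_id = sprintf("%s_%s_f%+04d", grid$subject,
                        ifelse(grid$condition == "burn", "B", "C"),
                        grid$fraction),
    subject = grid$subject, condition = grid$condition,
    fraction = grid$fraction, qc = FALSE, weight_mg = NA_real_,
    stringsAsFactors = FALSE
  )

  sdlog <- sqrt(log(1 + noise_cv^2))
  n_s <- nrow(samples)
  eff <- matrix(1, n_s, n_features)
  is_burn <- samples$condition == "burn"
  frac_idx <- match(samples$fraction, fractions)
  pl <- fid %in% planted
  eff[is_burn, pl] <- temporal_profile[frac_idx[is_burn]]
  subj_idx <- match(samples$subject, sprintf("S%02d", seq_len(n_subjects)))
  mu <- (rep(1, n_s) %o% base) * subj_eff[subj_idx, , drop = FALSE] * eff
  noise <- if (noise_cv > 0)
    matrix(exp(stats::rnorm(n_s * n_features, -sdlog^2 / 2, sdlog)),
           n_s, n_features) else 1
  tab <- feature_table(mu * noise, feats, samples)
  truth <- structure(list(planted_feature_ids = planted,
                          temporal_profile = temporal_profile,
                          effect_onset_fraction = onset,
                          noise_cv = noise_cv),
                     class = "metabolomics_truth")
  list(table = tab, truth = truth)
}

#' Synthetic biopsy lipidomics cohort with pooled QC injections
#'
#' Burn/control tissue pairs with per-sample tissue weights, optional planted
#' fold changes in the burn arm, and pooled quality-control samples
#' (arithmetic mean of all biological samples plus instrument noise)
#' interleaved every `qc_every` injections, mirroring standard untargeted
#' lipidomics run design.
#'
#' @param n_pairs number of burn/control pairs.
#' @param n_features number of features.
#' @param planted_fc named numeric vector mapping feature ids (e.g. "L0003")
#'   to burn/control fold changes; may be empty.
#' @param qc_every one QC injection after every `qc_every` biological samples.
#' @param weights_mg length-2 numeric (min, max) of the uniform tissue-weight
#'   distribution in milligrams.
#' @param seed integer seed.
#' @param noise_cv biological + analytical CV of the log-normal noise.
#' @param instrument_cv CV of the instrument noise on QC re-injections
#'   (0 = QC equals the cohort mean exactly).
#' @param ion_mode ionisation mode label.
#' @return a [feature_table()]; planted ids and fold changes are recoverable
#'   from the `planted_fc` attribute.
#' @export
gen_lipidomics_cohort <- function(n_pairs, n_features, planted_fc = numeric(0),
                                  qc_every = 5, weights_mg = c(5, 15),
                                  seed = 1, noise_cv = 0.1,
                                  instrument_cv = 0.02, ion_mode = "ESI+") {
  if (n_pairs < 1 || n_features < 1) stop("counts must be positive")
  if (qc_every < 1) stop("qc_every must be >= 1")
  if (any(weights_mg <= 0)) stop("negative or zero weights rejected")
  if (noise_cv < 0 || instrument_cv < 0) stop("CVs must be >= 0")
  set.seed(seed)
  fid <- sprintf("L%04d", seq_len(n_features))
  if (length(planted_fc) > 0 && !all(names(planted_fc) %in% fid))
    stop("planted_fc names must be generated feature ids")
  feats <- data.frame(feature_id = fid,
                      mz = round(stats::runif(n_features, 200, 1000), 4),
                      rt_s = round(stats::runif(n_features, 30, 1150), 1),
                      ion_mode = ion_mode, stringsAsFactors = FALSE)
  base <- exp(stats::rnorm(n_features, log(1e5), 1))
  n_bio <- 2 * n_pairs
  cond <- rep(c("burn", "control"), n_pairs)
  subj <- rep(sprintf("P%02d", seq_len(n_pairs)), each = 2)
  w <- stats::runif(n_bio, weights_mg[1], weights_mg[2])
  sdlog <- sqrt(log(1 + noise_cv^2))
  fc <- rep(1, n_features)
  fc[match(names(planted_fc), fid)] <- planted_fc
  mu <- rep(1, n_bio) %o% base
  mu[cond == "burn", ] <- mu[cond == "burn", , drop = FALSE] *
    (rep(1, n_pairs) %o% fc)
  noise <- if (noise_cv > 0)
    matrix(exp(stats::rnorm(n_bio * n_features, -sdlog^2 / 2, sdlog)),
           n_bio, n_features) else 1
  bio <- mu * noise
  # tissue amount scales the raw signal; weight normalisation undoes it
  bio <- bio * w

  n_qc <- floor(n_bio / qc_every)
  qc_mean <- colMeans(bio)
  sdq <- sqrt(log(1 + instrument_cv^2))
  qc <- matrix(rep(qc_mean, each = n_qc), n_qc, n_features)
  if (instrument_cv > 0 && n_qc > 0)
    qc <- qc * matrix(exp(stats::rnorm(n_qc * n_features, -sdq^2 / 2, sdq)),
                      n_qc, n_features)

  # injection order: qc_every biological samples then one QC, repeated
  samples <- data.frame(
    sample_id = c(sprintf("%s_%s", subj, ifelse(cond == "burn", "B", "C")),
                  if (n_qc > 0) sprintf("QC%02d", seq_len(n_qc))),
    subject = c(subj, rep(NA_character_, n_qc)),
    condition = c(cond, rep(NA_character_, n_qc)),
    fraction = NA_real_,
    qc = c(rep(FALSE, n_bio), rep(TRUE, n_qc)),
    weight_mg = c(w, rep(NA_real_, n_qc)),
    stringsAsFactors = FALSE
  )
  tab <- feature_table(rbind(bio, qc), feats, samples)
  attr(tab, "planted_fc") <- planted_fc
  tab
}
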