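# Shared fixtures, built in code at test time.

# small paired time-course table: 2 conditions x 3 fractions x 2 subjects,
# 6 features, deterministic given the seed
small_timecourse <- function(seed = 42, n_features = 6) {
  gen_metabolomics_timecourse(n_subjects = 2, n_features = n_features,
                              n_planted = 0, fractions = c(-30, 30, 60),
                              noise_cv = 0.3, seed = seed)
}

# a trace with a deterministic baseline of known SD and a plateau response
# whose amplitude is an exact multiple of that SD
plateau_trace <- function(amp_mult, windows = data.frame(
                            label = "drug", start_s = 60, end_s = 90,
                            is_depolarising = FALSE)) {
  t_s <- seq(0, 140, by = 2)
  base <- rep(c(0.99, 1.01), length.out = length(t_s))
  idx <- t_s >= 30 & t_s < 60
  mu <- mean(base[idx]); sdv <- sd(base[idx])
  r <- base
  on <- t_s >= 62 & t_s <= 90
  r[on] <- mu + amp_mult * sdv
  kcl <- data.frame(label = "KCl 60mM", start_s = 120, end_s = 136,
                    is_depolarising = TRUE)
  ca_trace("P1", t_s, r, rbind(windows, kcl))
}

# draw thresholds from a Gaussian mixture (independent of the generators)
draw_mixture <- function(n, means, sds, weights, seed) {
  set.seed(seed)
  comp <- sample(length(means), n, replace = TRUE, prob = weights)
  stats::rnorm(n, means[comp], sds[comp])
}

# the four sensory-neuron threshold population means (degrees C)
population_means <- c(33.9, 39.8, 44.4, 52)

# independent oracle: assemble the between/within scatter matrices
# explicitly in the PCA-reduced space and solve eigen(W^-1 B) directly
cva_eigen_oracle <- function(table, pca_rank, scale = FALSE) {
  s <- table$samples[!table$samples$qc, ]
  X <- table$intensities[!table$samples$qc, , drop = FALSE]
  Xc <- base::scale(X, center = TRUE, scale = scale)
  pc <- stats::prcomp(Xc, center = FALSE, rank. = pca_rank)
  T_sc <- pc$x
  cell <- interaction(s$condition, s$fraction, drop = TRUE)
  gm <- rowsum(T_sc, cell) / as.vector(table(cell))
  B <- matrix(0, ncol(T_sc), ncol(T_sc))
  W <- matrix(0, ncol(T_sc), ncol(T_sc))
  for (g in levels(cell)) {
    rows <- which(cell == g)
    mg <- gm[g, ]
    B <- B + length(rows) * tcrossprod(mg)
    for (i in rows) W <- W + tcrossprod(T_sc[i, ] - mg)
  }
  ev <- eigen(solve(W) %*% B, only.values = TRUE)$values
  sort(Re(ev[abs(Im(ev)) < 1e-8]), decreasing = TRUE)
}
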