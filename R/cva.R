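#' Cell-means design for a paired longitudinal experiment
#'
#' Builds the condition-by-fraction cell-means encoding used by the
#' discriminant analysis: one indicator column per (condition, fraction)
#' cell, over the non-QC samples of the table.
#'
#' @param table a [feature_table()] with `condition` and `fraction` sample
#'   metadata.
#' @return object of class `cva_design`: `encoding` (samples x cells
#'   indicator matrix), `cells` (data.frame condition/fraction per column),
#'   `sample_id` (row order).
#' @export
cva_design <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  s <- table$samples[!table$samples$qc, , drop = FALSE]
  if (any(is.na(s$condition)) || any(is.na(s$fraction)))
    stop("all non-QC samples need condition and fraction")
  cells <- unique(s[, c("condition", "fraction")])
  cells <- cells[order(cells$condition, cells$fraction), , drop = FALSE]
  rownames(cells) <- NULL
  idx <- match(interaction(s$condition, s$fraction, drop = TRUE),
               interaction(cells$condition, cells$fraction, drop = TRUE))
  enc <- matrix(0, nrow(s), nrow(cells))
  enc[cbind(seq_len(nrow(s)), idx)] <- 1
  if (qr(enc)$rank < ncol(enc)) stop("rank-deficient design")
  structure(list(encoding = enc, cells = cells, sample_id = s$sample_id),
            class = "cva_design")
}

#' Canonical variates analysis of a feature table
#'
#' Finds linear combinations of LC-MS features (canonical variates) maximally
#' discriminating the design cells, in the p >> n regime: columns are
#' mean-centred, the data are reduced by PCA, the generalised eigenproblem
#' of between-cell versus within-cell (residual) scatter is solved in the
#' reduced space, and the eigenvectors are back-projected through the PCA
#' loadings to give per-feature canonical weights. Canonical contrasts are
#' the design-cell means of each variate; each component's sign is fixed so
#' that the burn minus control contrast at the final fraction is
#' non-negative.
#'
#' @param table a [feature_table()].
#' @param design a [cva_design()]; default built from the table.
#' @param pca_rank dimension of the retained PCA space; the default
#'   `min(floor((n_samples - n_cells) / 2), n_features)` keeps the retained
#'   dimension well below the residual degrees of freedom so the within
#'   scatter stays well conditioned (at `n - q` dimensions it is singular in
#'   all but name and the discriminant overfits noise).
#' @param center mean-centre columns before PCA (default TRUE).
#' @param scale divide each column by its SD before PCA (default TRUE).
#'   Untargeted LC-MS intensities span decades and their noise is
#'   multiplicative, so without scaling the canonical weights are dominated
#'   by raw abundance rather than discriminative signal; set FALSE to keep
#'   weights on the intensity scale.
#' @return object of class `cva_result`: `canonical_vectors` (features x k
#'   weights), `canonical_variates` (samples x k), `canonical_contrasts`
#'   (cells x k), `eigenvalues`, `n_components_retained`, `design`.
#' @export
fit_cva <- function(table, design = cva_design(table), pca_rank = NULL,
                    center = TRUE, scale = TRUE) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "cva_design"))
  s_idx <- match(design$sample_id, table$samples$sample_id)
  X <- table$intensities[s_idx, , drop = FALSE]
  G <- design$encoding
  n <- nrow(X); q <- ncol(G); p <- ncol(X)
  if (n < q + 2) stop("need at least design cells + 2 samples")
  if (is.null(pca_rank)) pca_rank <- max(1, min(floor((n - q) / 2), p))
  if (pca_rank > n - 1) stop("pca_rank must be at most samples - 1 (over-parameterised)")
  if (pca_rank < 1) stop("pca_rank must be positive")
  mu <- if (center) colMeans(X) else rep(0, p)
  Xc <- sweep(X, 2, mu)
  if (scale) {
    sdv <- apply(Xc, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xc <- sweep(Xc, 2, sdv, "/")
  }
  sv <- svd(Xc, nu = pca_rank, nv = pca_rank)
  pos <- sv$d[seq_len(pca_rank)] > max(sv$d) * 1e-10
  r <- sum(pos)
  V <- sv$v[, seq_len(r), drop = FALSE]
  T_scores <- Xc %*% V                                   # samples x r

  GtG_inv <- solve(crossprod(G))
  Fhat <- G %*% (GtG_inv %*% crossprod(G, T_scores))     # fitted cell means
  E <- T_scores - Fhat
  B <- crossprod(Fhat)                                   # between-cell scatter
  W <- crossprod(E)                                      # within (residual)
  # whiten by the within scatter, then ordinary symmetric eigenproblem
  R <- chol(W + diag(max(diag(W)) * 1e-12, r))
  M <- backsolve(R, t(backsolve(R, t(B), transpose = TRUE)), transpose = TRUE)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- eg$values
  keep <- which(lam > max(lam[1], 0) * 1e-10 & lam > 0)
  k <- min(length(keep), q - 1)
  keep <- keep[seq_len(k)]
  A <- backsolve(R, eg$vectors[, keep, drop = FALSE])    # a' W a = I
  Wt <- V %*% A                                          # feature-space weights
  Z <- T_scores %*% A
  Cmat <- GtG_inv %*% crossprod(G, Z)                    # cell means of variates

  # sign convention: burn - control at the final fraction >= 0
  cells <- design$cells
  last_f <- max(cells$fraction)
  ib <- which(cells$condition == "burn" & cells$fraction == last_f)
  ic <- which(cells$condition == "control" & cells$fraction == last_f)
  if (length(ib) == 1 && length(ic) == 1) {
    flip <- (Cmat[ib, ] - Cmat[ic, ]) < 0
    if (any(flip)) {
      A[, flip] <- -A[, flip]; Wt[, flip] <- -Wt[, flip]
      Z[, flip] <- -Z[, flip]; Cmat[, flip] <- -Cmat[, flip]
    }
  }
  dimnames(Wt) <- list(colnames(X), paste0("CV", seq_len(k)))
  dimnames(Z) <- list(design$sample_id, paste0("CV", seq_len(k)))
  structure(list(canonical_vectors = Wt,
                 canonical_variates = Z,
                 canonical_contrasts = cbind(cells, as.data.frame(Cmat)),
                 eigenvalues = lam[keep],
                 n_components_retained = k,
                 pca_rank = r,
                 design = design),
            class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf("cva_result: %d components (PCA rank %d)\n",
              x$n_components_retained, x$pca_rank))
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Burn minus control contrast profile of one component
#'
#' @param result a [fit_cva()] result.
#' @param component component index.
#' @return data.frame `fraction`, `contrast` (burn cell mean minus control
#'   cell mean of the canonical variate, per fraction).
#' @export
contrast_profile <- function(result, component = 1) {
  stopifnot(inherits(result, "cva_result"))
  cc <- result$canonical_contrasts
  col <- paste0("V", component)
  b <- cc[cc$condition == "burn", c("fraction", col)]
  c0 <- cc[cc$condition == "control", c("fraction", col)]
  m <- merge(b, c0, by = "fraction", suffixes = c("_b", "_c"))
  data.frame(fraction = m$fraction,
             contrast = m[[paste0(col, "_b")]] - m[[paste0(col, "_c")]])
}

#' Rank features by canonical weight
#'
#' Orders all features by decreasing absolute canonical weight on one
#' component; ties are broken by feature id so the ranking is deterministic.
#'
#' @param result a [fit_cva()] result.
#' @param component component index (default 1).
#' @return data.frame `rank`, `feature_id`, `weight`, `abs_weight`.
#' @export
rank_features <- function(result, component = 1) {
  stopifnot(inherits(result, "cva_result"))
  if (component < 1 || component > result$n_components_retained)
    stop("component out of range")
  w <- result$canonical_vectors[, component]
  fid <- rownames(result$canonical_vectors)
  o <- order(-abs(w), fid)
  data.frame(rank = seq_along(w), feature_id = fid[o], weight = w[o],
             abs_weight = abs(w)[o], stringsAsFactors = FALSE)
}

#' Shortlist the top fraction of a canonical-weight ranking
#'
#' @param ranking output of [rank_features()].
#' @param fraction proportion in (0, 1]; the shortlist is the first
#'   `ceiling(fraction * n)` entries.
#' @return character vector of feature ids (a prefix of the ranking).
#' @export
select_top_fraction <- function(ranking, fraction = 0.05) {
  if (nrow(ranking) == 0) stop("empty ranking")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ranking$feature_id[seq_len(ceiling(fraction * nrow(ranking)))]
}
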