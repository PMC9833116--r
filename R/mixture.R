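# sum of K Gaussian bell curves evaluated at bin centres;
# par = (w1..wK, m1..mK, s1..sK), w on the count scale
gauss_sum <- function(par, x, K) {
  w <- par[1:K]; m <- par[K + 1:K]; s <- par[2 * K + 1:K]
  rowSums(vapply(seq_len(K),
                 function(k) w[k] * stats::dnorm(x, m[k], s[k]),
                 numeric(length(x))))
}

fit_gauss_k <- function(centers, counts, K, n_starts = 8, data = NULL) {
  span <- range(centers)
  n <- sum(counts)
  # the fit must not depend on (or disturb) the caller's RNG state: all
  # stochastic starts draw from a private, fixed stream
  if (exists(".Random.seed", .GlobalEnv)) {
    old_seed <- get(".Random.seed", .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(20260920 + K)
  starts <- list()
  # moment start: whole-histogram mean/SD (exact for K = 1)
  xw <- rep(centers, counts)
  starts[[1]] <- list(m = rep(mean(xw), K) +
                        (seq_len(K) - (K + 1) / 2) * stats::sd(xw),
                      s = rep(max(stats::sd(xw) / K, 0.5), K),
                      w = rep(n / K, K))
  # kmeans start on the raw data when available
  if (!is.null(data) && length(data) >= K) {
    km <- tryCatch(stats::kmeans(data, K, nstart = 5),
                   error = function(e) NULL)
    if (!is.null(km))
      starts[[length(starts) + 1]] <-
        list(m = sort(km$centers[, 1]),
             s = pmax(sqrt(km$withinss / pmax(km$size - 1, 1))[order(km$centers[, 1])], 0.3),
             w = km$size[order(km$centers[, 1])] / length(data) * n)
  }
  # quantile-spread start
  qs <- stats::quantile(xw, probs = (seq_len(K) - 0.5) / K)
  starts[[length(starts) + 1]] <-
    list(m = as.numeric(qs), s = rep(diff(span) / (4 * K), K),
         w = rep(n / K, K))
  for (j in seq_len(max(0, n_starts - length(starts)))) {
    starts[[length(starts) + 1]] <-
      list(m = sort(stats::runif(K, span[1], span[2])),
           s = stats::runif(K, 0.5, diff(span) / K),
           w = rep(n / K, K))
  }
  binw <- if (length(centers) > 1) centers[2] - centers[1] else 1
  # identifiability floor: a histogram with bin width binw cannot resolve a
  # component narrower than binw/2, nor two peaks closer than one bin
  s_min <- binw / 2
  best <- NULL
  for (st in starts) {
    par0 <- c(st$w * binw, st$m, pmax(st$s, s_min * 1.1))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0,
        fn = function(p) counts - gauss_sum(p, centers, K),
        lower = c(rep(1e-6, K), rep(span[1] - 2, K), rep(s_min, K)),
        upper = c(rep(10 * n * binw, K), rep(span[2] + 2, K),
                  rep(diff(span), K)),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    s_hat <- fit$par[2 * K + 1:K]
    if (any(s_hat <= s_min * 1.02)) next           # degenerate component
    m_hat <- sort(fit$par[K + 1:K])
    if (K > 1 && any(diff(m_hat) < binw)) next
    if (is.null(best) || sse < best$sse) best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best)) return(NULL)
  o <- order(best$par[K + 1:K])
  w <- best$par[1:K][o] / sum(best$par[1:K])
  list(means = best$par[K + 1:K][o], sds = best$par[2 * K + 1:K][o],
       weights = w, sse = best$sse, n_par = 3 * K)
}

#' Gaussian multi-peak decomposition of a threshold distribution
#'
#' Origin-style "multiple peak fit": the thresholds are binned into a
#' histogram and, for each candidate K, a sum of K Gaussian curves is fitted
#' to the bin counts by bounded least squares with multiple starts. K is
#' selected as the smallest candidate whose additional component fails an
#' F test on the SSE reduction (alpha 0.05); BIC over the candidates is
#' reported alongside.
#'
#' @param thresholds per-cell heat thresholds in degrees C.
#' @param K_candidates candidate component counts (default 1:5); each K
#'   requires at least 5 K observations.
#' @param breaks histogram breaks; default 1-degree bins over [32, 55]
#'   extended to cover the data.
#' @param alpha F-test level for the K selection.
#' @return object of class `mixture_fit`: `K`, `means`, `sds`, `weights`
#'   (sorted by mean), `sse`, and `candidates` (per-K SSE, F p value, BIC).
#' @export
fit_threshold_mixture <- function(thresholds, K_candidates = 1:5,
                                  breaks = NULL, alpha = 0.05) {
  thresholds <- thresholds[is.finite(thresholds)]
  if (length(thresholds) == 0) stop("no thresholds")
  K_candidates <- sort(unique(K_candidates))
  K_candidates <- K_candidates[length(thresholds) >= 5 * K_candidates]
  if (length(K_candidates) == 0) stop("too few observations for any candidate K")

  if (stats::sd(thresholds) < 1e-9) {            # degenerate: single value
    return(structure(list(K = 1L, means = thresholds[1], sds = 0,
                          weights = 1, sse = 0,
                          candidates = data.frame(K = 1L, sse = 0,
                                                  f_p = NA_real_,
                                                  bic = NA_real_)),
                     class = "mixture_fit"))
  }
  if (is.null(breaks)) {
    lo <- min(32, floor(min(thresholds)))
    hi <- max(55, ceiling(max(thresholds)))
    breaks <- seq(lo, hi, by = 1)
  }
  h <- graphics::hist(thresholds, breaks = breaks, plot = FALSE)
  centers <- h$mids; counts <- h$counts
  nb <- length(centers)

  fits <- list(); cand <- NULL
  for (K in K_candidates) {
    f <- fit_gauss_k(centers, counts, K, data = thresholds)
    if (is.null(f)) next                         # persistent degeneracy: reject K
    bic <- nb * log(f$sse / nb) + f$n_par * log(nb)
    fits[[as.character(K)]] <- f
    cand <- rbind(cand, data.frame(K = K, sse = f$sse, f_p = NA_real_,
                                   bic = bic))
  }
  if (is.null(cand)) stop("no candidate K produced a non-degenerate fit")
  # F tests on the SSE reduction of each added component. The selected K is
  # the largest candidate whose added component still achieves a significant
  # reduction: stopping at the first non-significant step is misleading when
  # an intermediate model misfits so badly that it inflates the denominator
  # (e.g. a clearly 4-modal histogram where the 1-vs-2 step is "flat").
  sel <- cand$K[1]
  for (i in seq_len(nrow(cand) - 1)) {
    k0 <- cand$K[i]; k1 <- cand$K[i + 1]
    df1 <- 3 * (k1 - k0)
    df2 <- nb - 3 * k1
    if (df2 <= 0) break
    fstat <- ((cand$sse[i] - cand$sse[i + 1]) / df1) / (cand$sse[i + 1] / df2)
    pval <- stats::pf(max(fstat, 0), df1, df2, lower.tail = FALSE)
    cand$f_p[i + 1] <- pval
    if (pval < alpha) sel <- k1
  }
  f <- fits[[as.character(sel)]]
  structure(list(K = sel, means = f$means, sds = f$sds,
                 weights = f$weights, sse = f$sse, candidates = cand),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: K = %d\n", x$K))
  print(data.frame(mean_C = round(x$means, 2), sd_C = round(x$sds, 2),
                   weight = round(x$weights, 3)))
  invisible(x)
}

#' Cumulative (population) heat threshold
#'
#' Two summaries of a pooled threshold distribution: `pooled-fit` fits a
#' single Gaussian to the pooled histogram and reports its mean;
#' `weighted-mean` takes the mixture-weighted mean of the fitted component
#' means.
#'
#' @param thresholds per-cell thresholds in degrees C.
#' @param mode "pooled-fit" or "weighted-mean".
#' @param mixture a [fit_threshold_mixture()] result for the weighted-mean
#'   mode; fitted on the fly when missing.
#' @return single temperature in degrees C.
#' @export
cumulative_threshold <- function(thresholds,
                                 mode = c("pooled-fit", "weighted-mean"),
                                 mixture = NULL) {
  mode <- match.arg(mode)
  thresholds <- thresholds[is.finite(thresholds)]
  if (length(thresholds) == 0) stop("no thresholds")
  if (length(thresholds) == 1) return(thresholds)
  if (mode == "pooled-fit") {
    fit <- fit_threshold_mixture(thresholds, K_candidates = 1)
    fit$means[1]
  } else {
    if (is.null(mixture)) mixture <- fit_threshold_mixture(thresholds)
    sum(mixture$weights * mixture$means)
  }
}
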