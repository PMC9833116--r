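test_that("a noiseless two-line trace recovers the planted intersection to < 0.05 C", {
  g <- gen_heat_ramp_cohort(1, component_means_C = 44.4, component_sds_C = 0,
                            component_weights = 1, baseline_sd = 0, seed = 1)
  expect_true(accelerating_filter(g$traces[[1]]))
  est <- arrhenius_threshold(g$traces[[1]])
  expect_true(est$accepted)
  expect_lt(abs(est$threshold_C - 44.4), 0.05)
  expect_gt(abs(est$fit$supra_slope), abs(est$fit$sub_slope))
})

test_that("straight-line and flat traces fail the accelerating filter", {
  t_s <- seq(0, 260, 2)
  temp <- ifelse(t_s <= 30, 32, 32 + (t_s - 30) * 0.1)
  x <- 1000 / (temp + 273.15)
  win <- data.frame(label = "heat ramp", start_s = 30, end_s = 260,
                    is_depolarising = FALSE)
  one_line <- 1 + ifelse(t_s > 30, 10^(-1 - 3 * (x - x[16])), 0)
  tr1 <- ca_trace("line", t_s, one_line, win, temp)
  expect_false(accelerating_filter(tr1))
  set.seed(2)
  tr2 <- ca_trace("flat", t_s, rnorm(length(t_s), 1, 0.005), win, temp)
  expect_false(accelerating_filter(tr2))
})

test_that("a reversed ramp violates the monotone-temperature precondition", {
  t_s <- seq(0, 260, 2)
  temp <- rev(ifelse(t_s <= 30, 32, 32 + (t_s - 30) * 0.1))
  win <- data.frame(label = "heat ramp", start_s = 30, end_s = 260,
                    is_depolarising = FALSE)
  tr <- ca_trace("rev", t_s, rep(1, length(t_s)), win, temp)
  expect_error(accelerating_filter(tr), "monotone")
})

test_that("the exhaustive breakpoint search matches a naive lm-based oracle", {
  g <- gen_heat_ramp_cohort(3, seed = 5)
  for (tr in g$traces) {
    pts <- nociomics:::arrhenius_points(tr)
    n <- length(pts$x)
    # independent oracle: lm() on every admissible split
    best_sse <- Inf; best_i <- NA
    for (i in 5:(n - 5)) {
      f1 <- lm(pts$y[1:i] ~ pts$x[1:i])
      f2 <- lm(pts$y[(i + 1):n] ~ pts$x[(i + 1):n])
      sse <- sum(resid(f1)^2) + sum(resid(f2)^2)
      if (sse < best_sse) { best_sse <- sse; best_i <- i }
    }
    two <- nociomics:::two_segment_fit(pts$x, pts$y)
    expect_equal(two$break_index, best_i)
    expect_equal(two$sse_total, best_sse, tolerance = 1e-9)
  }
})

test_that("threshold estimates are invariant to a positive rescaling of the ratio", {
  g <- gen_heat_ramp_cohort(1, component_means_C = 41, component_sds_C = 0,
                            component_weights = 1, baseline_sd = 0, seed = 3)
  tr <- g$traces[[1]]
  tr2 <- tr; tr2$ratio <- 3.7 * tr$ratio
  e1 <- arrhenius_threshold(tr)
  e2 <- arrhenius_threshold(tr2)
  expect_equal(e2$threshold_C, e1$threshold_C, tolerance = 1e-6)
})

test_that("per-cell threshold recovery is accurate on a noisy cohort", {
  g <- gen_heat_ramp_cohort(100, seed = 3)
  ct <- cohort_thresholds(g$traces)
  err <- abs(ct$threshold_C - g$truth$true_threshold_C)
  expect_gt(mean(ct$accepted), 0.9)
  expect_lt(median(err[ct$accepted], na.rm = TRUE), 1)
})

test_that("identical thresholds collapse to a single exact component", {
  f <- fit_threshold_mixture(rep(44.4, 60))
  expect_equal(f$K, 1L)
  expect_equal(f$means, 44.4)
})

test_that("the four-population cohort is decomposed with K = 4 and accurate means", {
  thr <- draw_mixture(400, population_means, rep(1, 4), rep(0.25, 4), seed = 1)
  fit <- fit_threshold_mixture(thr, K_candidates = 1:5)
  expect_equal(fit$K, 4L)
  expect_true(all(abs(fit$means - population_means) < 0.5))
  expect_true(all(diff(fit$means) > 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$sds > 0))
})

test_that("K selection finds 3 components on a clean 3-component draw", {
  thr <- draw_mixture(300, c(34, 42, 50), rep(1, 3), rep(1 / 3, 3), seed = 5)
  expect_equal(fit_threshold_mixture(thr)$K, 3L)
})

test_that("mixture recovery bias and RMSE stay within band on a well-separated battery", {
  errs <- sapply(1:6, function(seed) {
    thr <- draw_mixture(400, population_means, rep(1, 4), rep(0.25, 4), seed)
    fit_threshold_mixture(thr, K_candidates = 4)$means - population_means
  })
  expect_true(all(abs(rowMeans(errs)) < 0.3))
  expect_true(all(sqrt(rowMeans(errs^2)) < 0.8))
})

test_that("lowering the two upper components by 2 and 4 C moves the fitted means accordingly", {
  shifted <- population_means - c(0, 0, 2, 4)
  t0 <- draw_mixture(400, population_means, rep(1, 4), rep(0.25, 4), seed = 1)
  t1 <- draw_mixture(400, shifted, rep(1, 4), rep(0.25, 4), seed = 101)
  f0 <- fit_threshold_mixture(t0, K_candidates = 4)
  f1 <- fit_threshold_mixture(t1, K_candidates = 4)
  expect_true(all(abs((f0$means - f1$means) - c(0, 0, 2, 4)) < 0.5))
  expect_true(all(abs(f1$means - shifted) < 0.5))
})

test_that("the histogram fit agrees with an EM fit on raw thresholds", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  thr <- draw_mixture(400, population_means, rep(1, 4), rep(0.25, 4), seed = 2)
  fit <- fit_threshold_mixture(thr, K_candidates = 4)
  em <- mclust::Mclust(thr, G = 4, modelNames = "V", verbose = FALSE)
  expect_true(all(abs(sort(em$parameters$mean) - fit$means) < 0.5))
})

test_that("cumulative threshold summaries behave on degenerate and symmetric inputs", {
  expect_equal(cumulative_threshold(41.8, "pooled-fit"), 41.8)
  expect_equal(cumulative_threshold(41.8, "weighted-mean"), 41.8)
  # symmetric two-component mixture: weighted mean sits at the midpoint
  thr <- draw_mixture(500, c(40, 44), c(1.5, 1.5), c(0.5, 0.5), seed = 4)
  mix <- fit_threshold_mixture(thr, K_candidates = 2)
  wm <- cumulative_threshold(thr, "weighted-mean", mixture = mix)
  expect_lt(abs(wm - 42), 0.4)
  pf <- cumulative_threshold(thr, "pooled-fit")
  expect_lt(abs(pf - wm), 1)
  # the two summaries stay close on the near-symmetric planted cohort
  thr4 <- draw_mixture(400, population_means, rep(1, 4), rep(0.25, 4),
                       seed = 6)
  mix4 <- fit_threshold_mixture(thr4, K_candidates = 4)
  wm4 <- cumulative_threshold(thr4, "weighted-mean", mixture = mix4)
  expect_lt(abs(wm4 - mean(population_means)), 1)
})
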