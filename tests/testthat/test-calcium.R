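test_that("baseline statistics are exact on constant and consistent on Gaussian baselines", {
  t_s <- seq(0, 140, 2)
  tr <- ca_trace("c", t_s, rep(2.5, length(t_s)),
                 data.frame(label = "drug", start_s = 60, end_s = 90,
                            is_depolarising = FALSE))
  b <- baseline_stats(tr, 1)
  expect_equal(b$mu, 2.5)
  expect_equal(b$sd, 0)

  set.seed(7)
  t_l <- seq(0, 2.1e4, 2)
  trl <- ca_trace("c2", t_l, rnorm(length(t_l), 1, 0.05),
                  data.frame(label = "drug", start_s = 2.05e4, end_s = 2.09e4,
                             is_depolarising = FALSE))
  bl <- baseline_stats(trl, 1, baseline_s = 2e4)
  expect_lt(abs(bl$sd - 0.05) / 0.05, 0.03)
})

test_that("a baseline truncated by an earlier window raises an error", {
  t_s <- seq(0, 200, 2)
  win <- data.frame(label = c("a", "b"), start_s = c(60, 96),
                    end_s = c(90, 130), is_depolarising = c(FALSE, FALSE))
  tr <- ca_trace("c", t_s, rep(1, length(t_s)), win)
  expect_error(baseline_stats(tr, 2), "truncated")
})

test_that("the 3-sigma amplitude boundary is strict", {
  tr3 <- plateau_trace(3)       # amplitude exactly 3 baseline SDs
  call3 <- call_response(tr3, 1)
  expect_false(call3$responded)
  expect_equal(call3$amplitude, 3 * call3$baseline_sd)
  tr10 <- plateau_trace(10)
  call10 <- call_response(tr10, 1)
  expect_true(call10$responded)
  expect_gte(call10$onset_s, 60)
})

test_that("a transient entirely before the window is not a response", {
  t_s <- seq(0, 140, 2)
  set.seed(8)
  r <- rnorm(length(t_s), 1, 0.01)
  r[t_s >= 20 & t_s <= 40] <- r[t_s >= 20 & t_s <= 40] + 1   # early transient
  tr <- ca_trace("c", t_s, r,
                 data.frame(label = "drug", start_s = 80, end_s = 110,
                            is_depolarising = FALSE))
  expect_false(call_response(tr, 1)$responded)
})

test_that("flat degenerate traces are flagged, not called", {
  t_s <- seq(0, 140, 2)
  tr <- ca_trace("c", t_s, rep(1, length(t_s)),
                 data.frame(label = "drug", start_s = 60, end_s = 90,
                            is_depolarising = FALSE))
  call <- call_response(tr, 1)
  expect_false(call$responded)
  expect_true(call$degenerate)
})

test_that("amplitude and AUC are invariant to an additive offset", {
  g <- gen_calcium_traces(3, class_mix = c(compound = 1), seed = 9)
  tr <- g$traces[[1]]
  tr2 <- tr; tr2$ratio <- tr$ratio + 5
  a <- call_response(tr, 1); b <- call_response(tr2, 1)
  expect_equal(b$amplitude, a$amplitude, tolerance = 1e-12)
  expect_equal(b$auc, a$auc, tolerance = 1e-9)
})

test_that("responder labels are recovered on a well-separated cohort", {
  g <- gen_calcium_traces(1000, class_mix = c(compound = 0.5, dead = 0.5),
                          baseline_sd = 0.01, amp_mean = 0.1, seed = 1)
  calls <- call_cohort(g$traces)
  lp <- calls[calls$window == "LPC 30uM", ]
  comp <- g$truth$cell_id[g$truth$cell_class == "compound"]
  recovery <- mean(comp %in% lp$cell_id[lp$responded])
  expect_gte(recovery, 0.99)
})

test_that("the viability gate retains exactly the non-dead cells", {
  g <- gen_calcium_traces(200, seed = 1)
  calls <- call_cohort(g$traces)
  viab <- viability_filter(calls)
  nondead <- g$truth$cell_id[g$truth$cell_class != "dead"]
  expect_setequal(viab, nondead)
  expect_true(all(viab %in% g$truth$cell_id))

  gd <- gen_calcium_traces(30, class_mix = c(dead = 1), seed = 2)
  expect_length(viability_filter(call_cohort(gd$traces)), 0)
})

test_that("pooled counts satisfy the set identities", {
  g <- gen_calcium_traces(150, seed = 3)
  calls <- call_cohort(g$traces)
  vc <- calls[calls$cell_id %in% viability_filter(calls), ]
  pc <- pool_counts(vc, cross = c("LPC 30uM", "capsaicin 500nM"))
  expect_true(all(pc$per_label$responders <= pc$per_label$total))
  lp <- vc[vc$window == "LPC 30uM", ]
  cp <- vc[vc$window == "capsaicin 500nM", ]
  both <- length(intersect(lp$cell_id[lp$responded], cp$cell_id[cp$responded]))
  expect_equal(unname(pc$cross["resp", "resp"]), both)
  expect_equal(sum(pc$cross), nrow(lp))
  expect_error(pool_counts(vc, labels = "no such window"), "absent")
})

test_that("a cohort built with the observed co-response composition reproduces it", {
  # 322 of 372 LPC responders also respond to capsaicin (86.6%)
  rm <- list(both = c("LPC 30uM", "capsaicin 500nM", "KCl 60mM"),
             lpc_only = c("LPC 30uM", "KCl 60mM"))
  g1 <- gen_calcium_traces(322, class_mix = c(both = 1), response_map = rm,
                           baseline_sd = 0.005, seed = 4)
  g2 <- gen_calcium_traces(50, class_mix = c(lpc_only = 1), response_map = rm,
                           baseline_sd = 0.005, seed = 5)
  for (i in seq_along(g2$traces)) {
    g2$traces[[i]]$cell_id <- paste0("X", g2$traces[[i]]$cell_id)
  }
  traces <- c(g1$traces, g2$traces)
  calls <- call_cohort(traces)
  vc <- calls[calls$cell_id %in% viability_filter(calls), ]
  lp <- vc[vc$window == "LPC 30uM", ]
  cp <- vc[vc$window == "capsaicin 500nM", ]
  lpc_resp <- lp$cell_id[lp$responded]
  co <- intersect(lpc_resp, cp$cell_id[cp$responded])
  expect_equal(length(lpc_resp), 372)
  expect_equal(responder_percent(length(co), length(lpc_resp), 1), 86.6)
})

test_that("normalised amplitude is 1 for the first pulse by construction", {
  win <- data.frame(label = c("cap1", "cap2", "cap3", "KCl 60mM"),
                    start_s = c(60, 150, 240, 330),
                    end_s = c(90, 180, 270, 360),
                    is_depolarising = c(FALSE, FALSE, FALSE, TRUE))
  rm <- list(resp = win$label)
  g <- gen_calcium_traces(20, class_mix = c(resp = 1), windows = win,
                          response_map = rm, seed = 6)
  calls <- call_cohort(g$traces)
  pt <- pulse_response_table(calls, c("cap1", "cap2", "cap3"))
  expect_true(all(pt$norm_amplitude[pt$pulse == 1] == 1))
  expect_equal(nrow(pt), 60)
})

test_that("the false-positive rate of the 3-sigma rule on pure noise is small and seed-stable", {
  fp_rate <- function(seed) {
    g <- gen_calcium_traces(2000, class_mix = c(kcl_only = 1),
                            baseline_sd = 0.01, seed = seed)
    calls <- call_cohort(g$traces)
    lp <- calls[calls$window == "LPC 30uM", ]
    mean(lp$responded)
  }
  r1 <- fp_rate(1); r2 <- fp_rate(2)
  expect_lt(r1, 0.02)
  expect_lt(abs(r1 - r2), 0.02)
})
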