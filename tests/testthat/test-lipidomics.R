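test_that("weight normalisation divides biological rows by weight and QC rows by the mean weight", {
  tab <- gen_lipidomics_cohort(4, 10, seed = 1)
  wn <- normalize_by_weight(tab)
  s <- tab$samples
  i <- which(!s$qc)[3]
  expect_equal(wn$intensities[i, ],
               tab$intensities[i, ] / s$weight_mg[i])
  iq <- which(s$qc)[1]
  expect_equal(wn$intensities[iq, ],
               tab$intensities[iq, ] / mean(s$weight_mg[!s$qc]))

  tab1 <- tab; tab1$samples$weight_mg[!s$qc] <- 1
  expect_equal(normalize_by_weight(tab1)$intensities[!s$qc, ],
               tab$intensities[!s$qc, ])
  tab2 <- tab; tab2$samples$weight_mg[i] <- 2 * s$weight_mg[i]
  expect_equal(normalize_by_weight(tab2)$intensities[i, ],
               wn$intensities[i, ] / 2)
  tab3 <- tab; tab3$samples$weight_mg[i] <- NA
  expect_error(normalize_by_weight(tab3), "missing weight")
})

test_that("QC CV filter reproduces the hand-computed toy decision", {
  m <- rbind(c(100, 50), c(100, 50), c(180, 50))
  tab <- feature_table(
    rbind(matrix(100, 4, 2), m),
    data.frame(feature_id = c("fA", "fB")),
    data.frame(sample_id = paste0("s", 1:7),
               condition = c("burn", "burn", "control", "control",
                             rep(NA, 3)),
               qc = c(rep(FALSE, 4), rep(TRUE, 3)),
               weight_mg = c(rep(1, 4), rep(NA, 3))))
  out <- qc_cv_filter(tab, threshold = 0.30)
  # sd(100,100,180)/mean = 46.188/126.667 = 0.3646 > 0.30 -> discarded
  expect_equal(out$report$qc_cv[1], sd(c(100, 100, 180)) / mean(c(100, 100, 180)))
  expect_false(out$report$kept[1])
  expect_true(out$report$kept[2])                 # CV = 0 kept
  expect_equal(out$table$features$feature_id, "fB")
  expect_error(qc_cv_filter(subset_feature_table(tab, samples = 1:5)),
               "2 QC")
})

test_that("transform stack yields exactly standardised feature columns", {
  tab <- gen_lipidomics_cohort(8, 30, seed = 2)
  tr <- transform_stack(normalize_by_weight(tab))
  m <- tr$intensities
  expect_lt(max(abs(colMeans(m))), 1e-10)
  expect_lt(max(abs(apply(m, 2, var) - 1)), 1e-10)
  expect_error(transform_stack(tab, glog_lambda = -1), "lambda")
})

test_that("glog approaches log2 for positive x as lambda vanishes", {
  x <- c(0.5, 1, 10, 1e4)
  expect_equal(glog(x, 1e-12), log2(x), tolerance = 1e-9)
  expect_true(all(is.finite(glog(c(0, x), 5))))
})

test_that("median scaling leaves a rescaled sample invariant", {
  tab <- gen_lipidomics_cohort(6, 21, seed = 3)
  wn <- normalize_by_weight(tab)
  med <- apply(wn$intensities, 1, median)
  i <- which(!wn$samples$qc)[which.max(med[!wn$samples$qc])]
  tab10 <- wn
  tab10$intensities[i, ] <- 10 * wn$intensities[i, ]
  lam <- 0.01
  a <- transform_stack(wn, glog_lambda = lam)
  b <- transform_stack(tab10, glog_lambda = lam)
  expect_equal(b$intensities[i, ], a$intensities[i, ], tolerance = 1e-10)
})

test_that("Welch tests match stats::t.test and degenerate identically-distributed groups", {
  set.seed(4)
  x1 <- matrix(rnorm(10 * 20, sd = 2), 10)
  x2 <- matrix(rnorm(12 * 20), 12)
  res <- nociomics:::welch_t_matrix(x1, x2)
  for (j in c(1, 7, 20)) {
    tt <- t.test(x1[, j], x2[, j])
    expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$df[j], unname(tt$parameter), tolerance = 1e-12)
    expect_equal(res$p[j], tt$p.value, tolerance = 1e-12)
  }
  # identical groups: t = 0, p = 1, q = 1
  tab <- feature_table(matrix(rep(c(5, 6, 5, 6), 2), 4, 2),
                       data.frame(feature_id = c("f1", "f2")),
                       data.frame(sample_id = paste0("s", 1:4),
                                  condition = c("burn", "burn", "control",
                                                "control"),
                                  qc = FALSE, weight_mg = 1))
  r <- welch_holm(tab)
  expect_equal(r$t, c(0, 0))
  expect_equal(r$p, c(1, 1))
  expect_equal(r$q, c(1, 1))
  # single feature: q equals p
  r1 <- welch_holm(subset_feature_table(tab, features = 1))
  expect_equal(r1$q, r1$p)
})

test_that("Holm keeps the family-wise error rate at or below alpha on planted nulls", {
  set.seed(5)
  hits <- replicate(1000, {
    res <- nociomics:::welch_t_matrix(matrix(rnorm(500), 10),
                                      matrix(rnorm(500), 10))
    any(holm_adjust(res$p) < 0.05)
  })
  fwer <- mean(hits)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(fwer, 0.05 + 2 * se)
})

test_that("planted 5x fold changes are recovered with q < 0.05 at high power", {
  detected <- 0; planted_total <- 0
  for (seed in 1:10) {
    fc <- stats::setNames(rep(5, 5), sprintf("L%04d", 1:5))
    tab <- gen_lipidomics_cohort(10, 200, planted_fc = fc, noise_cv = 0.2,
                                 seed = seed)
    out <- lipidomics_pipeline(tab)
    hit <- out$results$feature_id[out$results$significant]
    detected <- detected + sum(names(fc) %in% hit)
    planted_total <- planted_total + length(fc)
  }
  expect_gte(detected / planted_total, 0.9)
})

test_that("pipeline report is deterministic and records the stage order", {
  tab <- gen_lipidomics_cohort(6, 40, planted_fc = c(L0002 = 3), seed = 6)
  a <- lipidomics_pipeline(tab)
  b <- lipidomics_pipeline(tab)
  expect_identical(a$results, b$results)
  expect_identical(a$table$intensities, b$table$intensities)
  expect_equal(a$steps[1], "weight_normalisation")
  expect_equal(tail(a$steps, 1), "welch_holm")
})

test_that("observed LPC ions annotate to the expected adducts", {
  # implementer-derived monoisotopic mass oracle for 18:0 LPC (C26H54NO7P)
  m_expected <- 26 * 12 + 54 * 1.0078250319 + 14.0030740052 +
    7 * 15.9949146221 + 30.97376151
  expect_equal(monoisotopic_mass("C26H54NO7P"), m_expected, tolerance = 1e-9)

  hits <- match_adducts(524.3943, "ESI+")
  h <- hits[hits$name == "18:0 LPC" & hits$adduct == "M+H", ]
  expect_equal(nrow(h), 1)
  expect_lte(abs(h$delta_da), 0.05)

  hits2 <- match_adducts(546.329, "ESI+")
  h2 <- hits2[hits2$name == "18:0 LPC" & hits2$adduct == "M+Na", ]
  expect_equal(nrow(h2), 1)
  expect_lte(abs(h2$delta_da), 0.05)

  # exact M+H: zero delta, zero ppm, promising
  exact <- monoisotopic_mass("C26H54NO7P") + 1.007276
  h3 <- match_adducts(exact, "ESI+")
  h3 <- h3[h3$name == "18:0 LPC" & h3$adduct == "M+H", ]
  expect_equal(h3$delta_da, 0)
  expect_equal(h3$delta_ppm, 0)
  expect_true(h3$promising)

  # negative mode searches M-H only
  neg <- match_adducts(monoisotopic_mass("C24H50NO7P") - 1.007276, "ESI-")
  expect_true(all(neg$adduct == "M-H"))
  expect_true("16:0 LPC" %in% neg$name)
  expect_error(match_adducts(500, "APCI"), "arg")
})
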