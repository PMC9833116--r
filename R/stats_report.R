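#' Round half to even at a given number of decimals
#'
#' IEC 60559 banker's rounding, the convention used for all reported
#' percentages.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_even <- function(x, digits = 2) round(x, digits)

#' Responder percentage from counts
#'
#' @param responders,total non-negative integer counts.
#' @param digits decimals reported (default 2, round half even).
#' @return percentage on the 0-100 scale.
#' @export
responder_percent <- function(responders, total, digits = 2) {
  stopifnot(all(total > 0), all(responders >= 0), all(responders <= total))
  round_half_even(100 * responders / total, digits)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with the point-probability two-sided
#' convention: p is the sum over all tables with the observed margins whose
#' probability does not exceed the observed table's (with a small relative
#' slack for floating-point ties).
#'
#' @param a,b,c,d counts: responders/non-responders (rows) by group
#'   (columns), or a 2x2 matrix passed as `a`.
#' @return list `p`, `method`, `table`.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2, 2)
  if (any(m != round(m)) || any(m < 0)) stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) stop("zero margin")
  p <- stats::fisher.test(m)$p.value
  list(p = min(p, 1), method = "Fisher exact (two-sided, point probability)",
       table = m)
}

#' Fisher-Freeman-Halton exact test for an r x 2 table
#'
#' Exact conditional test over all r x 2 tables with the observed margins;
#' for large totals an exact network evaluation becomes infeasible and a
#' Monte-Carlo p with its standard error is returned instead.
#'
#' @param counts r x 2 matrix (e.g. responders and non-responders per
#'   concentration).
#' @param exact_max largest total for which the exact computation is
#'   attempted (default 3000).
#' @param B Monte-Carlo replicates for the fallback.
#' @return list `p`, `method`, and `mc_se` (NA for exact).
#' @export
fisher_exact_rx2 <- function(counts, exact_max = 3000, B = 1e5) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2) stop("counts must have 2 columns")
  if (any(counts != round(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin")
  if (sum(counts) <= exact_max) {
    p <- stats::fisher.test(counts, workspace = 2e7)$p.value
    list(p = min(p, 1), method = "Freeman-Halton exact", mc_se = NA_real_)
  } else {
    ft <- stats::fisher.test(counts, simulate.p.value = TRUE, B = B)
    p <- ft$p.value
    list(p = p, method = sprintf("Monte-Carlo (B=%d)", B),
         mc_se = sqrt(p * (1 - p) / B))
  }
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p p values in [0, 1].
#' @return adjusted q values (monotone, q >= p).
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Benjamini-Hochberg-Yekutieli step-up adjustment
#'
#' FDR control under arbitrary dependence (harmonic-sum inflation of the
#' Benjamini-Hochberg q values).
#'
#' @param p p values in [0, 1].
#' @return adjusted q values.
#' @export
bh_yekutieli_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' One-way ANOVA with Bonferroni-adjusted pairwise Welch comparisons
#'
#' @param groups named list of numeric vectors (one per group, each n >= 2).
#' @return list `f`, `df`, `p`, and `pairwise` data.frame of
#'   Bonferroni-adjusted unequal-variance t comparisons.
#' @export
anova_oneway_bonferroni <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("every group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  if (stats::var(y) == 0) {
    fstat <- 0; pval <- 1
    dfs <- c(length(groups) - 1, length(y) - length(groups))
    tab <- data.frame(group1 = character(0), group2 = character(0),
                      q = numeric(0))
  } else {
    a <- stats::anova(stats::lm(y ~ g))
    fstat <- a$`F value`[1]; pval <- a$`Pr(>F)`[1]
    dfs <- a$Df
    pw <- stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                                 pool.sd = FALSE)
    tab <- as.data.frame(as.table(pw$p.value), stringsAsFactors = FALSE)
    names(tab) <- c("group1", "group2", "q")
    tab <- tab[!is.na(tab$q), ]
    rownames(tab) <- NULL
  }
  list(f = fstat, df = dfs, p = pval, pairwise = tab)
}

#' Responder counts from the LPC calcium-imaging experiments
#'
#' The pooled responder/total counts behind the study's reported
#' proportions: concentration-dependent LPC responses, LPC/capsaicin
#' co-classification, antagonist (tranilast, capsazepine) and knockout
#' comparisons, lateral-pressure block, and the heat-ramp response rates
#' with and without LPC pretreatment.
#'
#' @return data.frame `label`, `group`, `responders`, `total`,
#'   `reported_percent` (the percentage as printed in the source tables,
#'   used for cross-checking the arithmetic).
#' @export
lpc_response_counts <- function() {
  read_counts <- function(...) {
    d <- data.frame(..., stringsAsFactors = FALSE)
    names(d) <- c("label", "group", "responders", "total", "reported_percent")
    d
  }
  rbind(
    read_counts("LPC any 3-30uM", "pooled", 466L, 1940L, 24),
    read_counts("LPC responders also capsaicin", "pooled", 322L, 372L, 86.6),
    read_counts("capsaicin responders not LPC", "pooled", 477L, 799L, 59.7),
    read_counts("LPC+capsaicin co-response", "3uM", 16L, 256L, 6.25),
    read_counts("LPC+capsaicin co-response", "10uM", 90L, 528L, 17.05),
    read_counts("LPC+capsaicin co-response", "30uM", 216L, 747L, 28.92),
    read_counts("LPC only", "3uM", 5L, 256L, 1.95),
    read_counts("LPC only", "10uM", 19L, 528L, 3.6),
    read_counts("LPC only", "30uM", 26L, 747L, 3.48),
    read_counts("capsaicin overall", "3uM", 88L, 256L, 34.38),
    read_counts("capsaicin overall", "10uM", 252L, 528L, 47.73),
    read_counts("capsaicin overall", "30uM", 459L, 747L, 61.46),
    read_counts("tranilast block", "control", 34L, 201L, 16.92),
    read_counts("tranilast block", "tranilast", 3L, 106L, 2.83),
    read_counts("capsazepine block", "control", 103L, 418L, 24.64),
    read_counts("capsazepine block", "capsazepine", 25L, 348L, 7.18),
    read_counts("TRPV1 knockout", "wild-type", 124L, 280L, 44.29),
    read_counts("TRPV1 knockout", "TRPV1-KO", 1L, 234L, 0.44),
    read_counts("chlorpromazine block", "control", 69L, 217L, 31.8),
    read_counts("chlorpromazine block", "chlorpromazine", 13L, 255L, 5.1),
    read_counts("heat ramp", "control", 57L, 184L, 30.98),
    read_counts("heat ramp", "LPC 1uM", 142L, 441L, 32.2)
  )
}

#' Markdown report over a responder-count table
#'
#' Recomputes every percentage by pure arithmetic (round half even) and runs
#' the two-group Fisher exact comparisons within each label.
#'
#' @param counts data.frame as from [lpc_response_counts()] (columns
#'   `label`, `group`, `responders`, `total`).
#' @return list `table` (with recomputed `percent`), `fisher` (per-label
#'   pairwise exact p values for labels with exactly two groups), and
#'   `markdown` (character vector of report lines).
#' @export
responder_report <- function(counts = lpc_response_counts()) {
  counts$percent <- responder_percent(counts$responders, counts$total)
  fisher <- NULL
  for (lb in unique(counts$label)) {
    d <- counts[counts$label == lb, ]
    if (nrow(d) == 2 && !anyDuplicated(d$group)) {
      ft <- fisher_exact_2x2(d$responders[1], d$responders[2],
                             d$total[1] - d$responders[1],
                             d$total[2] - d$responders[2])
      fisher <- rbind(fisher,
                      data.frame(label = lb, group1 = d$group[1],
                                 group2 = d$group[2], p = ft$p,
                                 stringsAsFactors = FALSE))
    }
  }
  md <- c("# Responder proportions", "",
          "| label | group | responders | total | percent |",
          "|---|---|---|---|---|",
          sprintf("| %s | %s | %d | %d | %s%% |", counts$label, counts$group,
                  counts$responders, counts$total,
                  formatC(counts$percent, format = "fg")))
  if (!is.null(fisher)) {
    md <- c(md, "", "## Fisher exact comparisons", "",
            sprintf("- %s: %s vs %s, p = %.3g", fisher$label, fisher$group1,
                    fisher$group2, fisher$p))
  }
  list(table = counts, fisher = fisher, markdown = md)
}
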