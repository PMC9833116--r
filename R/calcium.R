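#' Baseline mean and SD before an application window
#'
#' The baseline interval is the `baseline_s` seconds immediately preceding
#' window start, clipped so it never reaches into an earlier window. At
#' least 10 samples must remain after clipping.
#'
#' @param trace a [ca_trace()].
#' @param window one-row windows data.frame (or row index into
#'   `trace$windows`).
#' @param baseline_s baseline length in seconds (default 30).
#' @return list `mu` (mean) and `sd` (sample SD) of the baseline ratio.
#' @export
baseline_stats <- function(trace, window, baseline_s = 30) {
  stopifnot(inherits(trace, "ca_trace"))
  w <- resolve_window(trace, window)
  lo <- w$start_s - baseline_s
  prev_end <- trace$windows$end_s[trace$windows$end_s <= w$start_s &
                                    trace$windows$start_s < w$start_s]
  if (length(prev_end) > 0) lo <- max(lo, max(prev_end))
  idx <- trace$t_s >= lo & trace$t_s < w$start_s
  if (sum(idx) < 10)
    stop("baseline interval truncated: fewer than 10 samples before window")
  list(mu = mean(trace$ratio[idx]), sd = stats::sd(trace$ratio[idx]))
}

resolve_window <- function(trace, window) {
  if (is.numeric(window) && length(window) == 1)
    window <- trace$windows[window, , drop = FALSE]
  stopifnot(is.data.frame(window), nrow(window) == 1)
  window
}

#' Call a calcium response in one application window
#'
#' A change in the ratio counts as a response when its amplitude (window
#' maximum minus baseline mean) strictly exceeds 3 baseline SDs and its
#' onset — the first sample above mu + 3 sd — falls inside the window plus
#' the allowed onset lag, i.e. the response corresponds in time to the drug
#' application. Amplitude and baseline-corrected trapezoid AUC are reported
#' whether or not the call is positive.
#'
#' @param trace a [ca_trace()].
#' @param window one-row windows data.frame or row index.
#' @param onset_lag_s seconds after window end still attributable to the
#'   application (perfusion dead time; default 10).
#' @param baseline_s baseline length passed to [baseline_stats()].
#' @param min_consecutive number of consecutive supra-threshold samples
#'   required to count as a response onset (default 2: a single-sample
#'   excursion is instrument noise, whereas a genuine calcium transient
#'   spans many samples at a 2-s frame interval).
#' @return data.frame row: `cell_id`, `window`, `responded`, `baseline_mu`,
#'   `baseline_sd`, `amplitude`, `auc`, `onset_s` (NA when no sample crosses
#'   the 3 sd line), `degenerate` (flat trace with zero baseline SD and zero
#'   amplitude).
#' @export
call_response <- function(trace, window, onset_lag_s = 10, baseline_s = 30,
                          min_consecutive = 2) {
  stopifnot(inherits(trace, "ca_trace"))
  w <- resolve_window(trace, window)
  b <- baseline_stats(trace, w, baseline_s = baseline_s)
  span <- trace$t_s >= w$start_s & trace$t_s <= w$end_s + onset_lag_s
  if (!any(span)) stop("window outside recording")
  r <- trace$ratio[span]; t <- trace$t_s[span]
  amplitude <- max(r) - b$mu
  auc <- pracma::trapz(t, r - b$mu)
  above <- r > b$mu + 3 * b$sd
  runs <- rle(above)
  sustained <- runs$values & runs$lengths >= min(min_consecutive, length(r))
  onset <- if (any(sustained)) {
    t[c(0, cumsum(runs$lengths))[which(sustained)[1]] + 1]
  } else NA_real_
  degenerate <- b$sd == 0 && amplitude <= 0
  responded <- !degenerate && amplitude > 3 * b$sd && !is.na(onset)
  data.frame(cell_id = trace$cell_id, window = w$label,
             responded = responded, baseline_mu = b$mu, baseline_sd = b$sd,
             amplitude = amplitude, auc = auc, onset_s = onset,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Call every window of every trace in a cohort
#'
#' @param traces list of [ca_trace()].
#' @param onset_lag_s,baseline_s,min_consecutive passed to
#'   [call_response()].
#' @return data.frame of calls, one row per cell x window.
#' @export
call_cohort <- function(traces, onset_lag_s = 10, baseline_s = 30,
                        min_consecutive = 2) {
  calls <- do.call(rbind, lapply(traces, function(tr) {
    do.call(rbind, lapply(seq_len(nrow(tr$windows)), function(w)
      call_response(tr, w, onset_lag_s = onset_lag_s,
                    baseline_s = baseline_s,
                    min_consecutive = min_consecutive)))
  }))
  rownames(calls) <- NULL
  calls
}

#' Viability gate on the depolarising stimulus
#'
#' Retains exactly the cells whose call on the terminal depolarising (KCl)
#' window was positive; cells not responding to the depolarising stimulus
#' are excluded from all downstream analysis.
#'
#' @param calls cohort calls from [call_cohort()].
#' @param depolarising_label label of the depolarising window; default the
#'   single window whose calls carry it (inferred when the cohort has one
#'   KCl-style label).
#' @return character vector of retained cell ids.
#' @export
viability_filter <- function(calls, depolarising_label = NULL) {
  if (is.null(depolarising_label)) {
    kc <- grep("KCl", unique(calls$window), value = TRUE)
    if (length(kc) != 1) stop("cannot infer the depolarising window label")
    depolarising_label <- kc
  }
  dep <- calls[calls$window == depolarising_label, ]
  missing <- setdiff(unique(calls$cell_id), dep$cell_id)
  if (length(missing) > 0)
    stop("cells without a depolarising-window call: ",
         paste(utils::head(missing, 5), collapse = ", "))
  dep$cell_id[dep$responded]
}

#' Pool responder counts across a viable cohort
#'
#' Summarises responders/total per window label and, when two labels are
#' given, the cross-classification (cells responding to both, either, or
#' neither) that feeds the exact contingency tests.
#'
#' @param calls cohort calls, already restricted to viable cells (see
#'   [viability_filter()]).
#' @param labels window labels to summarise; default all non-depolarising
#'   labels present.
#' @param cross optional length-2 character of labels to cross-classify.
#' @return list: `per_label` data.frame (`window`, `responders`, `total`,
#'   `percent`), and `cross` (2x2 matrix of counts) when requested.
#' @export
pool_counts <- function(calls, labels = NULL, cross = NULL) {
  if (is.null(labels))
    labels <- setdiff(unique(calls$window),
                      grep("KCl", unique(calls$window), value = TRUE))
  miss <- setdiff(labels, unique(calls$window))
  if (length(miss) > 0) stop("label absent from all traces: ",
                             paste(miss, collapse = ", "))
  per <- do.call(rbind, lapply(labels, function(lb) {
    d <- calls[calls$window == lb, ]
    data.frame(window = lb, responders = sum(d$responded), total = nrow(d),
               percent = round_half_even(100 * sum(d$responded) / nrow(d), 2),
               stringsAsFactors = FALSE)
  }))
  out <- list(per_label = per)
  if (!is.null(cross)) {
    stopifnot(length(cross) == 2)
    a <- calls[calls$window == cross[1], c("cell_id", "responded")]
    b <- calls[calls$window == cross[2], c("cell_id", "responded")]
    m <- merge(a, b, by = "cell_id", suffixes = c("_1", "_2"))
    out$cross <- table(factor(m$responded_1, c(TRUE, FALSE),
                              c("resp", "nonresp")),
                       factor(m$responded_2, c(TRUE, FALSE),
                              c("resp", "nonresp")),
                       dnn = cross)
  }
  out
}

#' Per-pulse amplitude table for repeated applications
#'
#' For sensitisation/desensitisation analyses across repeated pulses of the
#' same compound: per-cell amplitude and AUC per pulse, plus the amplitude
#' normalised to each cell's first pulse (1 for the first pulse by
#' construction).
#'
#' @param calls cohort calls restricted to the repeated-pulse windows, in
#'   pulse order.
#' @param pulse_order character vector of window labels in application
#'   order.
#' @return data.frame `cell_id`, `pulse`, `window`, `amplitude`, `auc`,
#'   `norm_amplitude`.
#' @export
pulse_response_table <- function(calls, pulse_order) {
  d <- calls[calls$window %in% pulse_order, ]
  d$pulse <- match(d$window, pulse_order)
  d <- d[order(d$cell_id, d$pulse), ]
  d1 <- d[d$pulse == 1, c("cell_id", "amplitude")]
  d$norm_amplitude <- d$amplitude / d1$amplitude[match(d$cell_id, d1$cell_id)]
  d[, c("cell_id", "pulse", "window", "amplitude", "auc", "norm_amplitude")]
}
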