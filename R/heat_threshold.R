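# Arrhenius coordinates of the heat-ramp portion of a trace:
# x = 1000 / T_K, y = log10(R - baseline_mu + eps). eps is a vanishing
# fraction of the baseline SD, only there to keep the log defined at noise
# dips; points at or below baseline after eps are dropped.
arrhenius_points <- function(trace, baseline_s = 30) {
  stopifnot(inherits(trace, "ca_trace"))
  if (is.null(trace$temp_C)) stop("temperature channel required")
  w <- trace$windows[trace$windows$label == "heat ramp", , drop = FALSE]
  if (nrow(w) != 1) {
    ramp <- which(diff(trace$temp_C) > 0)
    if (length(ramp) == 0) stop("no heat ramp found")
    w <- data.frame(start_s = trace$t_s[min(ramp)],
                    end_s = trace$t_s[max(ramp) + 1])
  }
  idx <- which(trace$t_s > w$start_s & trace$t_s <= w$end_s)
  temp <- trace$temp_C[idx]
  if (any(diff(temp) <= 0)) stop("temperature channel not monotone increasing over the ramp")
  pre <- trace$t_s <= w$start_s
  if (sum(pre) < 5) stop("need pre-ramp baseline samples")
  mu <- mean(trace$ratio[pre]); sdb <- stats::sd(trace$ratio[pre])
  eps <- max(1e-3 * sdb, .Machine$double.eps)
  sig <- trace$ratio[idx] - mu + eps
  ok <- sig > 0
  list(x = 1000 / (temp[ok] + 273.15), y = log10(sig[ok]),
       mu = mu, sd = sdb, eps = eps)
}

# closed-form OLS line fit; returns intercept a, slope b, sse
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2); sxy <- sum((x - mx) * (y - my))
  b <- if (sxx > 0) sxy / sxx else 0
  a <- my - b * mx
  sse <- sum((y - a - b * x)^2)
  list(a = a, b = b, sse = sse)
}

# exhaustive two-segment fit over interior breakpoints; each segment keeps
# at least min_pts points. Segments are in time order: the late (hot,
# small-x) points form the supra-threshold segment.
two_segment_fit <- function(x, y, min_pts = 5) {
  n <- length(x)
  if (n < 2 * min_pts) return(NULL)
  best <- NULL
  for (i in min_pts:(n - min_pts)) {
    f1 <- ols_line(x[1:i], y[1:i])
    f2 <- ols_line(x[(i + 1):n], y[(i + 1):n])
    sse <- f1$sse + f2$sse
    if (is.null(best) || sse < best$sse_total) {
      best <- list(sub = f1, supra = f2, break_index = i, sse_total = sse)
    }
  }
  best
}

#' Does a heat-ramp trace show an accelerating calcium rise?
#'
#' A trace qualifies when, in Arrhenius coordinates, a two-segment fit beats
#' a single straight line (two-segment SSE < `sse_ratio` times one-segment
#' SSE) and the supra-threshold slope magnitude exceeds the sub-threshold
#' one by at least `slope_ratio`. Only qualifying traces are eligible for
#' threshold estimation.
#'
#' @param trace a [ca_trace()] with a monotone temperature ramp.
#' @param sse_ratio two- vs one-segment SSE improvement required (default
#'   0.7).
#' @param slope_ratio required supra/sub slope-magnitude ratio (default
#'   1.5).
#' @param baseline_s pre-ramp baseline length used for the ordinate.
#' @return logical flag.
#' @export
accelerating_filter <- function(trace, sse_ratio = 0.7, slope_ratio = 1.5,
                                baseline_s = 30) {
  pts <- arrhenius_points(trace, baseline_s = baseline_s)
  if (length(pts$x) < 10) return(FALSE)
  one <- ols_line(pts$x, pts$y)
  two <- two_segment_fit(pts$x, pts$y)
  if (is.null(two)) return(FALSE)
  if (one$sse <= 1e-10 * length(pts$x)) return(FALSE)  # already a perfect line
  improved <- two$sse_total < sse_ratio * one$sse
  steeper <- if (abs(two$sub$b) == 0) abs(two$supra$b) > 0 else
    abs(two$supra$b) / abs(two$sub$b) > slope_ratio
  isTRUE(improved && steeper && abs(two$supra$b) > abs(two$sub$b))
}

#' Heat-activation threshold from a two-segment Arrhenius fit
#'
#' Exhaustively searches interior breakpoints of the Arrhenius plot, fits
#' independent least-squares lines below and above each candidate, keeps the
#' breakpoint minimising total SSE, and takes the temperature at the
#' analytic intersection of the two extrapolated lines as the cell's heat
#' threshold.
#'
#' @param trace a [ca_trace()] that passed [accelerating_filter()].
#' @param baseline_s pre-ramp baseline length.
#' @param min_pts minimum points per segment (default 5); estimates from
#'   shorter segments are not accepted.
#' @return object of class `threshold_estimate`: `threshold_C`, `accepted`,
#'   and `fit` (slopes, intercepts, breakpoint x, SSE).
#' @export
arrhenius_threshold <- function(trace, baseline_s = 30, min_pts = 5) {
  pts <- arrhenius_points(trace, baseline_s = baseline_s)
  two <- two_segment_fit(pts$x, pts$y, min_pts = min_pts)
  if (is.null(two)) stop("too few ramp points for a two-segment fit")
  b1 <- two$sub$b; b2 <- two$supra$b
  parallel <- abs(b1 - b2) < 1e-12
  x_int <- if (parallel) NA_real_ else (two$supra$a - two$sub$a) / (b1 - b2)
  thr <- if (is.na(x_int)) NA_real_ else 1000 / x_int - 273.15
  x_range <- range(pts$x)
  accepted <- !parallel && is.finite(thr) &&
    x_int >= x_range[1] - 1e-9 && x_int <= x_range[2] + 1e-9 &&
    abs(b2) > abs(b1)
  structure(list(threshold_C = thr, accepted = accepted,
                 fit = list(sub_slope = b1, sub_intercept = two$sub$a,
                            supra_slope = b2, supra_intercept = two$supra$a,
                            break_x = pts$x[two$break_index],
                            sse_total = two$sse_total,
                            n_sub = two$break_index,
                            n_supra = length(pts$x) - two$break_index)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("threshold_estimate: %.2f C (%s)\n", x$threshold_C,
              if (x$accepted) "accepted" else "not accepted"))
  invisible(x)
}

#' Heat thresholds for a whole cohort
#'
#' Applies the accelerating filter and, for qualifying cells, the Arrhenius
#' two-segment threshold estimate.
#'
#' @param traces list of [ca_trace()] with temperature channels.
#' @param ... passed to [accelerating_filter()] / [arrhenius_threshold()].
#' @return data.frame `cell_id`, `accelerating`, `threshold_C`, `accepted`.
#' @export
cohort_thresholds <- function(traces, ...) {
  rows <- lapply(traces, function(tr) {
    acc <- accelerating_filter(tr, ...)
    if (!acc)
      return(data.frame(cell_id = tr$cell_id, accelerating = FALSE,
                        threshold_C = NA_real_, accepted = FALSE,
                        stringsAsFactors = FALSE))
    est <- arrhenius_threshold(tr)
    data.frame(cell_id = tr$cell_id, accelerating = TRUE,
               threshold_C = est$threshold_C, accepted = est$accepted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
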