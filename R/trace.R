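#' Build a ratiometric calcium trace
#'
#' A `ca_trace` is one cell's Fura-2 F355/F380 ratio sampled on a uniform
#' time grid, an optional superfusate temperature channel, and the compound
#' application windows annotated on the recording.
#'
#' @param cell_id character identifier.
#' @param t_s strictly increasing time stamps in seconds (uniform grid).
#' @param ratio F355/F380 ratio, finite, same length as `t_s`.
#' @param windows data.frame with `label`, `start_s`, `end_s`,
#'   `is_depolarising`; windows must be time-ordered, non-overlapping and lie
#'   within the recording; at most one depolarising window, last in time.
#' @param temp_C optional temperature channel in degrees Celsius.
#' @return an object of class `ca_trace`.
#' @export
ca_trace <- function(cell_id, t_s, ratio, windows = empty_windows(),
                     temp_C = NULL) {
  t_s <- as.numeric(t_s); ratio <- as.numeric(ratio)
  if (length(t_s) != length(ratio)) stop("t_s and ratio lengths differ")
  if (any(diff(t_s) <= 0)) stop("t_s must be strictly increasing")
  if (any(!is.finite(ratio))) stop("ratio must be finite")
  windows <- validate_windows(windows, range(t_s))
  if (!is.null(temp_C) && length(temp_C) != length(t_s))
    stop("temp_C must match t_s")
  structure(list(cell_id = as.character(cell_id), t_s = t_s, ratio = ratio,
                 temp_C = temp_C, windows = windows),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("ca_trace %s: %d samples, dt=%.3g s, %d windows%s\n",
              x$cell_id, length(x$t_s),
              if (length(x$t_s) > 1) x$t_s[2] - x$t_s[1] else NA,
              nrow(x$windows),
              if (is.null(x$temp_C)) "" else ", temperature channel"))
  invisible(x)
}

#' An empty application-window table
#' @return zero-row windows data.frame with the canonical columns.
#' @export
empty_windows <- function() {
  data.frame(label = character(0), start_s = numeric(0), end_s = numeric(0),
             is_depolarising = logical(0), stringsAsFactors = FALSE)
}

validate_windows <- function(windows, span) {
  stopifnot(is.data.frame(windows))
  need <- c("label", "start_s", "end_s", "is_depolarising")
  if (!all(need %in% names(windows))) stop("windows needs columns ",
                                           paste(need, collapse = ", "))
  if (nrow(windows) == 0) return(windows)
  if (any(windows$start_s >= windows$end_s)) stop("window start must precede end")
  o <- order(windows$start_s)
  windows <- windows[o, , drop = FALSE]
  if (any(windows$end_s[-nrow(windows)] > windows$start_s[-1]))
    stop("windows must not overlap")
  if (!missing(span) &&
      (min(windows$start_s) < span[1] || max(windows$end_s) > span[2]))
    stop("windows must lie within the recording span")
  if (sum(windows$is_depolarising) > 1)
    stop("at most one depolarising window")
  if (any(windows$is_depolarising) &&
      which(windows$is_depolarising) != nrow(windows))
    stop("the depolarising window must be last")
  rownames(windows) <- NULL
  windows
}

#' Write a cohort of traces as CSV plus JSON sidecar
#'
#' The long CSV holds `cell_id, t_s, ratio, temp_C`; the sidecar JSON holds
#' the application windows and, when given, the generator ground truth, so a
#' cohort round-trips losslessly through text files.
#'
#' @param traces list of [ca_trace()] objects sharing one window layout.
#' @param csv,json output paths.
#' @param truth optional truth data.frame from a generator.
#' @return invisibly, the two paths.
#' @export
write_trace_bundle <- function(traces, csv, json, truth = NULL) {
  stopifnot(length(traces) > 0)
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, t_s = tr$t_s, ratio = tr$ratio,
               temp_C = if (is.null(tr$temp_C)) NA_real_ else tr$temp_C)
  }))
  utils::write.csv(long, csv, row.names = FALSE)
  side <- list(windows = traces[[1]]$windows)
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, json, digits = NA, na = "null")
  invisible(c(csv, json))
}

#' Read a trace cohort written by [write_trace_bundle()]
#'
#' @param csv,json paths written by [write_trace_bundle()].
#' @return list with `traces` (list of `ca_trace`) and `truth` (data.frame
#'   or NULL).
#' @export
read_trace_bundle <- function(csv, json) {
  long <- utils::read.csv(csv, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  win <- as.data.frame(side$windows, stringsAsFactors = FALSE)
  traces <- lapply(split(long, factor(long$cell_id, unique(long$cell_id))),
                   function(d) {
                     tc <- if (all(is.na(d$temp_C))) NULL else d$temp_C
                     ca_trace(d$cell_id[1], d$t_s, d$ratio, win, tc)
                   })
  names(traces) <- vapply(traces, function(tr) tr$cell_id, "")
  truth <- if (!is.null(side$truth))
    as.data.frame(side$truth, stringsAsFactors = FALSE) else NULL
  if (!is.null(truth)) {
    # all-null JSON columns come back logical; restore their numeric type
    for (col in c("true_amplitude", "onset_lag_s", "true_threshold_C"))
      if (col %in% names(truth)) truth[[col]] <- as.numeric(truth[[col]])
  }
  list(traces = traces, truth = truth)
}
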