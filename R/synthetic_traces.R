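#' Default application-window layout for a pharmacology run
#'
#' A compound pulse, a capsaicin pulse and the terminal depolarising KCl
#' pulse used for the viability gate.
#'
#' @param compound_label label of the first (test-compound) window.
#' @return windows data.frame.
#' @export
default_windows <- function(compound_label = "LPC 30uM") {
  data.frame(label = c(compound_label, "capsaicin 500nM", "KCl 60mM"),
             start_s = c(60, 150, 240), end_s = c(90, 180, 270),
             is_depolarising = c(FALSE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

default_response_map <- function(windows) {
  caps <- windows$label[grepl("caps", windows$label, ignore.case = TRUE)]
  dep <- windows$label[windows$is_depolarising]
  list(
    compound = windows$label,                 # responds to everything
    capsaicin_only = c(caps, dep),
    kcl_only = dep,
    dead = character(0)
  )
}

#' Synthetic Fura-2 pharmacology cohort
#'
#' Cells are drawn from discrete classes (by default: compound responder,
#' capsaicin-only, KCl-only, dead) that determine which application windows
#' evoke a transient. Transients rise instantaneously after a short onset lag
#' and decay mono-exponentially; baseline noise is additive Gaussian. Dead
#' cells stay flat through the terminal KCl pulse, so the downstream
#' viability gate removes exactly those.
#'
#' @param n_cells number of cells.
#' @param class_mix named probabilities per cell class; must sum to 1.
#' @param windows application windows (see [default_windows()]); the last
#'   must be the depolarising stimulus.
#' @param dt_s sampling interval in seconds (imaging default 2 s).
#' @param baseline_sd additive baseline noise SD in ratio units.
#' @param seed integer seed.
#' @param amp_mean mean transient amplitude (ratio units) for drug windows.
#' @param kcl_amp amplitude of the depolarising response.
#' @param onset_lag_s maximum onset lag after window start (perfusion dead
#'   time); actual lags are uniform on [0, onset_lag_s].
#' @param decay_tau_s mono-exponential decay constant.
#' @param response_map optional named list class -> window labels responded
#'   to; defaults cover the four standard classes.
#' @return list with `traces` (list of [ca_trace()]) and `truth` data.frame
#'   (`cell_id`, `cell_class`, `true_amplitude`, `onset_lag_s`,
#'   `true_threshold_C` = NA).
#' @export
gen_calcium_traces <- function(n_cells,
                               class_mix = c(compound = 0.25,
                                             capsaicin_only = 0.25,
                                             kcl_only = 0.4, dead = 0.1),
                               windows = default_windows(), dt_s = 2,
                               baseline_sd = 0.01, seed = 1,
                               amp_mean = 0.5, kcl_amp = 1,
                               onset_lag_s = 6, decay_tau_s = 20,
                               response_map = NULL) {
  if (n_cells < 1) stop("n_cells must be positive")
  if (dt_s <= 0) stop("dt must be > 0")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  windows <- validate_windows(windows)
  if (!any(windows$is_depolarising))
    stop("last window must be the depolarising stimulus")
  if (is.null(response_map)) response_map <- default_response_map(windows)
  if (!all(names(class_mix) %in% names(response_map)))
    stop("every class needs an entry in response_map")
  set.seed(seed)
  t_end <- max(windows$end_s) + 50
  t_s <- seq(0, t_end, by = dt_s)
  classes <- sample(names(class_mix), n_cells, replace = TRUE,
                    prob = class_mix)
  traces <- vector("list", n_cells)
  truth <- data.frame(cell_id = sprintf("C%04d", seq_len(n_cells)),
                      cell_class = classes,
                      true_amplitude = NA_real_, onset_lag_s = NA_real_,
                      true_threshold_C = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n_cells)) {
    r <- 1 + stats::rnorm(length(t_s), 0, baseline_sd)
    resp_to <- response_map[[classes[i]]]
    lag <- stats::runif(1, 0, onset_lag_s)
    amp_drawn <- NA_real_
    for (w in seq_len(nrow(windows))) {
      if (!windows$label[w] %in% resp_to) next
      amp <- if (windows$is_depolarising[w]) kcl_amp
             else amp_mean * exp(stats::rnorm(1, 0, 0.2))
      if (!windows$is_depolarising[w] && is.na(amp_drawn)) amp_drawn <- amp
      onset <- windows$start_s[w] + lag
      on <- t_s >= onset
      r[on] <- r[on] + amp * exp(-(t_s[on] - onset) / decay_tau_s)
    }
    truth$true_amplitude[i] <- amp_drawn
    truth$onset_lag_s[i] <- lag
    traces[[i]] <- ca_trace(truth$cell_id[i], t_s, r, windows)
  }
  names(traces) <- truth$cell_id
  list(traces = traces, truth = truth)
}

#' Synthetic heat-ramp cohort with planted threshold populations
#'
#' Each cell sees a 30-s baseline at 32 degrees C followed by a linear
#' 32-55 degrees C superfusate ramp. Heat-responsive cells follow a shallow
#' sub-threshold line and a steeper supra-threshold line in Arrhenius
#' coordinates (log10 baseline-subtracted ratio vs 1000/T_K), with the break
#' at a per-cell threshold drawn from a Gaussian mixture over the
#' populations.
#'
#' @param n_cells number of cells.
#' @param component_means_C mixture component means in degrees C; defaults to
#'   the four sensory-neuron threshold populations at 33.9, 39.8, 44.4 and
#'   52 degrees C.
#' @param component_sds_C per-component SDs (degrees C).
#' @param component_weights mixture weights, sum to 1.
#' @param ramp_C (start, end) ramp temperatures; rise is linear.
#' @param ramp_rate_C_s ramp speed in degrees C per second.
#' @param supra_gain ratio of supra- to sub-threshold Arrhenius slope
#'   magnitude; must exceed 1.
#' @param dt_s sampling interval (s).
#' @param baseline_sd additive noise SD (ratio units).
#' @param seed integer seed.
#' @param sub_slope sub-threshold slope dy/dx with x = 1000/T_K (negative:
#'   signal grows as temperature rises).
#' @param amp_at_threshold baseline-subtracted ratio amplitude at the
#'   threshold (ratio units).
#' @return list with `traces` (each carrying a temperature channel and one
#'   "heat ramp" window) and `truth` data.frame with `true_threshold_C` and
#'   the mixture component index.
#' @export
gen_heat_ramp_cohort <- function(n_cells,
                                 component_means_C = c(33.9, 39.8, 44.4, 52),
                                 component_sds_C = rep(1, length(component_means_C)),
                                 component_weights = rep(1 / length(component_means_C),
                                                         length(component_means_C)),
                                 ramp_C = c(32, 55), ramp_rate_C_s = 0.1,
                                 supra_gain = 5, dt_s = 2,
                                 baseline_sd = 0.005, seed = 1,
                                 sub_slope = -3, amp_at_threshold = 0.1) {
  if (n_cells < 1) stop("n_cells must be positive")
  if (abs(sum(component_weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(component_means_C < ramp_C[1] | component_means_C > ramp_C[2]))
    stop("component means must lie within the ramp range")
  if (supra_gain <= 1) stop("supra_gain must exceed 1 (no detectable acceleration)")
  if (dt_s <= 0) stop("dt must be > 0")
  set.seed(seed)
  base_dur <- 30
  ramp_dur <- diff(ramp_C) / ramp_rate_C_s
  t_s <- seq(0, base_dur + ramp_dur, by = dt_s)
  temp <- ifelse(t_s <= base_dur, ramp_C[1],
                 ramp_C[1] + (t_s - base_dur) * ramp_rate_C_s)
  windows <- data.frame(label = "heat ramp", start_s = base_dur,
                        end_s = base_dur + ramp_dur, is_depolarising = FALSE,
                        stringsAsFactors = FALSE)
  comp <- sample(length(component_means_C), n_cells, replace = TRUE,
                 prob = component_weights)
  thr <- stats::rnorm(n_cells, component_means_C[comp], component_sds_C[comp])
  thr <- pmin(pmax(thr, ramp_C[1] + 0.5), ramp_C[2] - 0.5)
  x <- 1000 / (temp + 273.15)
  traces <- vector("list", n_cells)
  truth <- data.frame(cell_id = sprintf("H%04d", seq_len(n_cells)),
                      cell_class = "heat", true_amplitude = NA_real_,
                      onset_lag_s = NA_real_, true_threshold_C = thr,
                      component = comp, stringsAsFactors = FALSE)
  ramp_on <- t_s > base_dur
  for (i in seq_len(n_cells)) {
    xs <- 1000 / (thr[i] + 273.15)
    ystar <- log10(amp_at_threshold)
    y <- ifelse(x >= xs, ystar + sub_slope * (x - xs),
                ystar + supra_gain * sub_slope * (x - xs))
    r <- 1 + ifelse(ramp_on, 10^y, 0) + stats::rnorm(length(t_s), 0, baseline_sd)
    traces[[i]] <- ca_trace(truth$cell_id[i], t_s, r, windows, temp)
  }
  names(traces) <- truth$cell_id
  list(traces = traces, truth = truth)
}
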