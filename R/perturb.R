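## In-silico perturbation experiments on the calibrated model.

standard_trace <- function(params, stimulus, sodium_free = FALSE,
                           frame_interval = 1.23, n_baseline_frames = 10,
                           n_post_frames = 121) {
  t_end <- stimulus$t_on + (n_post_frames + 1) * frame_interval
  traj <- simulate_model(params, stimulus, t_end = t_end,
                         dt_out = frame_interval, sodium_free = sodium_free,
                         keep_fluxes = FALSE)
  trajectory_to_trace(traj, frame_interval = frame_interval,
                      n_baseline_frames = n_baseline_frames,
                      n_post_frames = n_post_frames)
}

simulated_features <- function(params, stimulus, sodium_free = FALSE, ...) {
  tr <- standard_trace(params, stimulus, sodium_free = sodium_free, ...)
  trace_features(normalize_trace(tr), ...)
}

#' Mechanosensitive-influx sweep
#'
#' Scales the stimulus influx intensity by each fraction in `fractions`
#' (emulating a graded loss of mechanosensitive channels), simulates the
#' model with everything else — including the CICR amplification — held
#' fixed, and records the amplitude increase over baseline of each trace.
#'
#' @param params a [model_parameters()] object.
#' @param stimulus the full-influx [stimulus_influx()].
#' @param fractions sorted vector of influx fractions in `[0, 1]`.
#' @param ... frame-grid arguments passed to the trace pipeline.
#' @return data.frame of class `ca_sweep` with columns `influx_fraction`
#'   and `amplitude_increase` (peak normalized intensity minus 1).
#' @export
influx_sweep <- function(params, stimulus, fractions = seq(0, 1, by = 0.05),
                         ...) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  if (is.unsorted(fractions)) stop("fractions must be sorted increasing")
  inc <- vapply(fractions, function(f) {
    st <- stimulus
    st$intensity <- f * stimulus$intensity
    ft <- tryCatch(simulated_features(params, st, ...),
                   error = function(e) stop("sweep failed at fraction ", f,
                                            ": ", conditionMessage(e)))
    ft$amplitude - 1
  }, numeric(1))
  structure(data.frame(influx_fraction = fractions,
                       amplitude_increase = inc),
            class = c("ca_sweep", "data.frame"))
}

#' Invert the influx sweep at observed amplitude increases
#'
#' Estimates the percentage decrease in mechanosensitive influx that
#' reproduces an observed knock-out amplitude. The sweep curve is first
#' scaled so that fraction 1 maps onto the wild-type baseline increase, then
#' inverted by monotone interpolation at the knock-out increase.
#'
#' @param curve a `ca_sweep` from [influx_sweep()] (must be monotone
#'   non-decreasing).
#' @param wt_increase wild-type amplitude increase over baseline
#'   (amplitude - 1).
#' @param ko_increase knock-out amplitude increase (<= `wt_increase`).
#' @return percentage decrease in influx, `100 * (1 - fraction)`.
#' @examples
#' curve <- structure(data.frame(influx_fraction = seq(0, 1, 0.1),
#'                               amplitude_increase = seq(0, 1, 0.1)),
#'                    class = c("ca_sweep", "data.frame"))
#' ms_fraction_estimate(curve, wt_increase = 1, ko_increase = 0.4)  # 60
#' @export
ms_fraction_estimate <- function(curve, wt_increase, ko_increase) {
  stopifnot(inherits(curve, "ca_sweep"))
  if (any(diff(curve$amplitude_increase) < -1e-9)) {
    stop("sweep curve is not monotone; cannot invert")
  }
  if (ko_increase > wt_increase) stop("ko_increase must be <= wt_increase")
  full <- curve$amplitude_increase[which.max(curve$influx_fraction)]
  if (full <= 0) stop("sweep curve has no response at full influx")
  rel <- curve$amplitude_increase / full * wt_increase
  if (ko_increase < min(rel) - 1e-12 || ko_increase > max(rel) + 1e-12) {
    stop("ko_increase lies outside the sweep range; cannot interpolate")
  }
  f <- stats::approx(rel, curve$influx_fraction, xout = ko_increase,
                     ties = "ordered")$y
  100 * (1 - f)
}

#' Store-depletion experiment
#'
#' Pairs the full model against the same model with the CICR release shut
#' off (`V_cru = 0`, emulating thapsigargin-emptied ER stores) and reports
#' the percentage loss of the amplitude increase.
#'
#' @inheritParams influx_sweep
#' @return list with `reduction_pct`
#'   (`100 * (1 - increase_depleted / increase_full)`), plus the two
#'   feature sets `full` and `depleted`.
#' @export
store_depletion <- function(params, stimulus, ...) {
  ft_full <- simulated_features(params, stimulus, ...)
  depleted <- model_parameters(V_pump = params$V_pump, K_pump = params$K_pump,
                               V_cru = 0, K_cru = params$K_cru,
                               m_cru = params$m_cru, K_h = params$K_h,
                               tau_h = params$tau_h, V_ncx = params$V_ncx,
                               K_ncx = params$K_ncx, q_ncx = params$q_ncx,
                               k_na = params$k_na)
  ft_dep <- simulated_features(depleted, stimulus, ...)
  inc_full <- ft_full$amplitude - 1
  inc_dep <- ft_dep$amplitude - 1
  red <- if (inc_full <= 0) 0 else 100 * (1 - inc_dep / inc_full)
  list(reduction_pct = red, full = ft_full, depleted = ft_dep)
}

#' Sodium-free medium experiment
#'
#' Simulates the calibrated model with the whole Na+ pathway disabled:
#' the stimulus carries no Na+ (J_theta* = 0) and the cytosolic Na+ level is
#' clamped at its resting value, so the NCX never loses driving force. This
#' emulates replacing extracellular Na+ with a cation the exchanger cannot
#' use.
#'
#' @inheritParams influx_sweep
#' @return list with `amplitude` and `decay50` of the sodium-free trace and
#'   the full `ca_features` object under `features`.
#' @export
sodium_free <- function(params, stimulus, ...) {
  ft <- simulated_features(params, stimulus, sodium_free = TRUE, ...)
  list(amplitude = ft$amplitude, decay50 = ft$decay50, features = ft)
}
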