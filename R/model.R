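#' Single-cell Ca2+/Na+ flux model parameters
#'
#' Constructs the parameter set of the deterministic single-cell model of
#' relative cytosolic Ca2+ concentration `c` and relative Na+ concentration
#' `n` (both dimensionless, resting value 1), with a slow inactivation gate
#' `h` on the CICR release unit. The calcium balance is
#' \deqn{dc/dt = J_\theta(t) + J_{CRU} + J_{pump} + J_{leak} + J_{NCX}}
#' and the sodium balance
#' \deqn{dn/dt = J_\theta^*(t) + J_{pump}^* + J_{leak}^*.}
#' The flux forms are
#' * leak: \eqn{J_{leak} = k_{leak}} (constant influx),
#' * pump (SERCA/PMCA lumped): \eqn{J_{pump} = -V_{pump} c^2/(K_{pump}^2+c^2)},
#' * CICR release unit: \eqn{J_{CRU} = V_{cru}\, h\, c^{m}/(K_{cru}^m+c^m)}
#'   with gate \eqn{dh/dt = (h_\infty(c)-h)/\tau_h},
#'   \eqn{h_\infty(c)=K_h^2/(K_h^2+c^2)},
#' * NCX: \eqn{J_{NCX} = -V_{ncx}\, c/(K_{ncx}+c)\, n^{-q_{ncx}}}; the
#'   \eqn{n^{-q}} factor makes extrusion slower when cytosolic Na+ is
#'   elevated, which is the mechanism separating directly stimulated cells
#'   from their neighbors,
#' * sodium: \eqn{J_{pump}^* = -k_{na} n}, \eqn{J_{leak}^* = k_{leak,na}}.
#'
#' Sodium dynamics are deliberately not coupled back to NCX turnover: the
#' absolute cytosolic Na+ pool is large compared to the Ca2+ moved by the
#' exchanger.
#'
#' The two leak constants are never supplied by the user: they are solved at
#' construction so that the resting state `c = n = 1`, `h = h_inf(1)` is an
#' exact equilibrium (resting balance). Supplying parameters for which the
#' solved `k_leak` would be negative is rejected.
#'
#' Defaults are the shipped calibrated set (see [default_parameters()]),
#' obtained by fitting the model's perturbation summaries (amplitude and 50%
#' decay time with and without the Na+ pathway, store-depletion amplitude
#' loss, and the influx-sweep anchor) — see the package vignette.
#'
#' @param V_pump,K_pump pump maximum rate (1/s) and half-saturation
#'   (relative concentration).
#' @param V_cru,K_cru,m_cru CRU maximum release rate (1/s), half-activation
#'   and Hill coefficient (`m_cru >= 1`).
#' @param K_h,tau_h gate half-inactivation (relative concentration) and gate
#'   time constant (s).
#' @param V_ncx,K_ncx,q_ncx NCX maximum rate (1/s), half-saturation and
#'   Na+-inhibition exponent (`q_ncx >= 0`; 0 switches the Na+ coupling off).
#' @param k_na Na+ relaxation rate (1/s).
#' @return An object of class `ca_params`: a named list of the parameters
#'   above plus the solved `k_leak` and `k_leak_na`.
#' @seealso [resting_state()], [simulate_model()], [default_parameters()]
#' @examples
#' p <- model_parameters()
#' p$k_leak                     # solved from the resting balance
#' resting_state(p)
#' @export
model_parameters <- function(V_pump = 0.344468, K_pump = 2.045537,
                             V_cru = 0.554398, K_cru = 1.961317, m_cru = 4,
                             K_h = 1.590098, tau_h = 14.21162,
                             V_ncx = 0.0269488, K_ncx = 0.549508,
                             q_ncx = 2.415711, k_na = 0.000632395) {
  vals <- c(V_pump = V_pump, K_pump = K_pump, V_cru = V_cru, K_cru = K_cru,
            m_cru = m_cru, K_h = K_h, tau_h = tau_h, V_ncx = V_ncx,
            K_ncx = K_ncx, q_ncx = q_ncx, k_na = k_na)
  if (any(!is.finite(vals))) {
    stop("model parameters must be finite numbers")
  }
  strict_pos <- c("V_pump", "K_pump", "K_cru", "K_h", "tau_h", "V_ncx",
                  "K_ncx", "k_na")
  bad <- strict_pos[vals[strict_pos] <= 0]
  if (length(bad) > 0) {
    stop("model parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  }
  if (V_cru < 0) stop("V_cru must be non-negative")
  if (m_cru < 1) stop("m_cru must be >= 1")
  if (q_ncx < 0) stop("q_ncx must be >= 0")
  p <- as.list(vals)
  # resting balance: with c = n = 1 and h = h_inf(1) all fluxes cancel
  h0 <- gate_steady(1, K_h)
  p$k_leak <- V_pump / (K_pump^2 + 1) + V_ncx / (K_ncx + 1) -
    V_cru * h0 / (K_cru^m_cru + 1)
  p$k_leak_na <- k_na
  if (p$k_leak < 0) {
    stop("resting balance requires a negative Ca2+ leak: ",
         "CRU release at rest exceeds pump + NCX extrusion; ",
         "decrease V_cru or increase V_pump/V_ncx")
  }
  class(p) <- "ca_params"
  p
}

#' @export
print.ca_params <- function(x, ...) {
  cat("Single-cell Ca2+/Na+ model parameters (1/s unless noted):\n")
  print(unclass(unlist(x)))
  invisible(x)
}

gate_steady <- function(c, K_h) K_h^2 / (K_h^2 + c^2)

#' Mechanically triggered stimulus influx
#'
#' Describes the transient cation influx J_theta(t): a rectangular pulse of
#' the given intensity over the half-open interval
#' `[t_on, t_on + duration)`. For directly stimulated (target) cells the
#' mechanosensitive channels pass Na+ alongside Ca2+, so the sodium influx
#' J_theta*(t) equals J_theta(t) (`na_coupled = TRUE`). For neighbor cells
#' the Ca2+ arrives through gap junctions and carries no Na+ load
#' (`na_coupled = FALSE`, J_theta* = 0).
#'
#' @param t_on onset time (s).
#' @param duration pulse duration (s), strictly positive.
#' @param intensity influx magnitude (1/s), non-negative.
#' @param na_coupled logical; `TRUE` for target cells (J_theta* = J_theta),
#'   `FALSE` for neighbor cells (J_theta* = 0).
#' @return An object of class `ca_stimulus`.
#' @examples
#' stimulus_influx(12.3, 2.7, 0.2, na_coupled = TRUE)
#' @export
stimulus_influx <- function(t_on, duration, intensity, na_coupled = TRUE) {
  if (!is.finite(t_on) || t_on < 0) stop("t_on must be a non-negative time")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(intensity) || intensity < 0) stop("intensity must be >= 0")
  structure(list(t_on = t_on, duration = duration, intensity = intensity,
                 na_coupled = isTRUE(na_coupled)),
            class = "ca_stimulus")
}

#' A model state
#'
#' @param c relative cytosolic Ca2+ concentration (> 0, resting value 1).
#' @param n relative cytosolic Na+ concentration (> 0, resting value 1).
#' @param h CRU inactivation gate, in `[0, 1]`.
#' @return Named numeric vector of class `ca_state`.
#' @export
model_state <- function(c, n, h) {
  if (!is.finite(c) || c <= 0) stop("state variable c must be > 0, got ", c)
  if (!is.finite(n) || n <= 0) stop("state variable n must be > 0, got ", n)
  if (!is.finite(h) || h < 0 || h > 1) stop("gate h must lie in [0, 1]")
  structure(c(c = c, n = n, h = h), class = "ca_state")
}

#' Instantaneous flux terms
#'
#' Evaluates every flux term of the calcium and sodium balances at a given
#' state and time. The stimulus term is `intensity` inside the half-open
#' pulse window `[t_on, t_on + duration)` and 0 outside; its sodium twin
#' follows the coupling rule of the stimulus (see [stimulus_influx()]).
#'
#' @param state a [model_state()] (or named vector with `c`, `n`, `h`).
#' @param params a [model_parameters()] object.
#' @param stimulus a [stimulus_influx()] object, or `NULL` for no stimulus.
#' @param t time (s) at which to evaluate the stimulus window.
#' @return Named numeric vector with components `J_theta`, `J_cru`,
#'   `J_pump`, `J_leak`, `J_ncx` (Ca2+ terms, 1/s) and `J_theta_star`,
#'   `J_pump_star`, `J_leak_star` (Na+ terms, 1/s). `sum` of the first five
#'   is `dc/dt`; of the last three, `dn/dt`.
#' @examples
#' p <- model_parameters()
#' f <- model_fluxes(resting_state(p), p, NULL, 0)
#' sum(f[c("J_theta", "J_cru", "J_pump", "J_leak", "J_ncx")])  # ~ 0
#' @export
model_fluxes <- function(state, params, stimulus = NULL, t = 0) {
  stopifnot(inherits(params, "ca_params"))
  c <- unname(state[["c"]]); n <- unname(state[["n"]]); h <- unname(state[["h"]])
  if (!is.finite(c) || c <= 0) stop("state variable c must be > 0, got ", c)
  if (!is.finite(n) || n <= 0) stop("state variable n must be > 0, got ", n)
  J_theta <- 0
  J_theta_star <- 0
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "ca_stimulus"))
    if (t >= stimulus$t_on && t < stimulus$t_on + stimulus$duration) {
      J_theta <- stimulus$intensity
      if (stimulus$na_coupled) J_theta_star <- J_theta
    }
  }
  p <- params
  c(J_theta = J_theta,
    J_cru = p$V_cru * h * c^p$m_cru / (p$K_cru^p$m_cru + c^p$m_cru),
    J_pump = -p$V_pump * c^2 / (p$K_pump^2 + c^2),
    J_leak = p$k_leak,
    J_ncx = -p$V_ncx * (c / (p$K_ncx + c)) * n^(-p$q_ncx),
    J_theta_star = J_theta_star,
    J_pump_star = -p$k_na * n,
    J_leak_star = p$k_leak_na)
}

#' Resting steady state
#'
#' Returns the normalisation anchor of the model: `c = 1`, `n = 1`,
#' `h = h_inf(1)`. By construction of [model_parameters()] the total Ca2+
#' and Na+ fluxes vanish there; this is re-verified by evaluation and a
#' violation (e.g. a hand-edited `k_leak`) raises a configuration error.
#'
#' @param params a [model_parameters()] object.
#' @param tol tolerance (1/s) on the residual flux balance.
#' @return A [model_state()] with `c = 1`, `n = 1`.
#' @export
resting_state <- function(params, tol = 1e-10) {
  st <- model_state(1, 1, gate_steady(1, params$K_h))
  f <- model_fluxes(st, params, NULL, 0)
  dc <- sum(f[c("J_theta", "J_cru", "J_pump", "J_leak", "J_ncx")])
  dn <- sum(f[c("J_theta_star", "J_pump_star", "J_leak_star")])
  if (abs(dc) > tol || abs(dn) > tol) {
    stop("resting balance violated: total Ca2+ flux = ", signif(dc, 3),
         ", total Na+ flux = ", signif(dn, 3),
         " (parameters were not constructed with model_parameters())")
  }
  st
}

model_derivatives <- function(params, J_theta, J_theta_star,
                              sodium_free = FALSE) {
  p <- params
  function(t, y, ...) {
    cc <- y[[1]]; nn <- y[[2]]; hh <- y[[3]]
    if (!is.finite(cc) || cc <= 0) {
      stop("state variable c became non-positive at t = ", signif(t, 6))
    }
    n_eff <- if (sodium_free) 1 else nn
    dc <- J_theta +
      p$V_cru * hh * cc^p$m_cru / (p$K_cru^p$m_cru + cc^p$m_cru) -
      p$V_pump * cc^2 / (p$K_pump^2 + cc^2) +
      p$k_leak -
      p$V_ncx * (cc / (p$K_ncx + cc)) * n_eff^(-p$q_ncx)
    dn <- if (sodium_free) 0 else J_theta_star - p$k_na * nn + p$k_leak_na
    dh <- (gate_steady(cc, p$K_h) - hh) / p$tau_h
    list(c(dc, dn, dh))
  }
}

#' Simulate the model on a fixed output grid
#'
#' Integrates the model from the resting state with an adaptive
#' stiff-capable solver ([deSolve::ode()], `lsoda`, rtol 1e-8, atol 1e-10).
#' The rectangular pulse edges are handled by integrating the three smooth
#' segments (pre-pulse, pulse, post-pulse) separately, so the solver never
#' steps across a discontinuity. Output is sampled at every multiple of
#' `dt_out` in `[0, t_end]`.
#'
#' @param params a [model_parameters()] object.
#' @param stimulus a [stimulus_influx()] object.
#' @param t_end simulation horizon (s); must exceed `t_on + duration`.
#' @param dt_out output sampling interval (s).
#' @param sodium_free if `TRUE`, simulate the sodium-free condition: the
#'   stimulus carries no Na+ (J_theta* = 0) and `n` is clamped at 1 so the
#'   NCX runs at full rate throughout (see [sodium_free()]).
#' @param keep_fluxes if `TRUE` (default), evaluate and store every flux
#'   term along the trajectory.
#' @return An object of class `ca_trajectory`: list with `times`, `states`
#'   (data.frame `c`, `n`, `h`), `fluxes` (data.frame or `NULL`),
#'   `stimulus`, `params`, `sodium_free`.
#' @examples
#' p <- model_parameters()
#' s <- standard_stimulus()
#' traj <- simulate_model(p, s, t_end = 160, dt_out = 1.23)
#' max(traj$states$c)    # peak relative Ca2+
#' @export
simulate_model <- function(params, stimulus, t_end, dt_out,
                           sodium_free = FALSE, keep_fluxes = TRUE) {
  stopifnot(inherits(params, "ca_params"), inherits(stimulus, "ca_stimulus"))
  if (!is.finite(t_end) || t_end <= stimulus$t_on + stimulus$duration) {
    stop("t_end must exceed t_on + duration")
  }
  if (!is.finite(dt_out) || dt_out <= 0) stop("dt_out must be > 0")
  grid <- seq(0, t_end, by = dt_out)
  brk <- sort(unique(pmin(pmax(c(stimulus$t_on,
                                 stimulus$t_on + stimulus$duration), 0),
                          t_end)))
  seg_edges <- sort(unique(c(0, brk, t_end)))
  y <- as.numeric(resting_state(params))
  times <- numeric(0)
  ys <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(length(seg_edges) - 1)) {
    a <- seg_edges[i]; b <- seg_edges[i + 1]
    if (b - a < 1e-12) next
    tt <- sort(unique(c(a, grid[grid > a & grid < b], b)))
    # the stimulus is constant within a segment: evaluate the half-open
    # pulse window at the segment midpoint so edges are honored exactly
    mid <- (a + b) / 2
    in_pulse <- mid >= stimulus$t_on && mid < stimulus$t_on + stimulus$duration
    J <- if (in_pulse) stimulus$intensity else 0
    Jstar <- if (in_pulse && stimulus$na_coupled && !sodium_free) J else 0
    seg_deriv <- model_derivatives(params, J, Jstar, sodium_free)
    out <- tryCatch(
      deSolve::ode(y = y, times = tt, func = seg_deriv, parms = NULL,
                   method = "lsoda", rtol = 1e-8, atol = 1e-10),
      error = function(e) stop("integrator failure in segment starting at t = ",
                               signif(a, 6), ": ", conditionMessage(e))
    )
    if (any(!is.finite(out[, 2:4]))) {
      bad_t <- out[which(!is.finite(rowSums(out[, 2:4])))[1], 1]
      stop("integrator failure at t = ", signif(bad_t, 6))
    }
    y <- unname(out[nrow(out), 2:4])
    keep <- if (i < length(seg_edges) - 1) -nrow(out) else TRUE
    times <- c(times, out[keep, 1])
    ys <- rbind(ys, unname(out[keep, 2:4, drop = FALSE]))
  }
  on_grid <- vapply(times, function(t) {
    any(abs(t - grid) < 1e-9)
  }, logical(1))
  times <- times[on_grid]
  ys <- ys[on_grid, , drop = FALSE]
  states <- data.frame(c = ys[, 1], n = ys[, 2], h = ys[, 3])
  fl <- NULL
  if (keep_fluxes) {
    fl <- t(vapply(seq_along(times), function(i) {
      model_fluxes(c(c = states$c[i], n = states$n[i], h = states$h[i]),
                   params,
                   stimulus,
                   times[i])
    }, numeric(8)))
    if (sodium_free) {
      # the clamp holds n at 1 and removes the Na+ influx
      fl[, "J_theta_star"] <- 0
    }
    fl <- as.data.frame(fl)
  }
  structure(list(times = times, states = states, fluxes = fl,
                 stimulus = stimulus, params = params,
                 sodium_free = sodium_free),
            class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat("ca_trajectory:", length(x$times), "samples over [0, ",
      max(x$times), "] s; peak c = ", signif(max(x$states$c), 4),
      if (x$sodium_free) " (sodium-free)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ca_trajectory <- function(x, ...) {
  d <- data.frame(time_s = x$times, x$states)
  if (!is.null(x$fluxes)) d <- cbind(d, x$fluxes)
  d
}

#' Sample a trajectory onto an imaging frame grid
#'
#' Maps a model trajectory to a fluorescence intensity trace, taking the
#' normalized fluorescence to be the relative calcium concentration `c`
#' (linear indicator). The frame grid is aligned so that exactly
#' `n_baseline_frames` frames precede the stimulus onset: frame `k` sits at
#' time `t_on + (k - n_baseline_frames) * frame_interval`.
#'
#' @param traj a `ca_trajectory` from [simulate_model()].
#' @param frame_interval imaging frame interval (s); the imaging protocol default is
#'   1.23 s.
#' @param n_baseline_frames number of pre-stimulus frames (default 10).
#' @param n_post_frames number of frames from stimulus onset onwards
#'   (default 121); the trajectory must cover the whole grid.
#' @param cell_id identifier stored on the returned trace.
#' @return An [intensity_trace()] whose `stim_frame` equals
#'   `n_baseline_frames`.
#' @export
trajectory_to_trace <- function(traj, frame_interval = 1.23,
                                n_baseline_frames = 10, n_post_frames = 121,
                                cell_id = "model") {
  stopifnot(inherits(traj, "ca_trajectory"))
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  t_on <- traj$stimulus$t_on
  k <- seq_len(n_baseline_frames + n_post_frames) - 1
  tk <- t_on + (k - n_baseline_frames) * frame_interval
  if (tk[1] < min(traj$times) - 1e-9) {
    stop("trajectory does not span ", n_baseline_frames,
         " pre-stimulus frames (needs t = ", signif(tk[1], 6), ")")
  }
  if (tk[length(tk)] > max(traj$times) + 1e-9) {
    stop("trajectory too short for ", n_post_frames, " post-stimulus frames")
  }
  # exact grid hits are taken verbatim; otherwise linear interpolation
  vals <- stats::approx(traj$times, traj$states$c, xout = tk, rule = 2)$y
  exact <- outer(tk, traj$times, function(a, b) abs(a - b) < 1e-9)
  hit <- which(rowSums(exact) > 0)
  if (length(hit) > 0) {
    vals[hit] <- traj$states$c[apply(exact[hit, , drop = FALSE], 1,
                                     which.max)]
  }
  intensity_trace(cell_id = cell_id, frame_index = k, time = tk,
                  intensity = vals, stim_frame = n_baseline_frames,
                  group = if (traj$stimulus$na_coupled) "target" else "neighbor")
}
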