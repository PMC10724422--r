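## Independent oracles used by the tests. These deliberately re-derive the
## quantities through a different route than the package implementation.

# Fixed-step classical Runge-Kutta integration of the model equations,
# with the right-hand side written out from scratch.
rk4_reference <- function(params, stimulus, t_end, dt = 1e-3) {
  p <- unclass(params)
  hinf <- function(cc) p$K_h^2 / (p$K_h^2 + cc^2)
  rhs <- function(t, y) {
    cc <- y[1]; nn <- y[2]; hh <- y[3]
    J <- if (t >= stimulus$t_on && t < stimulus$t_on + stimulus$duration)
      stimulus$intensity else 0
    Js <- if (stimulus$na_coupled) J else 0
    dc <- J +
      p$V_cru * hh * cc^p$m_cru / (p$K_cru^p$m_cru + cc^p$m_cru) -
      p$V_pump * cc^2 / (p$K_pump^2 + cc^2) +
      p$k_leak -
      p$V_ncx * (cc / (p$K_ncx + cc)) * nn^(-p$q_ncx)
    dn <- Js - p$k_na * nn + p$k_leak_na
    dh <- (hinf(cc) - hh) / p$tau_h
    c(dc, dn, dh)
  }
  n_steps <- round(t_end / dt)
  y <- c(1, 1, hinf(1))
  times <- numeric(n_steps + 1)
  cs <- numeric(n_steps + 1)
  cs[1] <- y[1]
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    k1 <- rhs(t, y)
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, y + dt / 2 * k2)
    k4 <- rhs(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    times[i + 1] <- i * dt
    cs[i + 1] <- y[1]
  }
  data.frame(t = times, c = cs)
}

# Brute-force classification of axis-aligned rectangles by interval
# arithmetic: rect = c(x0, y0, x1, y1).
oracle_classify_rects <- function(rects, stim, eps = 0.5) {
  overlap_area <- function(a, b) {
    max(0, min(a[3], b[3]) - max(a[1], b[1])) *
      max(0, min(a[4], b[4]) - max(a[2], b[2]))
  }
  rect_dist <- function(a, b) {
    dx <- max(0, max(a[1], b[1]) - min(a[3], b[3]))
    dy <- max(0, max(a[2], b[2]) - min(a[4], b[4]))
    sqrt(dx^2 + dy^2)
  }
  is_target <- vapply(rects, function(r) overlap_area(r, stim) > 0, logical(1))
  labels <- ifelse(is_target, "target", "other")
  tgt <- which(is_target)
  for (i in which(!is_target)) {
    if (length(tgt) > 0 &&
        any(vapply(tgt, function(j) rect_dist(rects[[i]], rects[[j]]) <= eps,
                   logical(1)))) {
      labels[i] <- "neighbor"
    }
  }
  names(labels) <- names(rects)
  labels
}

rect_to_poly <- function(r) {
  rect_polygon(r[1], r[2], r[3] - r[1], r[4] - r[2])
}

# Dense-grid crossing finder for a continuous decay curve y(t): time from
# the maximum to the first crossing of the mid-level between max and basal.
oracle_decay50_dense <- function(fun, t_max = 200, basal = 1, dt = 1e-4) {
  tt <- seq(0, t_max, by = dt)
  y <- fun(tt)
  ipk <- which.max(y)
  level <- (y[ipk] + basal) / 2
  after <- y[seq(ipk, length(y))]
  cross <- which(after < level)[1]
  if (is.na(cross)) return(NA_real_)
  (cross - 1) * dt
}

# A simple flat-baseline trace on the default imaging frame grid.
make_trace <- function(values, cell_id = "c1", stim_frame = 10,
                       frame_interval = 1.23, group = "unlabeled") {
  k <- seq_along(values) - 1
  intensity_trace(cell_id = cell_id, frame_index = k,
                  time = k * frame_interval, intensity = values,
                  stim_frame = stim_frame, group = group)
}
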