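## Least-squares fitting of the kinetic model to quantile-averaged traces.
## Shared kinetics are fitted once across all bins (pooled residuals);
## each bin has its own stimulus influx (timing, duration, intensity), with
## the Na+ coupling fixed by cell group (target: coupled; neighbor: not).

#' Frame-wise residuals of the model against an observed trace
#'
#' Simulates the model under the given stimulus, samples it on the observed
#' frame grid and returns model minus observed at every frame. A simulation
#' failure yields a constant large-penalty residual (1e3) with a warning, so
#' optimizers survive pathological parameter proposals.
#'
#' @param params a [model_parameters()] object.
#' @param stimulus a [stimulus_influx()] object.
#' @param observed data.frame with columns `time_s` and `intensity`
#'   (normalized, baseline 1) on a regular frame grid.
#' @param stim_frame index of the first post-stimulus frame in `observed`.
#' @return numeric residual vector, one entry per frame.
#' @export
model_residuals <- function(params, stimulus, observed, stim_frame = 10) {
  stopifnot(is.data.frame(observed),
            all(c("time_s", "intensity") %in% names(observed)))
  tt <- observed$time_s
  dt <- stats::median(diff(tt))
  tryCatch({
    t_end <- max(tt) + dt
    if (t_end <= stimulus$t_on + stimulus$duration) {
      t_end <- stimulus$t_on + stimulus$duration + dt
    }
    traj <- simulate_model(params, stimulus, t_end = t_end, dt_out = dt,
                           keep_fluxes = FALSE)
    pred <- stats::approx(traj$times, traj$states$c, xout = tt, rule = 2)$y
    pred - observed$intensity
  }, error = function(e) {
    warning("simulation failed (", conditionMessage(e),
            "); returning penalty residuals")
    rep(1e3, length(tt))
  })
}

split_bins <- function(averaged) {
  stopifnot(is.data.frame(averaged),
            all(c("group", "bin", "time_s", "intensity") %in% names(averaged)))
  key <- interaction(averaged$group, averaged$bin, drop = TRUE)
  lapply(split(averaged, key), function(d) d[order(d$time_s), ])
}

#' Fit the model to quantile-averaged traces
#'
#' Bounded least-squares minimisation (Levenberg-Marquardt,
#' [minpack.lm::nls.lm()]) of the pooled sum of squared frame-wise
#' residuals over all (group, bin) averaged traces. The kinetic parameters
#' named in `shared_bounds` are fitted once across all bins (on a log
#' scale); every bin gets its own stimulus timing, duration and intensity.
#' The Na+ coupling is fixed by group — target bins are coupled, neighbor
#' bins are not — and never fitted. Multi-start: the first start is the
#' supplied initial guess, the remaining starts draw the free parameters
#' uniformly within their bounds from a seeded RNG; the best converged
#' start wins.
#'
#' @param averaged output of [group_average()] (or a data.frame with
#'   columns `group`, `bin`, `time_s`, `intensity`).
#' @param init initial [model_parameters()]; parameters not listed in
#'   `shared_bounds` stay fixed at these values.
#' @param shared_bounds named list of `c(lower, upper)` bounds for the
#'   kinetic parameters to fit (e.g. `list(q_ncx = c(0.01, 8))`); empty list
#'   fits only the per-bin stimuli.
#' @param t_stim known stimulation time (s); per-bin onsets are bounded to
#'   `t_stim` +/- `timing_frames` frames.
#' @param timing_frames half-width of the onset bound, in frames.
#' @param duration_bounds,intensity_bounds bounds for the per-bin pulse
#'   duration (s) and intensity (1/s).
#' @param frame_interval imaging frame interval (s).
#' @param n_starts number of optimizer starts (default 8).
#' @param seed RNG seed for the multi-start draws.
#' @param maxiter per-start Levenberg-Marquardt iteration cap.
#' @return object of class `ca_fit`: `shared` (fitted [model_parameters()]),
#'   `per_group` (data.frame of fitted per-bin stimuli), `sse` (per-bin),
#'   `sse_total`, `n_eval`, `seed`, `starts` (per-start diagnostics),
#'   `converged`.
#' @export
fit_model <- function(averaged, init = default_parameters(),
                      shared_bounds = list(),
                      t_stim = 12.3, timing_frames = 3,
                      duration_bounds = c(0.03, 10),
                      intensity_bounds = c(1e-4, 2),
                      frame_interval = 1.23,
                      n_starts = 8, seed = 1, maxiter = 60) {
  bins <- split_bins(averaged)
  if (length(bins) < 1) stop("no bins to fit")
  groups <- vapply(bins, function(d) as.character(d$group[1]), character(1))
  if (!all(groups %in% c("target", "neighbor"))) {
    stop("fit expects target and/or neighbor bins only")
  }
  shared_names <- names(shared_bounds)
  stopifnot(all(shared_names %in% names(unclass(init))))
  nb <- length(bins)
  ns <- length(shared_names)

  # parameter vector: log(shared) ++ per bin (t_on, log dur, log intensity)
  lower <- c(if (ns) log(vapply(shared_bounds, `[`, numeric(1), 1)),
             rep(c(t_stim - timing_frames * frame_interval,
                   log(duration_bounds[1]), log(intensity_bounds[1])), nb))
  upper <- c(if (ns) log(vapply(shared_bounds, `[`, numeric(1), 2)),
             rep(c(t_stim + timing_frames * frame_interval,
                   log(duration_bounds[2]), log(intensity_bounds[2])), nb))

  build <- function(x) {
    kin <- unclass(init)[c("V_pump", "K_pump", "V_cru", "K_cru", "m_cru",
                           "K_h", "tau_h", "V_ncx", "K_ncx", "q_ncx", "k_na")]
    if (ns) kin[shared_names] <- as.list(exp(x[seq_len(ns)]))
    params <- do.call(model_parameters, kin)
    stims <- lapply(seq_len(nb), function(i) {
      off <- ns + 3 * (i - 1)
      stimulus_influx(t_on = x[off + 1], duration = exp(x[off + 2]),
                      intensity = exp(x[off + 3]),
                      na_coupled = groups[i] == "target")
    })
    list(params = params, stims = stims)
  }

  n_eval <- 0L
  resid_fn <- function(x) {
    n_eval <<- n_eval + 1L
    b <- tryCatch(build(x), error = function(e) NULL)
    if (is.null(b)) {
      return(rep(1e3, sum(vapply(bins, nrow, 0L))))
    }
    unlist(lapply(seq_len(nb), function(i) {
      suppressWarnings(model_residuals(b$params, b$stims[[i]], bins[[i]]))
    }), use.names = FALSE)
  }

  # initial guess: onset at the known stimulation time, 3 s pulse, intensity
  # sized so that the raw influx roughly matches the observed increase
  x0 <- c(if (ns) log(vapply(shared_names, function(nm) {
    v <- unclass(init)[[nm]]
    min(max(v, shared_bounds[[nm]][1]), shared_bounds[[nm]][2])
  }, numeric(1))),
  unlist(lapply(seq_len(nb), function(i) {
    amp <- max(bins[[i]]$intensity)
    c(t_stim, log(3), log(min(max((amp - 1) / 3, intensity_bounds[1] * 2),
                              intensity_bounds[2] / 2)))
  })))

  set.seed(seed)
  starts <- list(x0)
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- stats::runif(length(lower), lower, upper)
    }
  }
  diag <- list()
  best <- NULL
  for (s in seq_along(starts)) {
    r <- tryCatch(
      minpack.lm::nls.lm(par = starts[[s]], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-10, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(r)) {
      diag[[s]] <- data.frame(start = s, converged = FALSE, sse = NA_real_,
                              info = NA_integer_)
      next
    }
    diag[[s]] <- data.frame(start = s, converged = r$info %in% 1:4,
                            sse = r$deviance, info = r$info)
    if (is.null(best) || r$deviance < best$deviance) best <- r
  }
  if (is.null(best)) {
    stop("no optimizer start converged; per-start diagnostics:\n",
         paste(utils::capture.output(print(do.call(rbind, diag))),
               collapse = "\n"))
  }
  bb <- build(best$par)
  per_group <- do.call(rbind, lapply(seq_len(nb), function(i) {
    st <- bb$stims[[i]]
    data.frame(group = groups[i], bin = bins[[i]]$bin[1], t_on = st$t_on,
               duration = st$duration, intensity = st$intensity,
               na_coupled = st$na_coupled, stringsAsFactors = FALSE)
  }))
  sse_bin <- vapply(seq_len(nb), function(i) {
    sum(model_residuals(bb$params, bb$stims[[i]], bins[[i]])^2)
  }, numeric(1))
  structure(list(shared = bb$params, per_group = per_group,
                 sse = stats::setNames(sse_bin, names(bins)),
                 sse_total = sum(sse_bin), n_eval = n_eval, seed = seed,
                 starts = do.call(rbind, diag),
                 converged = best$info %in% 1:4),
            class = "ca_fit")
}

#' @export
print.ca_fit <- function(x, ...) {
  cat("ca_fit:", nrow(x$per_group), "bins, pooled SSE =",
      signif(x$sse_total, 5), "(", x$n_eval, "objective evaluations )\n")
  print(x$per_group)
  invisible(x)
}

#' Observed-versus-predicted overlay table
#'
#' Simulates the fitted model for every bin and tabulates observed and
#' predicted intensities on the observed frame grid, together with the
#' amplitude and 50% decay time of both traces (the predicted features are
#' computed by the same trace pipeline as the observed ones).
#'
#' @param fit a `ca_fit` from [fit_model()].
#' @param averaged the averaged traces the fit was computed from.
#' @param stim_frame index of the first post-stimulus frame.
#' @return list with `overlay` (data.frame: group, bin, time_s, observed,
#'   predicted) and `summary` (per-bin amplitude/decay50, observed and
#'   predicted).
#' @export
goodness_report <- function(fit, averaged, stim_frame = 10) {
  stopifnot(inherits(fit, "ca_fit"))
  bins <- split_bins(averaged)
  overlay <- list()
  summ <- list()
  for (i in seq_len(nrow(fit$per_group))) {
    pg <- fit$per_group[i, ]
    d <- bins[[paste(pg$group, pg$bin, sep = ".")]]
    stim <- stimulus_influx(pg$t_on, pg$duration, pg$intensity,
                            pg$na_coupled)
    res <- model_residuals(fit$shared, stim, d, stim_frame)
    pred <- d$intensity + res
    overlay[[i]] <- data.frame(group = pg$group, bin = pg$bin,
                               time_s = d$time_s, observed = d$intensity,
                               predicted = pred, stringsAsFactors = FALSE)
    fr <- seq_along(d$time_s) - 1
    f_obs <- trace_features(structure(list(
      cell_id = "obs", frame_index = fr, time = d$time_s,
      intensity = d$intensity, stim_frame = stim_frame, group = pg$group,
      normalized = TRUE, I_basal = NA_real_), class = "ca_trace"))
    f_pred <- trace_features(structure(list(
      cell_id = "pred", frame_index = fr, time = d$time_s,
      intensity = pred, stim_frame = stim_frame, group = pg$group,
      normalized = TRUE, I_basal = NA_real_), class = "ca_trace"))
    summ[[i]] <- data.frame(group = pg$group, bin = pg$bin,
                            amplitude_obs = f_obs$amplitude,
                            amplitude_pred = f_pred$amplitude,
                            decay50_obs = f_obs$decay50,
                            decay50_pred = f_pred$decay50,
                            sse = sum(res^2), stringsAsFactors = FALSE)
  }
  list(overlay = do.call(rbind, overlay), summary = do.call(rbind, summ))
}
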