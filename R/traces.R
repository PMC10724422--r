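#' A per-cell fluorescence intensity trace
#'
#' @param cell_id cell identifier (coerced to character).
#' @param frame_index 0-based, strictly increasing integer frame indices
#'   with no gaps.
#' @param time acquisition time of each frame (s).
#' @param intensity fluorescence intensity (a.u., raw or normalized).
#' @param stim_frame index of the first post-stimulus frame (>= 1, so at
#'   least one baseline frame exists).
#' @param group cell group label: one of `"target"`, `"neighbor"`,
#'   `"other"`, `"unlabeled"`.
#' @return An object of class `ca_trace`.
#' @export
intensity_trace <- function(cell_id, frame_index, time, intensity,
                            stim_frame, group = "unlabeled") {
  frame_index <- as.integer(frame_index)
  if (length(frame_index) < 2) stop("a trace needs at least two frames")
  if (any(diff(frame_index) != 1L)) {
    stop("frame_index must be strictly increasing with no gaps")
  }
  if (length(time) != length(frame_index) ||
      length(intensity) != length(frame_index)) {
    stop("time and intensity must match frame_index in length")
  }
  if (stim_frame < 1 || stim_frame > max(frame_index)) {
    stop("stim_frame must leave at least one baseline frame")
  }
  group <- match.arg(group, c("target", "neighbor", "other", "unlabeled"))
  structure(list(cell_id = as.character(cell_id), frame_index = frame_index,
                 time = as.numeric(time), intensity = as.numeric(intensity),
                 stim_frame = as.integer(stim_frame), group = group,
                 normalized = FALSE, I_basal = NA_real_),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat("ca_trace ", x$cell_id, " [", x$group, "]: ", length(x$intensity),
      " frames, stim_frame = ", x$stim_frame,
      if (x$normalized) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Normalize a trace by its baseline intensity
#'
#' The baseline `I_basal` is the mean raw intensity over the `n_baseline`
#' frames immediately preceding the stimulus frame; every intensity is
#' divided by it, so the baseline level of the normalized trace is 1 and
#' the trace maximum is the amplitude Imax/Ibasal.
#'
#' @param trace an [intensity_trace()].
#' @param n_baseline number of baseline frames to average (default 10).
#' @return The normalized trace, with `I_basal` recorded. Normalizing an
#'   already-normalized trace re-divides by the (unit) baseline mean and is
#'   therefore idempotent up to rounding.
#' @export
normalize_trace <- function(trace, n_baseline = 10) {
  stopifnot(inherits(trace, "ca_trace"))
  if (trace$stim_frame < n_baseline) {
    stop("trace has fewer than ", n_baseline, " baseline frames")
  }
  base_rows <- which(trace$frame_index >= trace$stim_frame - n_baseline &
                       trace$frame_index < trace$stim_frame)
  I_basal <- mean(trace$intensity[base_rows])
  if (!is.finite(I_basal) || I_basal <= 0) {
    stop("non-positive baseline intensity for cell ", trace$cell_id,
         " (I_basal = ", signif(I_basal, 4), "); exclude this cell")
  }
  out <- trace
  out$intensity <- trace$intensity / I_basal
  out$normalized <- TRUE
  out$I_basal <- I_basal
  out
}

#' Trace features: amplitude, 50% decay time, responder flag
#'
#' Operates on a normalized trace. The amplitude is the maximum normalized
#' intensity over the post-stimulus frames (frames before `stim_frame` are
#' ignored). The 50% decay time is the time from the frame of that maximum
#' to the first crossing of the reference level, located by linear
#' interpolation between frames:
#' * `decay_reference = "mid_basal"` (default): level = (amplitude + 1) / 2,
#'   the mid-level between maximum and baseline;
#' * `decay_reference = "half_max"`: level = amplitude / 2.
#'
#' If the trace never crosses the level before the recording ends the decay
#' time is `NA` with `decay50_defined = FALSE`.
#'
#' @param trace a normalized [intensity_trace()] (baseline frames must equal
#'   1 to within `1e-9`).
#' @param decay_reference which decay-time convention to use (see above).
#' @param responder_threshold amplitude at or above which a cell counts as a
#'   responder (default 1.2; used mainly by synthetic-data quality checks).
#' @return A list of class `ca_features`: `cell_id`, `group`, `I_basal`,
#'   `amplitude`, `peak_frame`, `peak_time`, `decay50` (s or `NA`),
#'   `decay50_defined`, `responder`.
#' @export
trace_features <- function(trace, decay_reference = c("mid_basal", "half_max"),
                           responder_threshold = 1.2) {
  stopifnot(inherits(trace, "ca_trace"))
  decay_reference <- match.arg(decay_reference)
  base_rows <- which(trace$frame_index < trace$stim_frame)
  if (!trace$normalized &&
      abs(mean(trace$intensity[base_rows]) - 1) > 1e-9) {
    stop("trace is not normalized; call normalize_trace() first")
  }
  post <- which(trace$frame_index >= trace$stim_frame)
  y <- trace$intensity[post]
  tt <- trace$time[post]
  ipk <- which.max(y)
  amplitude <- y[ipk]
  level <- switch(decay_reference,
                  mid_basal = (amplitude + 1) / 2,
                  half_max = amplitude / 2)
  decay50 <- NA_real_
  if (ipk < length(y)) {
    after <- seq(ipk, length(y) - 1)
    cross <- after[y[after] >= level & y[after + 1] < level]
    if (length(cross) > 0) {
      i <- cross[1]
      frac <- (y[i] - level) / (y[i] - y[i + 1])
      decay50 <- (tt[i] - tt[ipk]) + frac * (tt[i + 1] - tt[i])
    }
  }
  structure(list(cell_id = trace$cell_id, group = trace$group,
                 I_basal = trace$I_basal, amplitude = amplitude,
                 peak_frame = trace$frame_index[post[ipk]],
                 peak_time = tt[ipk], decay50 = decay50,
                 decay50_defined = !is.na(decay50),
                 responder = amplitude >= responder_threshold),
            class = "ca_features")
}

#' Feature table for a list of traces
#'
#' Applies [normalize_trace()] and [trace_features()] to every trace and
#' binds the results into a data frame. Cells whose baseline intensity is
#' non-positive are excluded with a warning.
#'
#' @param traces list of [intensity_trace()] objects.
#' @param n_baseline baseline frames for normalisation.
#' @param ... passed to [trace_features()].
#' @return data.frame with one row per retained cell.
#' @export
feature_table <- function(traces, n_baseline = 10, ...) {
  rows <- lapply(traces, function(tr) {
    ntr <- tryCatch(normalize_trace(tr, n_baseline), error = function(e) NULL)
    if (is.null(ntr)) {
      warning("excluding cell ", tr$cell_id, ": non-positive baseline")
      return(NULL)
    }
    f <- trace_features(ntr, ...)
    data.frame(cell_id = f$cell_id, group = f$group, I_basal = f$I_basal,
               amplitude = f$amplitude, peak_time = f$peak_time,
               decay50 = f$decay50, decay50_defined = f$decay50_defined,
               responder = f$responder, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Amplitude-quantile group averages
#'
#' Splits the normalized traces of each cell group into amplitude-quantile
#' bins and returns the frame-wise mean trace of every (group, bin). Bin
#' membership is by amplitude rank, ties broken by `cell_id` order; with
#' `quantiles = 4` the bins are amplitude quartiles. If a group has fewer
#' responder traces than requested bins, the bin count for that group is
#' reduced with a warning.
#'
#' @param traces list of normalized [intensity_trace()] objects (all on the
#'   same frame grid).
#' @param quantiles number of amplitude-quantile bins (default 4).
#' @param responders_only if `TRUE` (default) only responder traces
#'   (amplitude >= `responder_threshold`) enter the averages.
#' @param responder_threshold see [trace_features()].
#' @return data.frame with columns `group`, `bin`, `frame`, `time_s`,
#'   `intensity`, `n_cells`; attribute `"bins"` holds a per-bin summary
#'   (group, bin, n_cells, mean_amplitude), attribute `"members"` the cell
#'   ids of every bin, and attribute `"stim_frame"` the common stimulus
#'   frame.
#' @export
group_average <- function(traces, quantiles = 4, responders_only = TRUE,
                          responder_threshold = 1.2) {
  stopifnot(length(traces) > 0)
  if (!all(vapply(traces, function(x) isTRUE(x$normalized), logical(1)))) {
    stop("all traces must be normalized")
  }
  nf <- length(traces[[1]]$intensity)
  if (!all(vapply(traces, function(x) length(x$intensity), 0L) == nf)) {
    stop("all traces must share one frame grid")
  }
  amps <- vapply(traces, function(x) {
    trace_features(x, responder_threshold = responder_threshold)$amplitude
  }, numeric(1))
  ids <- vapply(traces, function(x) x$cell_id, character(1))
  grp <- vapply(traces, function(x) x$group, character(1))
  keep <- if (responders_only) amps >= responder_threshold else
    rep(TRUE, length(traces))
  out <- list()
  summ <- list()
  members_out <- list()
  for (g in unique(grp[keep])) {
    sel <- which(keep & grp == g)
    q <- quantiles
    if (length(sel) < q) {
      warning("group ", g, ": only ", length(sel),
              " traces; reducing bin count from ", q)
      q <- max(1L, length(sel))
    }
    ord <- sel[order(amps[sel], ids[sel])]
    rank <- seq_along(ord)
    bin <- ceiling(rank * q / length(ord))
    for (b in seq_len(q)) {
      members <- ord[bin == b]
      mat <- vapply(traces[members], function(x) x$intensity, numeric(nf))
      mat <- matrix(mat, nrow = nf)
      avg <- rowMeans(mat)
      out[[length(out) + 1]] <- data.frame(
        group = g, bin = b, frame = traces[[members[1]]]$frame_index,
        time_s = traces[[members[1]]]$time, intensity = avg,
        n_cells = length(members), stringsAsFactors = FALSE)
      summ[[length(summ) + 1]] <- data.frame(
        group = g, bin = b, n_cells = length(members),
        mean_amplitude = mean(amps[members]), stringsAsFactors = FALSE)
      members_out[[paste(g, b, sep = ".")]] <- ids[members]
    }
  }
  res <- do.call(rbind, out)
  attr(res, "bins") <- do.call(rbind, summ)
  attr(res, "members") <- members_out
  attr(res, "stim_frame") <- traces[[1]]$stim_frame
  res
}

#' Pearson correlation between a per-cell covariate and amplitudes
#'
#' Standard product-moment correlation with a two-sided p-value from the
#' t distribution, as used to relate response amplitude to surface
#' modulation depth or particle speed.
#'
#' @param x per-cell covariate.
#' @param y per-cell amplitudes (same length).
#' @return list `r`, `p`, `n`, `defined`; if either variable has zero
#'   variance the correlation is undefined (`defined = FALSE`, `r` and `p`
#'   are `NA`).
#' @export
correlate_features <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}
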