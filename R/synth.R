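#' Configuration of the synthetic trace/layout generator
#'
#' Defines the statistical structure of a synthetic imaging experiment:
#' a monolayer tiled by rectangular cells, a thin photostimulation
#' rectangle, a responder/non-responder mixture per cell group, per-cell
#' heterogeneity of the stimulus influx and of the baseline fluorescence,
#' and a photon-noise-like intensity noise model. Responding cells are
#' simulated with the kinetic model, so the generated traces carry the
#' target/neighbor kinetic difference the analysis is meant to detect.
#'
#' Defaults emulate the imaging protocol: 1.23 s frame interval, 10
#' pre-stimulus + 121 post-stimulus frames, a 1.4 x 80 um stimulation
#' rectangle, and a stimulus-locked surge of a few seconds followed by a
#' slow decay.
#'
#' @param n_cells number of cells (placed on a near-square grid).
#' @param frame_interval imaging frame interval (s).
#' @param n_baseline_frames,n_post_frames frames before / from stimulus
#'   onset.
#' @param cell_size nominal cell side (um).
#' @param stim_rect stimulation rectangle width and height (um).
#' @param responder_prob named probabilities that a target / neighbor /
#'   other cell responds at all.
#' @param jtheta_sdlog log-normal sd of the per-cell stimulus-intensity
#'   scale factor (meanlog 0), the source of amplitude heterogeneity.
#' @param noise_mult,noise_add multiplicative Gaussian noise sd and additive
#'   Gaussian noise sd (the latter as a fraction of `I_basal`).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-cell raw baseline intensity `I_basal` (a.u.).
#' @param params ground-truth [model_parameters()].
#' @param stimulus ground-truth target-cell [stimulus_influx()]; neighbor
#'   cells reuse it with `na_coupled = FALSE` and intensity scaled by
#'   `neighbor_intensity_frac`.
#' @param neighbor_intensity_frac fraction of the target influx reaching a
#'   neighbor through gap junctions.
#' @param seed RNG seed recorded in the output metadata.
#' @return list of class `ca_synth_config`.
#' @export
synth_config <- function(n_cells = 100, frame_interval = 1.23,
                         n_baseline_frames = 10, n_post_frames = 121,
                         cell_size = 20, stim_rect = c(80, 1.4),
                         responder_prob = c(target = 0.7, neighbor = 0.5,
                                            other = 0.1),
                         jtheta_sdlog = 0.25, noise_mult = 0.02,
                         noise_add = 0.01, baseline_meanlog = log(100),
                         baseline_sdlog = 0.3,
                         params = default_parameters(),
                         stimulus = standard_stimulus(),
                         neighbor_intensity_frac = 0.6,
                         seed = 20231109) {
  stopifnot(all(responder_prob >= 0 & responder_prob <= 1),
            jtheta_sdlog >= 0, noise_mult >= 0, noise_add >= 0,
            inherits(params, "ca_params"), inherits(stimulus, "ca_stimulus"))
  structure(as.list(environment()), class = "ca_synth_config")
}

#' Generate a synthetic cell layout
#'
#' Tiles a near-square field with non-overlapping rectangular cells (one per
#' grid slot, sides jittered within the slot) and places the stimulation
#' rectangle across the middle row. Deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @return a [cell_layout()].
#' @export
generate_layout <- function(config) {
  stopifnot(inherits(config, "ca_synth_config"))
  n <- config$n_cells
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  s <- config$cell_size
  # confluent monolayer: sub-micron gaps, well below the adjacency epsilon
  gap <- 0.1
  jit <- 0.15
  set.seed(config$seed)
  cells <- list()
  k <- 0
  for (r in seq_len(nrow_grid)) {
    for (cc in seq_len(ncol_grid)) {
      if (k >= n) break
      k <- k + 1
      w <- s - gap - stats::runif(1, 0, jit)
      h <- s - gap - stats::runif(1, 0, jit)
      x0 <- (cc - 1) * s + stats::runif(1, 0, s - gap - w)
      y0 <- (r - 1) * s + stats::runif(1, 0, s - gap - h)
      cells[[sprintf("cell_%03d", k)]] <- rect_polygon(x0, y0, w, h)
    }
  }
  mid_y <- (ceiling(nrow_grid / 2) - 0.5) * s
  stim <- rect_polygon(x0 = (ncol_grid * s - config$stim_rect[1]) / 2,
                       y0 = mid_y - config$stim_rect[2] / 2,
                       width = config$stim_rect[1],
                       height = config$stim_rect[2])
  cell_layout(cells, stim_regions = list(stim))
}

#' Generate synthetic fluorescence traces with ground truth
#'
#' For each cell: classify it from the layout, draw its responder status,
#' and — if it responds — simulate the kinetic model with the group's
#' stimulus (target: Na+-coupled; neighbor: uncoupled, reduced intensity;
#' other: no stimulus) scaled by a per-cell log-normal factor. The noisy raw
#' intensity is `I_basal * c * (1 + e_m) + I_basal * e_a` with Gaussian
#' `e_m`, `e_a`. Non-responders and "other" cells fluctuate around their
#' baseline.
#'
#' @param config a [synth_config()].
#' @param layout optionally a pre-built [cell_layout()]; defaults to
#'   [generate_layout()] of the config.
#' @return list with `traces` (list of [intensity_trace()]), `table` (long
#'   data.frame: cell_id, frame, time_s, intensity, group, stim_frame),
#'   `truth` (per-cell data.frame: group, responder, jtheta_scale,
#'   true_amplitude, true_decay50), `layout`, and `config`.
#' @export
generate_traces <- function(config, layout = NULL) {
  stopifnot(inherits(config, "ca_synth_config"))
  if (is.null(layout)) layout <- generate_layout(config)
  groups <- classify_cells(layout)
  set.seed(config$seed + 1)
  nb <- config$n_baseline_frames
  np <- config$n_post_frames
  dt <- config$frame_interval
  stim_t <- config$stimulus
  frames <- seq_len(nb + np) - 1
  times <- (frames - nb) * dt + stim_t$t_on
  # cache noise-free model traces per (group, scale); scales differ per cell
  sim_norm <- function(stim) {
    tr <- standard_trace(config$params, stim, frame_interval = dt,
                         n_baseline_frames = nb, n_post_frames = np)
    tr$intensity
  }
  traces <- list()
  truth <- list()
  for (id in names(groups)) {
    g <- groups[[id]]
    responder <- stats::runif(1) < config$responder_prob[[g]]
    scale <- if (responder && g != "other") {
      stats::rlnorm(1, 0, config$jtheta_sdlog)
    } else {
      NA_real_
    }
    c_true <- rep(1, length(frames))
    if (responder && g != "other") {
      stim <- stim_t
      stim$na_coupled <- g == "target"
      stim$intensity <- stim_t$intensity * scale *
        (if (g == "neighbor") config$neighbor_intensity_frac else 1)
      c_true <- sim_norm(stim)
    }
    I_basal <- stats::rlnorm(1, config$baseline_meanlog, config$baseline_sdlog)
    e_m <- stats::rnorm(length(frames), 0, config$noise_mult)
    e_a <- stats::rnorm(length(frames), 0, config$noise_add)
    raw <- I_basal * c_true * (1 + e_m) + I_basal * e_a
    traces[[id]] <- intensity_trace(cell_id = id, frame_index = frames,
                                    time = times, intensity = raw,
                                    stim_frame = nb, group = g)
    tf <- trace_features(intensity_trace(id, frames, times, c_true, nb, g))
    truth[[id]] <- data.frame(cell_id = id, group = g, responder = responder,
                              jtheta_scale = scale, I_basal = I_basal,
                              true_amplitude = tf$amplitude,
                              true_decay50 = tf$decay50,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, frame = tr$frame_index,
               time_s = tr$time, intensity = tr$intensity, group = tr$group,
               stim_frame = tr$stim_frame, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(traces = traces, table = tab,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       layout = layout, config = config)
}

#' Generate synthetic particle-displacement records
#'
#' Per-iteration lateral displacements of surface particles, drawn around a
#' configured mean with Gaussian jitter; fixtures for [shear_speed()].
#'
#' @param n number of records.
#' @param mean_displacement mean displacement per scan iteration (nm).
#' @param jitter Gaussian sd of the displacement (nm).
#' @param inscription_time stripe inscription time (ms).
#' @param seed RNG seed.
#' @return data.frame with `iteration`, `displacement_nm`,
#'   `inscription_ms`, `speed_nm_per_ms`.
#' @export
generate_particle_tracks <- function(n = 100, mean_displacement = 41,
                                     jitter = 2, inscription_time = 27.7,
                                     seed = 20231109) {
  set.seed(seed)
  d <- pmax(0, stats::rnorm(n, mean_displacement, jitter))
  data.frame(iteration = seq_len(n), displacement_nm = d,
             inscription_ms = inscription_time,
             speed_nm_per_ms = vapply(d, shear_speed, numeric(1),
                                      inscription_time = inscription_time))
}
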