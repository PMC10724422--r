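#' Shipped calibrated model parameters
#'
#' Reads the calibrated default parameter set from the JSON configuration
#' shipped with the package (`inst/extdata/default_params.json`). The set
#' was obtained by fitting the model to the perturbation summary surface
#' (amplitude and 50% decay time with and without the Na+ pathway, the
#' store-depletion amplitude loss, and the influx-sweep anchor); the seeded
#' calibration script is included under `scripts/calibrate.R` in the source
#' repository.
#'
#' @return a [model_parameters()] object.
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "default_params.json", package = "caflux",
                      mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_parameters, cfg$parameters)
}

#' The standard calibrated target-cell stimulus
#'
#' The stimulus pulse belonging to the shipped calibration: onset after the
#' 10 baseline frames, a pulse of a few seconds, Na+-coupled (target cell).
#'
#' @return a [stimulus_influx()] object.
#' @export
standard_stimulus <- function() {
  path <- system.file("extdata", "default_params.json", package = "caflux",
                      mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(stimulus_influx, cfg$stimulus)
}

#' Write model configuration (parameters + stimulus) to JSON
#'
#' @param params a [model_parameters()] object.
#' @param stimulus a [stimulus_influx()] object.
#' @param path output file.
#' @export
write_model_config <- function(params, stimulus, path) {
  kin <- unclass(params)[c("V_pump", "K_pump", "V_cru", "K_cru", "m_cru",
                           "K_h", "tau_h", "V_ncx", "K_ncx", "q_ncx", "k_na")]
  jsonlite::write_json(list(parameters = kin, stimulus = unclass(stimulus)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read model configuration from JSON
#'
#' @param path JSON file written by [write_model_config()].
#' @return list with elements `params` and `stimulus`.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(params = do.call(model_parameters, as.list(cfg$parameters)),
       stimulus = do.call(stimulus_influx, as.list(cfg$stimulus)))
}

#' Read a per-cell trace table from CSV
#'
#' Expects columns `cell_id`, `frame`, `time_s`, `intensity` and optionally
#' `group` and `stim_frame`. Lines starting with `#` (provenance headers)
#' are skipped. Rows are validated per cell: frames must be strictly
#' increasing with no gaps and no duplicates.
#'
#' @param path CSV file.
#' @param stim_frame fallback stimulus frame when the table has no
#'   `stim_frame` column.
#' @return list of [intensity_trace()] objects, one per cell.
#' @export
read_trace_table <- function(path, stim_frame = 10) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("cell_id", "frame", "time_s", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("trace table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  traces_from_table(df, stim_frame = stim_frame)
}

#' Build traces from a long-format table
#'
#' @param df data.frame with columns `cell_id`, `frame`, `time_s`,
#'   `intensity`, optional `group`, `stim_frame`.
#' @param stim_frame fallback stimulus frame.
#' @return list of [intensity_trace()] objects.
#' @export
traces_from_table <- function(df, stim_frame = 10) {
  parts <- split(df, df$cell_id)
  lapply(parts, function(d) {
    d <- d[order(d$frame), ]
    if (anyDuplicated(d$frame)) {
      stop("data error: duplicated frame for cell ", d$cell_id[1])
    }
    if (any(diff(d$frame) != 1)) {
      stop("data error: non-contiguous frames for cell ", d$cell_id[1])
    }
    intensity_trace(cell_id = d$cell_id[1], frame_index = d$frame,
                    time = d$time_s, intensity = d$intensity,
                    stim_frame = if ("stim_frame" %in% names(d))
                      d$stim_frame[1] else stim_frame,
                    group = if ("group" %in% names(d)) d$group[1]
                    else "unlabeled")
  })
}

#' Write a trace table to CSV with a provenance header
#'
#' @param table long-format trace data.frame (see [generate_traces()]).
#' @param path output CSV.
#' @param seed seed recorded in the provenance header.
#' @param config_hash configuration digest recorded in the header.
#' @export
write_trace_table <- function(table, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hash), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

provenance_header <- function(seed = NA, config_hash = NA) {
  ver <- tryCatch(as.character(utils::packageVersion("caflux")),
                  error = function(e) "dev")
  sprintf("# caflux %s | seed: %s | config: %s", ver, as.character(seed),
          as.character(config_hash))
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  flat <- config
  flat$params <- unclass(flat$params)
  flat$stimulus <- unclass(flat$stimulus)
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on synthetic data
#'
#' End-to-end driver: generates a synthetic data set from `config`,
#' normalizes the traces, extracts per-cell features, forms the
#' amplitude-quantile group averages, optionally fits the model to the
#' averages, runs the perturbation battery on the ground-truth parameters,
#' and writes everything (CSV tables, JSON results, provenance headers)
#' into `out_dir`. Deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @param quantiles amplitude-quantile bins for [group_average()].
#' @param fit if `TRUE`, fit the model to the averages (slow); the fit uses
#'   `n_starts` starts.
#' @param n_starts optimizer starts for the optional fit.
#' @return (invisibly) list with `features`, `averaged`, `fit` (or `NULL`),
#'   `perturbations`, and the output paths.
#' @export
run_pipeline <- function(config, out_dir, quantiles = 4, fit = FALSE,
                         n_starts = 8) {
  stopifnot(inherits(config, "ca_synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_digest(config)
  synth <- generate_traces(config)
  write_trace_table(synth$table, file.path(out_dir, "traces.csv"),
                    seed = config$seed, config_hash = hash)
  write_trace_table(synth$truth, file.path(out_dir, "ground_truth.csv"),
                    seed = config$seed, config_hash = hash)
  jsonlite::write_json(
    lapply(synth$layout$cells, function(p) unname(apply(p, 1, c,
                                                        simplify = FALSE))),
    file.path(out_dir, "layout.json"), auto_unbox = TRUE, digits = NA)
  meta <- config
  meta$params <- unclass(meta$params)
  meta$stimulus <- unclass(meta$stimulus)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("caflux")),
         config_hash = hash, seed = config$seed, config = meta),
    file.path(out_dir, "metadata.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, pretty = TRUE)
  feats <- feature_table(synth$traces)
  write_trace_table(feats, file.path(out_dir, "features.csv"),
                    seed = config$seed, config_hash = hash)
  norm <- lapply(synth$traces, normalize_trace)
  keep <- vapply(norm, function(x) x$group %in% c("target", "neighbor"),
                 logical(1))
  averaged <- group_average(norm[keep], quantiles = quantiles)
  write_trace_table(averaged, file.path(out_dir, "group_averages.csv"),
                    seed = config$seed, config_hash = hash)
  fit_res <- NULL
  if (fit) {
    fit_res <- fit_model(averaged, init = config$params,
                         t_stim = config$stimulus$t_on,
                         frame_interval = config$frame_interval,
                         n_starts = n_starts, seed = config$seed)
    jsonlite::write_json(
      list(per_group = fit_res$per_group, sse_total = fit_res$sse_total,
           seed = fit_res$seed),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows", pretty = TRUE)
  }
  sweep <- influx_sweep(config$params, config$stimulus,
                        fractions = seq(0, 1, by = 0.05))
  pert <- list(
    store_depletion_pct = store_depletion(config$params,
                                          config$stimulus)$reduction_pct,
    sodium_free = sodium_free(config$params, config$stimulus)[
      c("amplitude", "decay50")],
    ms_fraction_pct = ms_fraction_estimate(sweep, wt_increase = 1.22,
                                           ko_increase = (0.71 + 0.59) / 2))
  jsonlite::write_json(pert, file.path(out_dir, "perturbations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(sweep, file.path(out_dir, "influx_sweep.csv"),
                   row.names = FALSE)
  invisible(list(features = feats, averaged = averaged, fit = fit_res,
                 perturbations = pert, out_dir = out_dir))
}
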