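# Plain-text I/O for rasters, traces, spectra, rate series, segments and
# run configs. Rasters round-trip bit-exactly (times written with full
# double precision).

#' Write / read a spike raster as TSV
#'
#' Columns `time_ms`, `neuron_id`, `class_label`, sorted by time. Times are
#' written with 17 significant digits so the round trip is bit-exact.
#'
#' @param raster data.frame with the three columns.
#' @param path output file.
#' @return `read_raster` returns the data.frame; `write_raster` its path,
#'   invisibly.
#' @export
write_raster <- function(raster, path) {
  df <- raster[order(raster$time_ms), c("time_ms", "neuron_id", "class_label")]
  df$time_ms <- sprintf("%.17g", df$time_ms)
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  df <- read.delim(path,
    colClasses = c("character", "integer", "character"),
    stringsAsFactors = FALSE
  )
  df$time_ms <- as.numeric(df$time_ms)
  df
}

#' Write / read simulation traces as a plain-text directory container
#'
#' Stores the shared time base, network-mean traces and any per-neuron
#' trace matrices as CSV datasets (`t.csv`, `mean.csv`, `v.csv`, `u.csv`,
#' `Gex.csv`, `Gin.csv`) inside one directory, with the run metadata in a
#' JSON sidecar (`config.json`).
#'
#' @param sim a `sim_result`.
#' @param dir output directory (created if needed).
#' @return `read_traces` returns a list with `t`, `mean_v`, `mean_u`,
#'   `trace_ids`, trace matrices and `config`; `write_traces` the directory,
#'   invisibly.
#' @export
write_traces <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    utils::write.csv(as.data.frame(x), file.path(dir, name), row.names = FALSE)
  }
  wr(data.frame(t = sim$t), "t.csv")
  wr(data.frame(mean_v = sim$mean_v, mean_u = sim$mean_u), "mean.csv")
  if (length(sim$trace_ids)) {
    colnames(sim$trace_v) <- colnames(sim$trace_u) <-
      colnames(sim$trace_gex) <- colnames(sim$trace_gin) <-
      paste0("n", sim$trace_ids)
    wr(sim$trace_v, "v.csv")
    wr(sim$trace_u, "u.csv")
    wr(sim$trace_gex, "Gex.csv")
    wr(sim$trace_gin, "Gin.csv")
  }
  cfg <- list(
    N = sim$N, dt = sim$dt, t_end = sim$t_end,
    record_interval = sim$record_interval, model_kind = sim$model_kind,
    seed = sim$seed, trace_ids = sim$trace_ids,
    synapses = unclass(sim$synapses),
    network = unclass(sim$connectivity$config)
  )
  writeLines(
    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA),
    file.path(dir, "config.json")
  )
  invisible(dir)
}

#' @rdname write_traces
#' @export
read_traces <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      return(NULL)
    }
    utils::read.csv(p)
  }
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  mean_df <- rd("mean.csv")
  out <- list(
    t = rd("t.csv")$t,
    mean_v = mean_df$mean_v, mean_u = mean_df$mean_u,
    trace_ids = cfg$trace_ids, config = cfg
  )
  for (nm in c("v", "u", "Gex", "Gin")) {
    m <- rd(paste0(nm, ".csv"))
    out[[paste0("trace_", tolower(nm))]] <- if (is.null(m)) NULL else as.matrix(m)
  }
  out
}

#' Write a spectrum or rate series as CSV
#'
#' Spectra are written as `f_hz,power`; rate series as `t_ms,rate_hz`.
#'
#' @param x a `spectrum_est` or `rate_series`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_measure_csv <- function(x, path) {
  df <- if (inherits(x, "spectrum_est")) {
    data.frame(f_hz = x$f, power = x$S)
  } else if (inherits(x, "rate_series")) {
    data.frame(t_ms = x$t, rate_hz = x$r)
  } else {
    stop("x must be a spectrum_est or rate_series")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write period segments as BED-like TSV
#'
#' Columns `start_ms`, `end_ms`, `kind`.
#'
#' @param segments a [segment_periods()] result.
#' @param path output file.
#' @param what `"periods"` (active/quiescent) or `"states"` (up/down/rest).
#' @return the path, invisibly.
#' @export
write_segments <- function(segments, path, what = c("periods", "states")) {
  what <- match.arg(what)
  write.table(segments[[what]], path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read / write a run configuration (YAML)
#'
#' A run config bundles the network, synapse, noise, stimulation,
#' integration, recording and seed settings under YAML keys of the same
#' names.
#'
#' @param path YAML file.
#' @return `read_run_config` returns a named list; `write_run_config` the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config named list to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
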