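# Experiment drivers: noise-versus-coupling state diagrams, qualitative
# state classification, and duration-versus-noise scans.

#' Sweep grid over noise intensity and inhibition/excitation ratio
#'
#' The two-dimensional diagram axes: `g_in/g_ex` linear in `[0.5, 7]` and
#' the synaptic noise intensity `D` log-spaced in `[1e-6, 1e-2]`, at fixed
#' `g_ex` (default 0.15).
#'
#' @param ratio_values `g_in/g_ex` values (default 12 linear points).
#' @param D_values noise intensities (default 12 log-spaced points).
#' @param g_ex fixed excitatory increment.
#' @return list with the grid vectors and `g_ex`.
#' @export
sweep_grid <- function(ratio_values = seq(0.5, 7, length.out = 12),
                       D_values = 10^seq(-6, -2, length.out = 12),
                       g_ex = 0.15) {
  list(ratio_values = ratio_values, D_values = D_values, g_ex = g_ex)
}

#' Qualitative state label from spectral entropy and synchrony
#'
#' Pure function of `(H_s, PLV)` and two thresholds: `H_s` below
#' `hs_threshold` means oscillatory, `PLV` above `plv_threshold` means
#' synchronous. Values within `margin` of both thresholds are labelled
#' `"transition"`.
#'
#' @param H_s spectral entropy in `[0, 1]`.
#' @param PLV phase-locking value in `[0, 1]`.
#' @param hs_threshold oscillatory if `H_s < hs_threshold` (default 0.5).
#' @param plv_threshold synchronous if `PLV > plv_threshold` (default 0.5).
#' @param margin half-width of the transition band around both thresholds
#'   (default 0.1).
#' @return one of `"sync_oscillatory"`, `"sync_non_oscillatory"`,
#'   `"async_oscillatory"`, `"async_non_oscillatory"`, `"transition"`.
#' @export
classify_state <- function(H_s, PLV, hs_threshold = 0.5, plv_threshold = 0.5,
                           margin = 0.1) {
  if (abs(H_s - hs_threshold) < margin && abs(PLV - plv_threshold) < margin) {
    return("transition")
  }
  osc <- H_s < hs_threshold
  sync <- PLV > plv_threshold
  paste0(
    if (sync) "sync" else "async",
    if (osc) "_oscillatory" else "_non_oscillatory"
  )
}

#' Run a (D, g_in/g_ex) state-diagram sweep
#'
#' One simulation per grid cell (network redrawn per cell with a recorded
#' seed); spectral entropy and PLV are computed post-transient and the cell
#' is labelled with [classify_state()]. Per-cell failures are caught, logged
#' and marked missing; the sweep continues.
#'
#' @param grid a [sweep_grid()].
#' @param config a [network_config()] (its seed is combined with the cell
#'   index).
#' @param t_sim simulated time per cell (ms); must cover the PLV window plus
#'   the transient.
#' @param transient discarded initial time (ms), default 500.
#' @param plv_window PLV window (ms), default 2000.
#' @param seed base seed.
#' @param model_kind `"izhikevich"` or `"adex"`.
#' @return an object of class `state_diagram`: data.frame with one row per
#'   cell (`D`, `ratio`, `g_in`, `H_s`, `PLV`, `label`, `seed`, `ok`) plus
#'   the grid and thresholds as attributes.
#' @export
run_sweep <- function(grid, config = network_config(), t_sim = 3000,
                      transient = 500, plv_window = 2000, seed = 1L,
                      model_kind = "izhikevich") {
  stopifnot(t_sim >= transient + plv_window)
  cells <- expand.grid(D = grid$D_values, ratio = grid$ratio_values)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    D <- cells$D[i]
    ratio <- cells$ratio[i]
    cell_seed <- seed + i
    out <- data.frame(
      D = D, ratio = ratio, g_in = ratio * grid$g_ex,
      H_s = NA_real_, PLV = NA_real_, label = NA_character_,
      seed = cell_seed, ok = FALSE, stringsAsFactors = FALSE
    )
    res <- tryCatch(
      {
        cfg <- config
        cfg$seed <- cell_seed
        net <- build_network(cfg)
        syn <- synapse_params(g_ex = grid$g_ex, g_in = ratio * grid$g_ex, D = D)
        sim <- simulate_network(net, syn,
          t_end = t_sim,
          model_kind = model_kind, seed = cell_seed
        )
        rate <- firing_rate(sim$raster, sim$N,
          t0 = transient,
          t_end = t_sim
        )
        hs <- spectral_entropy(rate)$H_s
        pl <- plv(sim$raster, sim$N,
          T_window = plv_window, t0 = transient,
          seed = cell_seed
        )$plv
        c(hs, pl)
      },
      error = function(e) {
        message(sprintf(
          "sweep cell %d (D=%g, ratio=%.2f) failed: %s",
          i, D, ratio, conditionMessage(e)
        ))
        NULL
      }
    )
    if (!is.null(res)) {
      out$H_s <- res[1]
      out$PLV <- res[2]
      out$label <- classify_state(res[1], res[2])
      out$ok <- TRUE
    }
    out
  })
  df <- do.call(rbind, rows)
  structure(df,
    class = c("state_diagram", "data.frame"),
    grid = grid, hs_threshold = 0.5, plv_threshold = 0.5
  )
}

#' Mean active/quiescent (and up/down) durations versus noise intensity
#'
#' For each noise intensity and network composition, simulates, segments,
#' and tabulates mean +/- SE durations of active and quiescent periods and
#' of the up and down states within active periods. Compositions with no
#' detected periods of a kind get `NA` with `n = 0`.
#'
#' @param D_values noise intensities to scan.
#' @param configs named list of [network_config()] objects (one per
#'   composition).
#' @param synapses base [synapse_params()] (its `D` is overridden).
#' @param t_sim simulated time per point (ms).
#' @param transient discarded initial time (ms).
#' @param seed base seed.
#' @return data.frame with columns `composition`, `D`, `kind`, `mean_ms`,
#'   `se_ms`, `n`.
#' @export
duration_vs_noise <- function(D_values,
                              configs = list(RS_LTS = network_config()),
                              synapses = synapse_params(),
                              t_sim = 60000, transient = 500, seed = 1L) {
  rows <- list()
  for (comp in names(configs)) {
    for (i in seq_along(D_values)) {
      D <- D_values[i]
      cfg <- configs[[comp]]
      cfg$seed <- seed + i
      net <- build_network(cfg)
      syn <- synapses
      syn$D <- D
      sim <- simulate_network(net, syn,
        t_end = t_sim,
        seed = seed + i
      )
      seg <- segment_simulation(sim, t0 = transient)
      for (kind in c("active", "quiescent", "up", "down")) {
        st <- tryCatch(duration_stats(seg, kind), error = function(e) NULL)
        rows[[length(rows) + 1]] <- data.frame(
          composition = comp, D = D, kind = kind,
          mean_ms = if (is.null(st)) NA_real_ else st$mean,
          se_ms = if (is.null(st)) NA_real_ else st$se,
          n = if (is.null(st)) 0L else st$n,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
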