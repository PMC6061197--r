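#' Simulate the network
#'
#' Advances all neurons and synaptic conductances with the stochastic Heun
#' (predictor-corrector) scheme. The additive conductance noise uses the same
#' Wiener increment in predictor and corrector stage; spikes detected at the
#' end of a step trigger the fire-and-reset rule and enqueue conductance
#' jumps on all postsynaptic targets, delivered at the next step (one-step
#' delay, effectively zero). Conductances are reflected at zero. With `D = 0`
#' and no stimulus the global rest state is an exact fixed point: the network
#' stays silent indefinitely.
#'
#' Initial conditions default to the per-class resting state with zero
#' conductances.
#'
#' @param connectivity a [build_network()] result.
#' @param synapses a [synapse_params()] object (carries `g_ex`, `g_in`, `D`).
#' @param stimulus optional [stim_protocol()] object, or `NULL` for free
#'   evolution.
#' @param t_end simulated time (ms).
#' @param dt integration step (ms), default 0.05.
#' @param record_interval sampling interval for traces (ms), default 1;
#'   must be `>= dt`.
#' @param record_ids neuron ids (1-based) whose full `v`, `u`, `G_ex`, `G_in`
#'   traces are recorded, in addition to the always-recorded network means.
#' @param model_kind `"izhikevich"` or `"adex"`.
#' @param seed integer seed of the simulation RNG (noise realization).
#' @return an object of class `sim_result`: list with `raster` (data.frame
#'   `time_ms`, `neuron_id`, `class_label`, sorted by time), `t`, `mean_v`,
#'   `mean_u`, per-recorded-neuron trace matrices, `reset_count`,
#'   `last_spike_time`, `dt`, `t_end` and a config snapshot.
#' @examples
#' net <- build_network(network_config(N = 200, p = 0.05, seed = 1))
#' sim <- simulate_network(net, synapse_params(D = 1e-5), t_end = 500, seed = 1)
#' head(sim$raster)
#' @export
simulate_network <- function(connectivity, synapses = synapse_params(),
                             stimulus = NULL, t_end = 1000, dt = 0.05,
                             record_interval = 1, record_ids = integer(0),
                             model_kind = c("izhikevich", "adex"),
                             seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(connectivity, "connectivity"))
  stopifnot(t_end > 0, dt > 0, record_interval >= dt)
  N <- connectivity$N

  params_of <- lapply(
    stats::setNames(unique(connectivity$type_of), unique(connectivity$type_of)),
    neuron_params,
    model_kind = model_kind
  )
  pk <- function(field) {
    vapply(connectivity$type_of, function(l) params_of[[l]][[field]], 0)
  }
  a <- pk("a"); b <- pk("b"); cc <- pk("c"); d <- pk("d")
  common <- params_of[[1]]

  rest <- lapply(params_of, resting_state)
  v0 <- vapply(connectivity$type_of, function(l) rest[[l]][["v"]], 0)
  u0 <- vapply(connectivity$type_of, function(l) rest[[l]][["u"]], 0)

  I_stim <- numeric(N)
  t_stim <- 0
  if (!is.null(stimulus)) {
    I_stim <- make_stimulus(stimulus, connectivity)
    t_stim <- stimulus$t_stim
  }

  # CSR adjacency, 0-based for the compiled core
  ord <- order(connectivity$edges[, "pre"])
  pre_sorted <- connectivity$edges[ord, "pre"]
  targets <- connectivity$edges[ord, "post"] - 1L
  offsets <- c(0L, cumsum(tabulate(pre_sorted, nbins = N)))

  res <- .simulate_cpp(
    adj_targets = as.integer(targets),
    adj_offsets = as.integer(offsets),
    is_exc = connectivity$is_exc,
    a = a, b = b, c = cc, d = d,
    alpha = common$alpha, beta = common$beta, gamma = common$gamma,
    v_peak = common$v_peak,
    model = if (model_kind == "izhikevich") 0L else 1L,
    adex_gL = common$adex_gL, adex_DeltaT = common$adex_DeltaT,
    adex_vT = common$adex_vT, adex_offset = common$adex_offset,
    g_ex = synapses$g_ex, g_in = synapses$g_in,
    tau_ex = synapses$tau_ex, tau_in = synapses$tau_in,
    E_ex = synapses$E_ex, E_in = synapses$E_in,
    D = synapses$D,
    n_ex = as.integer(connectivity$n_ex),
    n_in = as.integer(connectivity$n_in),
    reflect = TRUE,
    I_stim = I_stim, t_stim = t_stim,
    v0 = v0, u0 = u0,
    t_end = t_end, dt = dt, record_interval = record_interval,
    record_ids = as.integer(record_ids - 1L),
    seed = as.integer(seed)
  )

  raster <- data.frame(
    time_ms = res$spike_t,
    neuron_id = res$spike_id + 1L,
    class_label = connectivity$type_of[res$spike_id + 1L],
    stringsAsFactors = FALSE
  )

  structure(
    list(
      raster = raster,
      t = res$t, mean_v = res$mean_v, mean_u = res$mean_u,
      trace_ids = as.integer(record_ids),
      trace_v = res$trace_v, trace_u = res$trace_u,
      trace_gex = res$trace_gex, trace_gin = res$trace_gin,
      reset_count = res$reset_count,
      last_spike_time = res$last_spike_time,
      N = N, dt = dt, t_end = t_end, t_stim = t_stim,
      record_interval = record_interval,
      model_kind = model_kind, seed = as.integer(seed),
      connectivity = connectivity, synapses = synapses
    ),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> N=%d, %s, t_end=%g ms (dt=%g), %d spikes, D=%g\n",
    x$N, x$model_kind, x$t_end, x$dt, nrow(x$raster), x$synapses$D
  ))
  invisible(x)
}

#' Raster plot of a simulation
#'
#' @param x a `sim_result`.
#' @param max_neurons plot at most this many neurons (lowest ids).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sim_result <- function(x, max_neurons = 512, ...) {
  r <- x$raster[x$raster$neuron_id <= max_neurons, ]
  graphics::plot(r$time_ms, r$neuron_id,
    pch = ".", xlab = "time (ms)",
    ylab = "neuron", ...
  )
  invisible(x)
}

#' Deterministic stimulation trials
#'
#' Runs the noiseless (`D = 0`) stimulation protocol grid: each trial applies
#' one protocol, then lets the network evolve freely. The free-activity
#' duration is the time from stimulus end to the last network spike; trials
#' shorter than `min_duration` are discarded. Eventually every trial ends at
#' rest, so kept trials are the long-lived self-sustained transients.
#'
#' @param connectivity a [build_network()] result.
#' @param synapses a [synapse_params()] with `D = 0` (enforced).
#' @param protocols list of [stim_protocol()] objects (the protocol grid).
#' @param t_end simulated time per trial (ms).
#' @param min_duration minimum free-activity duration (ms) to keep a trial.
#' @param dt,record_interval integration and recording steps (ms).
#' @return list with `kept` (list of `sim_result`), `free_duration` for all
#'   trials, and `kept_idx`.
#' @export
run_deterministic_trials <- function(connectivity, synapses = synapse_params(),
                                     protocols, t_end = 2000,
                                     min_duration = 400, dt = 0.05,
                                     record_interval = 1) {
  if (synapses$D != 0) {
    synapses$D <- 0
  }
  free <- numeric(length(protocols))
  kept <- list()
  kept_idx <- integer(0)
  for (i in seq_along(protocols)) {
    pr <- protocols[[i]]
    sim <- simulate_network(connectivity, synapses,
      stimulus = pr,
      t_end = t_end, dt = dt, record_interval = record_interval, seed = 1L
    )
    last <- sim$last_spike_time
    free[i] <- if (is.na(last)) 0 else max(0, last - pr$t_stim)
    if (free[i] >= min_duration) {
      kept[[length(kept) + 1]] <- sim
      kept_idx <- c(kept_idx, i)
    }
  }
  list(kept = kept, free_duration = free, kept_idx = kept_idx)
}

#' Default deterministic protocol grid
#'
#' The stimulation grid of the deterministic setup: amplitudes, durations and
#' stimulated fractions crossed, one protocol per combination with a distinct
#' target seed.
#'
#' @param I_stim,t_stim,fraction vectors of amplitudes, durations (ms) and
#'   fractions to cross.
#' @param seed base seed; trial `i` selects targets with `seed + i`.
#' @return list of [stim_protocol()] objects.
#' @export
protocol_grid <- function(I_stim = c(10, 15, 20), t_stim = c(50, 150, 300),
                          fraction = c(1, 1 / 2, 1 / 4, 1 / 8, 1 / 16),
                          seed = 1L) {
  grid <- expand.grid(I = I_stim, tt = t_stim, fr = fraction)
  lapply(seq_len(nrow(grid)), function(i) {
    stim_protocol(grid$I[i], grid$tt[i], grid$fr[i], target_seed = seed + i)
  })
}
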