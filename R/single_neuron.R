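#' First-spike time of an isolated noise-driven neuron
#'
#' Monte-Carlo estimate of the mean time to the first spike of a neuron
#' initialized at rest with zero conductances and driven only by the
#' Ornstein-Uhlenbeck fluctuations of its synaptic conductances (reflected
#' at zero; in-degree factor `n` defaults to 1). This is a first-passage
#' problem: the neuron fires once the fluctuating synaptic current lifts the
#' rest state past the ignition threshold. With `D = 0` the rest state is
#' stable and no spike ever occurs; this is signalled as an error.
#'
#' Trials that do not spike before `t_max` are censored; their fraction is
#' reported and they are excluded from the mean.
#'
#' @param params a [neuron_params()] object.
#' @param D synaptic noise intensity, `> 0`.
#' @param n in-degree factor scaling the noise variance (default 1).
#' @param n_trials number of Monte-Carlo trials.
#' @param t_max per-trial time cap (ms), default 1e4.
#' @param dt integration step (ms), default 0.05 (same as network runs).
#' @param seed RNG seed.
#' @param synapses a [synapse_params()] (taus and reversals; `D` therein is
#'   ignored in favour of the `D` argument).
#' @return list with `mean`, `se`, `n_trials`, `censored_fraction`, `times`
#'   (uncensored first-spike times, ms).
#' @export
first_spike_time <- function(params, D, n = 1, n_trials = 200, t_max = 1e4,
                             dt = 0.05, seed = 1L,
                             synapses = synapse_params()) {
  if (D <= 0) {
    stop("D = 0: the rest state is stable and the neuron never spikes")
  }
  rest <- resting_state(params)
  times <- .first_spike_cpp(
    a = params$a, b = params$b, c = params$c, d = params$d,
    alpha = params$alpha, beta = params$beta, gamma = params$gamma,
    v_peak = params$v_peak,
    model = if (params$model_kind == "izhikevich") 0L else 1L,
    adex_gL = params$adex_gL, adex_DeltaT = params$adex_DeltaT,
    adex_vT = params$adex_vT, adex_offset = params$adex_offset,
    tau_ex = synapses$tau_ex, tau_in = synapses$tau_in,
    E_ex = synapses$E_ex, E_in = synapses$E_in,
    D = D, n_deg = n,
    v_rest = rest[["v"]], u_rest = rest[["u"]],
    n_trials = as.integer(n_trials), t_max = t_max, dt = dt,
    seed = as.integer(seed)
  )
  cens <- is.na(times)
  ok <- times[!cens]
  list(
    mean = if (length(ok)) mean(ok) else NA_real_,
    se = if (length(ok) > 1) sd(ok) / sqrt(length(ok)) else NA_real_,
    n_trials = n_trials,
    censored_fraction = mean(cens),
    times = ok
  )
}

#' First-spike-time curve over a noise grid
#'
#' @param params a [neuron_params()] object.
#' @param D_grid noise intensities.
#' @param ... passed to [first_spike_time()].
#' @return data.frame `D`, `mean_ms`, `se_ms`, `censored_fraction`.
#' @export
first_spike_curve <- function(params, D_grid, ...) {
  rows <- lapply(seq_along(D_grid), function(i) {
    fs <- first_spike_time(params, D_grid[i], ...)
    data.frame(
      D = D_grid[i], mean_ms = fs$mean, se_ms = fs$se,
      censored_fraction = fs$censored_fraction
    )
  })
  do.call(rbind, rows)
}

#' Phase-plane trajectory of a recorded neuron
#'
#' Extracts the `(v, u)` trajectory of one recorded neuron over a set of
#' time windows, together with snapshots of the voltage nullcline at each
#' window boundary computed from the neuron's recorded instantaneous
#' synaptic current (the recovery nullcline `u = b v` is static). Also flags
#' whether, at the window end, the neuron lies inside the nullcline parabola
#' below the reset voltage: the hyperpolarized down-state signature.
#'
#' @param sim a `sim_result` with the neuron in `record_ids`.
#' @param neuron_id neuron (1-based) to extract.
#' @param windows list of `c(start, end)` windows (ms).
#' @param inside_tol margin (in units of `u`) above the nullcline required
#'   before the neuron counts as inside the parabola; the rest point lies
#'   exactly on the nullcline, so a strict comparison would flip on
#'   round-off (default 0.5).
#' @return list of per-window lists with `t`, `v`, `u`, `I_syn`,
#'   `nullcline_start`, `nullcline_end`, `inside_parabola`, plus the
#'   reference lines `v_reset`, `v_peak` and the rest state.
#' @export
phase_plane_trace <- function(sim, neuron_id, windows, inside_tol = 0.5) {
  q <- match(neuron_id, sim$trace_ids)
  if (is.na(q)) stop("neuron not recorded; pass it in record_ids")
  label <- sim$connectivity$type_of[neuron_id]
  params <- neuron_params(label, model_kind = sim$model_kind)
  syn <- sim$synapses
  out <- lapply(windows, function(w) {
    keep <- sim$t >= w[1] & sim$t <= w[2]
    if (!any(keep)) stop("window outside the recorded range")
    v <- sim$trace_v[keep, q]
    u <- sim$trace_u[keep, q]
    Isyn <- synaptic_current(v, sim$trace_gex[keep, q], sim$trace_gin[keep, q],
      params = syn
    )
    nl0 <- nullclines(params, I = Isyn[1])
    nl1 <- nullclines(params, I = Isyn[length(Isyn)])
    v_end <- v[length(v)]
    u_end <- u[length(u)]
    ubar_at <- params$alpha * v_end^2 + params$beta * v_end + params$gamma +
      Isyn[length(Isyn)]
    list(
      t = sim$t[keep], v = v, u = u, I_syn = Isyn,
      nullcline_start = nl0, nullcline_end = nl1,
      inside_parabola = (u_end > ubar_at + inside_tol) && (v_end < params$c)
    )
  })
  list(
    neuron_id = neuron_id, class_label = label, windows = out,
    v_reset = params$c, v_peak = params$v_peak,
    rest = resting_state(params)
  )
}

#' Population snapshot at one instant
#'
#' `(v, u)` scatter and synaptic-current histogram for a random sample of
#' recorded neurons at a given time.
#'
#' @param sim a `sim_result` with recorded neurons.
#' @param t time instant (ms) within the record.
#' @param sample number of neurons to sample (default 200, capped at the
#'   number recorded).
#' @param seed seed for the sample draw.
#' @return list with `t`, `neuron_ids`, `v`, `u`, `I_syn`, `n_sampled`.
#' @export
population_snapshot <- function(sim, t, sample = 200, seed = 1L) {
  k <- which.min(abs(sim$t - t))
  if (abs(sim$t[k] - t) > sim$record_interval) {
    stop("t outside the recorded range")
  }
  n_rec <- length(sim$trace_ids)
  if (n_rec == 0) stop("no recorded neurons")
  m <- min(sample, n_rec)
  sel <- with_seed(seed, sample.int(n_rec, m))
  v <- sim$trace_v[k, sel]
  u <- sim$trace_u[k, sel]
  Isyn <- synaptic_current(v, sim$trace_gex[k, sel], sim$trace_gin[k, sel],
    params = sim$synapses
  )
  list(
    t = sim$t[k], neuron_ids = sim$trace_ids[sel],
    v = v, u = u, I_syn = Isyn, n_sampled = m
  )
}
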