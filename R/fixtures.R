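# Synthetic rasters and traces with known statistical structure, so the
# measures and the segmentation logic can be exercised without running the
# full network simulator. Generation is fully determined by (parameters,
# seed) and all outputs use the same containers as the simulator.

#' Poisson raster fixture
#'
#' Independent homogeneous Poisson spike trains: the statistical structure
#' of asynchronous-irregular activity (flat rate spectrum, no pairwise
#' phase locking).
#'
#' @param N number of neurons.
#' @param rate per-neuron rate (Hz).
#' @param T_ms record length (ms).
#' @param seed RNG seed.
#' @return data.frame `time_ms`, `neuron_id`, `class_label` (`"synthetic"`),
#'   sorted by time.
#' @export
make_poisson_raster <- function(N, rate, T_ms, seed = 1L) {
  with_seed(seed, {
    counts <- rpois(N, rate * T_ms * 1e-3)
    times <- runif(sum(counts), 0, T_ms)
    ids <- rep(seq_len(N), counts)
    ord <- order(times)
    data.frame(
      time_ms = times[ord], neuron_id = ids[ord],
      class_label = rep("synthetic", length(times)),
      stringsAsFactors = FALSE
    )
  })
}

#' Jittered periodic raster fixture
#'
#' Population bursts every `1/f` seconds; each neuron participates in each
#' burst with probability `participation`, and each emitted spike is
#' jittered by a Gaussian of SD `jitter_sd` ms. With zero jitter the rate
#' series is a delta comb whose power sits on the harmonics of `f`; a
#' nonzero jitter applies a Gaussian envelope `exp(-(2 pi f sigma)^2 / 2)`
#' that suppresses the higher harmonics, so the spectrum concentrates at
#' the fundamental, and at large jitter the power spreads into a broad
#' band (rising spectral entropy).
#'
#' @param N number of neurons.
#' @param f burst frequency (Hz), `> 0`.
#' @param jitter_sd per-spike jitter SD (ms).
#' @param participation per-burst participation probability.
#' @param T_ms record length (ms).
#' @param seed RNG seed.
#' @return raster data.frame as in [make_poisson_raster()].
#' @export
make_periodic_raster <- function(N, f, jitter_sd = 0, participation = 1,
                                 T_ms = 2000, seed = 1L) {
  stopifnot(f > 0)
  with_seed(seed, {
    period <- 1000 / f
    burst_times <- seq(period / 2, T_ms - period / 2, by = period)
    times <- numeric(0)
    ids <- integer(0)
    for (bt in burst_times) {
      part <- which(runif(N) < participation)
      tt <- bt + rnorm(length(part), 0, jitter_sd)
      times <- c(times, tt)
      ids <- c(ids, part)
    }
    keep <- times >= 0 & times < T_ms
    times <- times[keep]
    ids <- ids[keep]
    ord <- order(times)
    data.frame(
      time_ms = times[ord], neuron_id = ids[ord],
      class_label = rep("synthetic", length(times)),
      stringsAsFactors = FALSE
    )
  })
}

#' Two- or three-state voltage fixture
#'
#' Alternating-level mean-voltage trace with exponentially distributed dwell
#' times, mimicking the collective up/down (and rest) phenomenology, plus a
#' consistent rate series: high rate in the depolarized state, near zero
#' elsewhere. The generator's state sequence is returned as ground truth for
#' classifier parameter-recovery tests.
#'
#' @param levels named voltage levels (mV); names from
#'   `c("up", "down", "rest")`, cycled in the given order.
#' @param dwell_means mean dwell time (ms) per level, same length/order.
#' @param noise_sd additive Gaussian noise SD on the trace (mV).
#' @param T_ms record length (ms).
#' @param rate_up rate (Hz) emitted in the `up` state (default 50);
#'   other states emit `rate_low` (default 0).
#' @param rate_low rate (Hz) outside up states.
#' @param seed RNG seed.
#' @return list with `t` (1-ms grid), `mean_v`, `rate` (a `rate_series`),
#'   `true_states` (per-bin labels), `true_segments` (data.frame).
#' @export
make_two_state_voltage <- function(levels = c(up = -55, down = -78),
                                   dwell_means = c(up = 150, down = 100),
                                   noise_sd = 1, T_ms = 10000,
                                   rate_up = 50, rate_low = 0, seed = 1L) {
  stopifnot(
    length(levels) %in% c(2, 3),
    length(dwell_means) == length(levels),
    all(names(levels) %in% c("up", "down", "rest"))
  )
  with_seed(seed, {
    t <- seq(0, T_ms - 1)
    nlev <- length(levels)
    # alternate levels in order, exponential dwell times
    st <- integer(0)
    cur <- 1
    total <- 0
    seg_start <- numeric(0)
    seg_end <- numeric(0)
    seg_kind <- character(0)
    while (total < T_ms) {
      dwell <- max(1, round(rexp(1, 1 / dwell_means[cur])))
      dwell <- min(dwell, T_ms - total)
      st <- c(st, rep(cur, dwell))
      seg_start <- c(seg_start, total)
      seg_end <- c(seg_end, total + dwell)
      seg_kind <- c(seg_kind, names(levels)[cur])
      total <- total + dwell
      cur <- cur %% nlev + 1
    }
    mean_v <- as.numeric(levels[st]) + rnorm(T_ms, 0, noise_sd)
    lam <- ifelse(names(levels)[st] == "up", rate_up, rate_low)
    r <- rpois(T_ms, lam * 1e-3 * 1000) # counts per 1-ms bin at N=1000
    rate <- structure(
      list(t = t, r = r / (1000 * 1e-3), delta_t = 1, N = 1000),
      class = "rate_series"
    )
    list(
      t = t, mean_v = mean_v, rate = rate,
      true_states = names(levels)[st],
      true_segments = data.frame(
        start_ms = seg_start, end_ms = seg_end, kind = seg_kind,
        stringsAsFactors = FALSE
      )
    )
  })
}
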