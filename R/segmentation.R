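#' Segmentation thresholds
#'
#' Thresholds for labelling 1-ms bins of network activity into up / down /
#' rest states. All thresholds are recorded with the labels for
#' reproducibility.
#'
#' The qualitative anchors are: the down state is a hyperpolarized mean
#' voltage close to -80 mV; the rest state is a mean voltage within a narrow
#' band of the composition-weighted resting voltage together with near-zero
#' activity; the up state is a depolarized mean voltage together with a
#' network rate above 20% of its reference (window-average) value.
#'
#' @param v_rest resting voltage reference (mV); computed from the network
#'   composition when labelling a simulation.
#' @param rest_band half-width of the rest voltage band (mV), default 3.
#' @param v_down hyperpolarized anchor (mV), default -80.
#' @param down_band half-width of the down band (mV), default 5.
#' @param rate_frac up state requires rate above this fraction of the
#'   reference rate (default 0.2).
#' @param rate_ref `"mean"` (window-average rate, default) or `"max"`.
#' @param min_gap label runs shorter than this (ms) are merged into their
#'   neighbours when segmenting (default 20).
#' @return an object of class `seg_thresholds`.
#' @export
seg_thresholds <- function(v_rest = -70, rest_band = 3, v_down = -80,
                           down_band = 5, rate_frac = 0.2,
                           rate_ref = c("mean", "max"), min_gap = 20) {
  rate_ref <- match.arg(rate_ref)
  structure(
    list(
      v_rest = v_rest, rest_band = rest_band, v_down = v_down,
      down_band = down_band, rate_frac = rate_frac, rate_ref = rate_ref,
      min_gap = min_gap
    ),
    class = "seg_thresholds"
  )
}

# composition-weighted resting voltage of a connectivity
.rest_voltage <- function(connectivity) {
  tab <- table(connectivity$type_of)
  rests <- vapply(
    names(tab),
    function(l) resting_state(neuron_params(l))[["v"]], 0
  )
  sum(rests * as.numeric(tab)) / sum(tab)
}

#' Label time bins as up / down / rest
#'
#' Applies the threshold rules bin by bin: `up` when the mean voltage is
#' above the rest band and the network rate exceeds `rate_frac` of its
#' reference value; `down` when the mean voltage is within `down_band` of
#' the hyperpolarized anchor (and below the rest band); `rest` otherwise.
#'
#' @param mean_v network-mean voltage per bin (mV).
#' @param rate a [firing_rate()] result on the same time base.
#' @param thresholds a [seg_thresholds()] object.
#' @return an object of class `state_labels`: list with `labels` (factor
#'   up/down/rest per bin), `t`, and the thresholds used.
#' @export
label_bins <- function(mean_v, rate, thresholds = seg_thresholds()) {
  if (length(mean_v) != length(rate$r)) {
    stop("mean_v and rate must share one time base")
  }
  if (all(mean_v == 0) && all(rate$r == 0)) stop("all-zero inputs")
  th <- thresholds
  ref <- if (th$rate_ref == "mean") mean(rate$r) else max(rate$r)
  high_rate <- rate$r > th$rate_frac * ref
  up <- mean_v > th$v_rest + th$rest_band & high_rate
  down <- !up &
    mean_v < th$v_rest - th$rest_band &
    abs(mean_v - th$v_down) <= th$down_band
  labels <- rep("rest", length(mean_v))
  labels[down] <- "down"
  labels[up] <- "up"
  structure(
    list(
      labels = factor(labels, levels = c("up", "down", "rest")),
      t = rate$t, delta_t = rate$delta_t, thresholds = th
    ),
    class = "state_labels"
  )
}

# run-length segments of a character vector of labels; returns data.frame
.rle_segments <- function(lab, t, delta_t) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(
    start_ms = t[starts],
    end_ms = t[ends] + delta_t,
    kind = r$values,
    stringsAsFactors = FALSE
  )
}

#' Segment labelled bins into active and quiescent periods
#'
#' Maximal runs of up/down alternation become `active` periods; maximal rest
#' runs become `quiescent` periods. Runs shorter than `min_gap` ms are merged
#' into their neighbours (hysteresis against single-bin flicker). Within each
#' active period, the up/down sub-intervals are retained.
#'
#' @param labels a [label_bins()] result.
#' @param min_gap override of the thresholds' `min_gap` (ms).
#' @return an object of class `period_segments`: list with `periods`
#'   (data.frame `start_ms`, `end_ms`, `kind` in active/quiescent),
#'   `states` (data.frame of up/down/rest sub-intervals), and the window.
#' @export
segment_periods <- function(labels, min_gap = NULL) {
  th <- labels$thresholds
  if (is.null(min_gap)) min_gap <- th$min_gap
  lab <- as.character(labels$labels)
  act <- ifelse(lab == "rest", "quiescent", "active")
  delta_t <- labels$delta_t

  # merge runs shorter than min_gap into their neighbours, repeatedly
  repeat {
    r <- rle(act)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths * delta_t < min_gap)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- if (i == 1) r$values[2] else r$values[i - 1]
    act <- inverse.rle(r)
  }

  periods <- .rle_segments(act, labels$t, delta_t)
  states <- .rle_segments(lab, labels$t, delta_t)
  structure(
    list(
      periods = periods, states = states,
      t0 = labels$t[1], t_end = labels$t[length(labels$t)] + delta_t,
      min_gap = min_gap, thresholds = th
    ),
    class = "period_segments"
  )
}

#' Duration statistics of segments
#'
#' Mean, standard deviation, standard error and a histogram of the durations
#' of segments of one kind, with simple outlier flagging (beyond 3 SD of the
#' mean) and an exponential-shape diagnostic: the squared correlation of
#' log survival versus duration (1 for an exponential distribution).
#'
#' @param segments a [segment_periods()] result.
#' @param kind `"active"`, `"quiescent"` (periods) or `"up"`, `"down"`,
#'   `"rest"` (states within the window).
#' @param breaks passed to [graphics::hist()] computation (default
#'   `"Sturges"`).
#' @return an object of class `duration_stats`: list with `durations`, `n`,
#'   `mean`, `sd`, `se` (NA for a single interval, flagged), `histogram`
#'   (list of `breaks`, `counts`), `outliers` (indices), `exp_r2`.
#' @export
duration_stats <- function(segments, kind, breaks = "Sturges") {
  df <- if (kind %in% c("active", "quiescent")) {
    segments$periods
  } else {
    segments$states
  }
  dur <- df$end_ms[df$kind == kind] - df$start_ms[df$kind == kind]
  if (!length(dur)) {
    stop(sprintf("no intervals of kind '%s'", kind))
  }
  m <- mean(dur)
  s <- if (length(dur) > 1) sd(dur) else NA_real_
  se <- if (length(dur) > 1) s / sqrt(length(dur)) else NA_real_
  h <- graphics::hist(dur, breaks = breaks, plot = FALSE)
  out <- if (!is.na(s) && s > 0) which(abs(dur - m) > 3 * s) else integer(0)
  # exponential-shape diagnostic: log-survival linearity
  exp_r2 <- NA_real_
  if (length(dur) >= 5) {
    sdur <- sort(dur)
    surv <- 1 - (seq_along(sdur) - 0.5) / length(sdur)
    exp_r2 <- suppressWarnings(stats::cor(sdur, log(surv)))^2
  }
  structure(
    list(
      kind = kind, durations = dur, n = length(dur),
      mean = m, sd = s, se = se,
      histogram = list(breaks = h$breaks, counts = h$counts),
      outliers = out, single_interval = length(dur) == 1,
      exp_r2 = exp_r2
    ),
    class = "duration_stats"
  )
}

#' @export
print.duration_stats <- function(x, ...) {
  cat(sprintf(
    "<duration_stats> %s: n=%d, mean=%.1f ms (sd=%.1f, se=%.1f)\n",
    x$kind, x$n, x$mean, x$sd, x$se
  ))
  invisible(x)
}

#' Histogram and modality of network-averaged traces
#'
#' Histogram of a network-averaged voltage (or recovery-variable) trace,
#' with median/mean box summary and a modality count: the number of local
#' maxima of a kernel-density estimate whose height exceeds
#' `prominence` times the global maximum.
#'
#' @param v numeric trace (typically `sim_result$mean_v`), or a list of
#'   traces to pool across trials.
#' @param breaks histogram breaks (default 60 equal bins).
#' @param prominence relative height threshold for counting a mode
#'   (default 0.05).
#' @param bw kernel bandwidth passed to [stats::density()] (default
#'   `"nrd0"`).
#' @return list with `histogram` (breaks, counts, mids), `median`, `mean`,
#'   `n_modes`, `mode_locations`.
#' @export
voltage_histogram <- function(v, breaks = 60, prominence = 0.05, bw = "nrd0") {
  if (is.list(v)) v <- unlist(v)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  n_modes <- NA_integer_
  locs <- numeric(0)
  if (length(unique(v)) > 1) {
    dd <- density(v, bw = bw)
    y <- dd$y
    peak <- which(diff(sign(diff(y))) == -2) + 1
    peak <- peak[y[peak] >= prominence * max(y)]
    n_modes <- length(peak)
    locs <- dd$x[peak]
  } else {
    n_modes <- 1L
    locs <- v[1]
  }
  list(
    histogram = list(breaks = h$breaks, counts = h$counts, mids = h$mids),
    median = median(v), mean = mean(v),
    n_modes = n_modes, mode_locations = locs
  )
}

#' Label and segment a simulation in one call
#'
#' Convenience wrapper: computes the 1-ms firing rate and mean-voltage
#' labels over a window of a [simulate_network()] result, using the
#' network's composition-weighted resting voltage, then segments.
#'
#' @param sim a `sim_result`.
#' @param t0 start of the analysed window (ms), e.g. after a transient.
#' @param t_end end of the window (default: end of the record).
#' @param thresholds optional [seg_thresholds()]; by default `v_rest` is set
#'   from the composition.
#' @return a [segment_periods()] result.
#' @export
segment_simulation <- function(sim, t0 = 0, t_end = NULL, thresholds = NULL) {
  if (is.null(t_end)) t_end <- sim$t_end
  if (is.null(thresholds)) {
    thresholds <- seg_thresholds(v_rest = .rest_voltage(sim$connectivity))
  }
  keep <- sim$t > t0 & sim$t <= t_end
  rate <- firing_rate(sim$raster, sim$N,
    delta_t = sim$record_interval,
    t0 = t0, t_end = t_end
  )
  n <- min(length(rate$r), sum(keep))
  rate$t <- rate$t[seq_len(n)]
  rate$r <- rate$r[seq_len(n)]
  mv <- sim$mean_v[keep][seq_len(n)]
  labels <- label_bins(mv, rate, thresholds)
  segment_periods(labels)
}
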