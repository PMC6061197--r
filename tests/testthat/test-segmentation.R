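# State labelling, period segmentation, duration statistics and
# voltage histograms.

test_that("alternating synthetic trace yields alternating up/down labels", {
  th <- seg_thresholds(v_rest = -70)
  n <- 400
  mean_v <- rep(c(-55, -78), each = 50, length.out = n)
  r <- structure(
    list(
      t = seq_len(n) - 1,
      r = rep(c(40, 0), each = 50, length.out = n), delta_t = 1, N = 100
    ),
    class = "rate_series"
  )
  lab <- label_bins(mean_v, r, th)
  expect_equal(
    as.character(lab$labels),
    rep(c("up", "down"), each = 50, length.out = n)
  )
  # all bins carry a label
  expect_false(anyNA(lab$labels))
  seg <- segment_periods(lab)
  expect_equal(seg$periods$kind, "active")
})

test_that("near-rest voltage with sporadic spikes is labelled rest", {
  th <- seg_thresholds(v_rest = -70)
  n <- 300
  mean_v <- rep(-70, n) + rnorm(n, 0, 0.2)
  r <- structure(
    list(t = seq_len(n) - 1, r = rbinom(n, 1, 0.05), delta_t = 1, N = 100),
    class = "rate_series"
  )
  set.seed(2)
  lab <- label_bins(mean_v, r, th)
  expect_true(all(lab$labels == "rest"))
  seg <- segment_periods(lab)
  expect_equal(seg$periods$kind, "quiescent")
  expect_equal(nrow(seg$periods), 1)
  expect_error(label_bins(numeric(5), r, th), "time base")
})

test_that("segments partition the window and short runs are merged", {
  th <- seg_thresholds(v_rest = -70, min_gap = 20)
  n <- 500
  lab_seq <- rep("rest", n)
  lab_seq[101:300] <- rep(c("up", "down"), each = 25, length.out = 200)
  lab_seq[350:355] <- "up" # 6-ms flicker, below min_gap
  mean_v <- c(rest = -70, up = -55, down = -78)[lab_seq]
  r <- structure(
    list(
      t = seq_len(n) - 1,
      r = ifelse(lab_seq == "up", 40, 0), delta_t = 1, N = 100
    ),
    class = "rate_series"
  )
  seg <- segment_periods(label_bins(mean_v, r, th))
  # durations sum to the window length
  expect_equal(sum(seg$periods$end_ms - seg$periods$start_ms), n)
  # the flicker was absorbed: active covers only the genuine block
  act <- seg$periods[seg$periods$kind == "active", ]
  expect_equal(nrow(act), 1)
  expect_equal(act$start_ms, 100)
  expect_equal(act$end_ms, 300)
})

test_that("duration statistics summarise intervals", {
  segs <- structure(
    list(
      periods = data.frame(
        start_ms = c(0, 100, 300, 600),
        end_ms = c(100, 300, 600, 700),
        kind = c("active", "quiescent", "active", "quiescent")
      ),
      states = data.frame(
        start_ms = 0, end_ms = 0,
        kind = character(1)
      ),
      t0 = 0, t_end = 700
    ),
    class = "period_segments"
  )
  # add a third active interval so mean/sd are the worked example
  segs$periods <- rbind(
    segs$periods,
    data.frame(start_ms = 700, end_ms = 900, kind = "active")
  )
  st <- duration_stats(segs, "active")
  expect_equal(sort(st$durations), c(100, 200, 300))
  expect_equal(st$mean, 200)
  expect_equal(st$sd, 100)
  expect_equal(st$se, 100 / sqrt(3))
  # single interval: SE flagged undefined
  st1 <- duration_stats(segs, "quiescent")
  expect_equal(st1$n, 2)
  segs$periods <- segs$periods[2, ]
  st2 <- duration_stats(segs, "quiescent")
  expect_true(st2$single_interval)
  expect_true(is.na(st2$se))
  expect_error(duration_stats(segs, "active"), "no intervals")
})

test_that("voltage histograms report modality", {
  set.seed(3)
  bimodal <- c(rnorm(4000, -76, 1), rnorm(4000, -55, 1.5))
  vh <- voltage_histogram(bimodal)
  expect_equal(vh$n_modes, 2)
  expect_true(vh$median >= min(bimodal) && vh$median <= max(bimodal))
  unimodal <- rnorm(5000, -70, 0.8)
  vh1 <- voltage_histogram(unimodal)
  expect_equal(vh1$n_modes, 1)
  expect_equal(vh1$mode_locations, -70, tolerance = 0.5)
  expect_equal(vh1$mean, mean(unimodal))
  # constant trace: single-bin mass
  expect_equal(voltage_histogram(rep(-65, 100))$n_modes, 1)
  # trimodal synthetic trace
  tri <- make_two_state_voltage(
    levels = c(up = -55, rest = -70, down = -78),
    dwell_means = c(up = 120, rest = 150, down = 100),
    noise_sd = 0.8, T_ms = 30000, seed = 4
  )
  expect_equal(voltage_histogram(tri$mean_v)$n_modes, 3)
})

test_that("segmentation recovers generator dwell times on fixtures", {
  # two-level fixture: recovered mean dwells within 10% across seeds
  rel_err <- function(seed) {
    fx <- make_two_state_voltage(
      levels = c(up = -55, down = -78),
      dwell_means = c(up = 150, down = 100),
      noise_sd = 1, T_ms = 60000, rate_up = 50, seed = seed
    )
    lab <- label_bins(fx$mean_v, fx$rate, seg_thresholds(v_rest = -70))
    true_up <- with(
      fx$true_segments,
      mean((end_ms - start_ms)[kind == "up"])
    )
    got <- as.character(lab$labels)
    # mean run length of the up label
    r <- rle(got)
    got_up <- mean(r$lengths[r$values == "up"])
    abs(got_up - true_up) / true_up
  }
  errs <- vapply(1:20, rel_err, 0)
  expect_lt(mean(errs), 0.1)
  # noiseless fixture: labels match the generator states exactly
  fx0 <- make_two_state_voltage(noise_sd = 0, T_ms = 5000, seed = 3)
  lab0 <- label_bins(fx0$mean_v, fx0$rate, seg_thresholds(v_rest = -70))
  expect_equal(as.character(lab0$labels), fx0$true_states)
})
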