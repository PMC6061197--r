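# Population measures: rate, spectra, spectral entropy, PLV, balance, 1/f^n.

test_that("firing rate converts bin counts to Hz per neuron", {
  ras <- data.frame(
    time_ms = c(rep(0.5, 50), 2.2), neuron_id = c(1:50, 3),
    class_label = "RS"
  )
  r <- firing_rate(ras, N = 1000, t_end = 3)
  expect_equal(r$r[1], 50 / (1000 * 1e-3)) # 50 Hz
  expect_equal(r$r[2], 0)
  # empty raster
  r0 <- firing_rate(ras[0, ], N = 10, t_end = 5)
  expect_true(all(r0$r == 0))
  # every neuron once per bin -> 1/delta_t
  full <- data.frame(
    time_ms = rep(c(0.5, 1.5), each = 10),
    neuron_id = rep(1:10, 2), class_label = "RS"
  )
  expect_equal(firing_rate(full, N = 10, t_end = 2)$r, c(1000, 1000))
  expect_error(firing_rate(ras, N = 10, delta_t = 0), "delta_t")
})

test_that("periodogram satisfies Parseval and known limits", {
  set.seed(3)
  x <- rnorm(1024)
  sp <- power_spectrum(x, kind = "series", demean = FALSE)
  # Parseval: the two-sided sum of S equals delta_t * sum(x^2) in the
  # continuous-signal convention (delta_t in s)
  M <- length(x)
  w <- c(1, rep(2, M / 2 - 1), 1) # DC and Nyquist once, others twice
  expect_equal(sum(w * sp$S), 1e-3 * sum(x^2), tolerance = 1e-6)

  # Poisson train: high-frequency plateau equals the rate (units 1/s)
  set.seed(4)
  nu <- 20
  T_ms <- 60000
  counts <- rpois(T_ms, nu * 1e-3)
  spp <- power_spectrum(counts, kind = "spikes")
  plateau <- mean(spp$S[spp$f > 100])
  expect_equal(plateau, nu, tolerance = 0.1)

  # pure sinusoid: single dominant bin at its frequency
  t <- seq_len(2000)
  v <- sin(2 * pi * 10 * t / 1000)
  spv <- power_spectrum(v, kind = "series")
  expect_equal(spv$f[which.max(spv$S)], 10)
  expect_error(power_spectrum(1), "2 samples")
})

test_that("ensemble averaging is pointwise and shrinks variance", {
  s1 <- power_spectrum(c(0, 2, 0, 2), kind = "series")
  s2 <- power_spectrum(c(2, 0, 2, 0), kind = "series")
  avg <- average_spectrum(list(s1, s2))
  expect_equal(avg$S, (s1$S + s2$S) / 2)
  expect_equal(average_spectrum(list(s1, s1))$S, s1$S)
  s3 <- power_spectrum(c(1, 2, 3), kind = "series")
  expect_error(average_spectrum(list(s1, s3)), "grid")
  # K independent periodograms: variance of the mean shrinks ~ 1/K
  set.seed(9)
  mk <- function() power_spectrum(rnorm(512), kind = "series", demean = FALSE)
  one <- mk()$S
  many <- average_spectrum(lapply(1:50, function(i) mk()))$S
  expect_lt(sd(many) / mean(many), 0.3 * sd(one) / mean(one))
})

test_that("moving average is a centered mean with edge truncation", {
  sp <- power_spectrum(rep(1, 64), kind = "series", demean = FALSE)
  sp$S <- rep(2, length(sp$S))
  expect_equal(moving_average(sp, 20)$S, rep(2, length(sp$S)))
  expect_equal(moving_average(sp, 1)$S, sp$S)
  # an impulse well inside the record spreads into a plateau of 1/window
  sp2 <- power_spectrum(rep(1, 256), kind = "series", demean = FALSE)
  sp2$S <- rep(0, length(sp2$S))
  sp2$S[60] <- 1
  sm <- moving_average(sp2, 20)
  expect_equal(max(sm$S), 1 / 20)
  expect_equal(sum(sm$S > 0), 20)
})

test_that("spectral entropy attains its limits", {
  # broadband: independent Poisson counts -> H_s near 1
  set.seed(5)
  rate <- list(r = rpois(20000, 2), delta_t = 1)
  expect_gt(spectral_entropy(rate)$H_s, 0.95)
  # single frequency -> H_s near 0
  t <- seq_len(20000)
  rate_sin <- list(r = 5 + 5 * sin(2 * pi * 10 * t / 1000), delta_t = 1)
  expect_lt(spectral_entropy(rate_sin)$H_s, 0.05)
  # exactly uniform power: H_s = 1 to machine precision
  H <- -sum(rep(1 / 1000, 1000) * log(rep(1 / 1000, 1000))) / log(1000)
  expect_equal(H, 1, tolerance = 1e-12)
  expect_error(
    spectral_entropy(list(r = numeric(100), delta_t = 1)),
    "all-zero"
  )
})

test_that("concentrating spectral power never increases the entropy", {
  # move power from many bins into one, recomputing the normalized entropy
  p <- rep(1 / 1000, 1000)
  H0 <- -sum(p * log(p)) / log(1000)
  for (frac in c(0.2, 0.5, 0.9)) {
    q <- p * (1 - frac)
    q[1] <- q[1] + frac
    H1 <- -sum(q[q > 0] * log(q[q > 0])) / log(1000)
    expect_lt(H1, H0)
    H0 <- H1
  }
})

test_that("PLV is 1 for identical trains and small for independent ones", {
  ras1 <- make_poisson_raster(1, 8, 2000, seed = 2)
  two <- rbind(ras1, transform(ras1, neuron_id = 2L))
  p <- plv(two, N = 2, K = 1, T_window = 2000, seed = 1)
  expect_equal(p$plv, 1)
  # independent Poisson trains: O(1/sqrt(T)) null
  ras <- make_poisson_raster(120, 30, 2000, seed = 6)
  p0 <- plv(ras, N = 120, K = 60, T_window = 2000, seed = 2)
  expect_lt(p0$plv, 0.1)
  expect_gte(p0$plv, 0)
  expect_error(plv(ras1[0, ], N = 2), "no spikes")
})

test_that("PLV saturates in the number of pairs", {
  net <- study_net(seed = 11)
  sim <- simulate_network(net, synapse_params(D = 1e-5),
    t_end = 2600, seed = 21
  )
  p60 <- plv(sim$raster, sim$N, K = 60, t0 = 500, seed = 3)$plv
  p120 <- plv(sim$raster, sim$N, K = 120, t0 = 500, seed = 3)$plv
  expect_lt(abs(p60 - p120), 0.05)
})

test_that("balance estimate reproduces the LIF-style 4:1 cancellation", {
  expect_equal(balance_estimate(0.15, 1, 8, 2, 0, 0), 0)
  expect_equal(balance_estimate(0.15, 0, 8, 2, 5, 5, v_ref = 0), 0)
  # equal rates and taus, C_ex/C_in = 4: zero net drive at g_in/g_ex = 4
  # (additive convention, where inhibition hyperpolarizes)
  b <- balance_estimate(
    g_ex = 1, g_in = 4, C_ex = 8, C_in = 2, nu_ex = 5, nu_in = 5,
    tau_ex = 5, tau_in = 5, v_ref = -40, E_ex = 0, E_in = -80,
    sign_convention = "additive"
  )
  expect_equal(b, 0)
  # as printed, the second term is subtracted
  expect_equal(
    balance_estimate(1, 1, 1, 1, 1, 1,
      tau_ex = 1, tau_in = 1, v_ref = -65
    ),
    1e-3 * 65 - 1e-3 * (-15)
  )
})

test_that("power-law exponents are recovered from log-log slopes", {
  f <- seq(0, 500, by = 0.5)
  sp <- structure(
    list(f = f, S = c(1, f[-1]^-2), T = 2, delta_t = 1),
    class = "spectrum_est"
  )
  expect_equal(fit_powerlaw(sp), 2, tolerance = 1e-10)
  sp$S <- rep(3, length(f))
  expect_equal(fit_powerlaw(sp), 0, tolerance = 1e-10)
  # noisy synthetic power law
  set.seed(8)
  sp$S <- c(1, 5 * f[-1]^-1.5) * exp(rnorm(length(f), 0, 0.05))
  expect_equal(fit_powerlaw(sp), 1.5, tolerance = 0.1)
  sp$S <- rep(0, length(f))
  expect_error(fit_powerlaw(sp), "in-band")
})
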