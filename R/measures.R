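#' Time-dependent network firing rate
#'
#' Bins the raster at `delta_t` and reports
#' `r(k) = count_k / (N * delta_t)` in Hz (spikes per neuron per second).
#'
#' @param raster data.frame with a `time_ms` column (a `sim_result$raster`
#'   works directly).
#' @param N number of neurons in the network.
#' @param delta_t bin width (ms), default 1.
#' @param t0,t_end analysed window (ms); defaults to `[0, max spike time]`
#'   rounded up to a whole bin.
#' @return an object of class `rate_series`: list with `t` (bin left edges,
#'   ms), `r` (Hz), `delta_t`, `N`.
#' @export
firing_rate <- function(raster, N, delta_t = 1, t0 = 0, t_end = NULL) {
  if (delta_t <= 0) stop("delta_t must be positive")
  times <- raster$time_ms
  if (is.null(t_end)) {
    t_end <- if (length(times)) delta_t * ceiling(max(times) / delta_t) else delta_t
  }
  n_bins <- max(1L, floor((t_end - t0) / delta_t))
  times <- times[times >= t0 & times < t0 + n_bins * delta_t]
  counts <- tabulate(floor((times - t0) / delta_t) + 1L, nbins = n_bins)
  structure(
    list(
      t = t0 + delta_t * (seq_len(n_bins) - 1),
      r = counts / (N * delta_t * 1e-3),
      delta_t = delta_t, N = N
    ),
    class = "rate_series"
  )
}

#' Periodogram power spectrum
#'
#' One-sided periodogram `|FFT|^2 / T` of a uniformly sampled signal. For
#' spike trains binned at 1 ms the units are 1/s (the high-frequency plateau
#' of a Poisson train equals its rate); for voltage traces, mV^2/Hz.
#'
#' @param x numeric signal sampled every `delta_t` ms. For spike-train
#'   spectra pass per-bin spike counts; for voltage spectra, the trace.
#' @param delta_t sampling interval (ms).
#' @param kind `"spikes"` treats `x` as per-bin counts of a delta train
#'   (its Fourier integral is the plain sum over spikes, units 1/s);
#'   `"series"` treats `x` as a sampled continuous signal (the integral
#'   carries a `delta_t` factor; for voltage, units mV^2/Hz).
#' @param demean subtract the mean before transforming (default `TRUE`;
#'   concentrates the DC power of a nonzero-mean signal into the zero bin).
#' @return an object of class `spectrum_est`: list with `f` (Hz, ascending,
#'   starting at 0), `S`, `T` (record length, s), `delta_t`.
#' @export
power_spectrum <- function(x, delta_t = 1, kind = c("spikes", "series"),
                           demean = TRUE) {
  kind <- match.arg(kind)
  M <- length(x)
  if (M < 2) stop("need at least 2 samples")
  if (demean) x <- x - mean(x)
  T_s <- M * delta_t * 1e-3
  X <- fft(x)
  if (kind == "series") X <- X * delta_t * 1e-3
  n_one <- floor(M / 2) + 1L
  S <- Mod(X[seq_len(n_one)])^2 / T_s
  f <- (seq_len(n_one) - 1) / T_s
  structure(
    list(f = f, S = S, T = T_s, delta_t = delta_t),
    class = "spectrum_est"
  )
}

#' Ensemble-averaged spectrum
#'
#' Pointwise mean of spectra computed on identical frequency grids.
#'
#' @param spectra list of [power_spectrum()] results.
#' @return a `spectrum_est` with the averaged power.
#' @export
average_spectrum <- function(spectra) {
  f0 <- spectra[[1]]$f
  for (s in spectra) {
    if (length(s$f) != length(f0) || any(abs(s$f - f0) > 1e-9)) {
      stop("frequency grid mismatch")
    }
  }
  S <- Reduce(`+`, lapply(spectra, `[[`, "S")) / length(spectra)
  structure(
    list(f = f0, S = S, T = spectra[[1]]$T, delta_t = spectra[[1]]$delta_t),
    class = "spectrum_est"
  )
}

#' Centered moving average of a spectrum
#'
#' Running mean over `window` points with edge truncation (the window
#' shrinks near the record ends).
#'
#' @param spec a `spectrum_est`.
#' @param window number of points (default 20).
#' @return a smoothed `spectrum_est`.
#' @export
moving_average <- function(spec, window = 20) {
  stopifnot(window >= 1)
  n <- length(spec$S)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  cs <- cumsum(c(0, spec$S))
  i <- seq_len(n)
  lo <- pmax(1, i - half_lo)
  hi <- pmin(n, i + half_hi)
  spec$S <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  spec
}

#' Spectral entropy of the network firing rate
#'
#' Normalized Shannon entropy of the rate power spectrum on exactly `N_b`
#' one-sided frequency bins:
#' `H_s = -sum_k S(f_k) log S(f_k) / log N_b` with `sum_k S(f_k) = 1`.
#' Broadband (white) rate fluctuations give `H_s ~ 1`; a pure
#' single-frequency oscillation gives `H_s ~ 0`.
#'
#' The rate series is mean-subtracted. When the record provides more than
#' `N_b` raw periodogram bins they are aggregated (averaged) into `N_b`
#' equal-width bins, which also regularizes the chi-squared scatter of the
#' raw periodogram; shorter records are zero-padded to `2 N_b` samples so the
#' one-sided grid has exactly `N_b` bins. Zero-power bins contribute 0.
#'
#' @param rate a [firing_rate()] result (or any list with `r` and `delta_t`).
#' @param N_b number of frequency bins (default 1000).
#' @return list with `H_s` and `N_b`.
#' @export
spectral_entropy <- function(rate, N_b = 1000) {
  r <- rate$r
  if (all(r == 0)) stop("spectral entropy undefined for an all-zero rate")
  x <- r - mean(r)
  M <- length(x)
  if (M < 2 * N_b) {
    x <- c(x, numeric(2 * N_b - M))
  }
  spec <- power_spectrum(x, delta_t = rate$delta_t, demean = FALSE)
  S <- spec$S[-1] # positive-frequency bins (DC is zero after mean removal)
  n_raw <- length(S)
  groups <- floor((seq_len(n_raw) - 1) * N_b / n_raw) + 1
  Sb <- vapply(split(S, groups), mean, 0)
  p <- Sb / sum(Sb)
  nz <- p > 0
  H <- -sum(p[nz] * log(p[nz])) / log(N_b)
  list(H_s = H, N_b = N_b)
}

#' Analytic signal via the Fourier transform
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' imaginary part is the Hilbert transform of `x`.
#'
#' @param x real signal.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value of spike-train pairs
#'
#' Synchrony index in `[0, 1]`: for each of `K` randomly drawn neuron pairs,
#' both spike trains are binned at 1 ms over a window of `T_window` ms and
#' converted to instantaneous phases via the analytic signal; the per-pair
#' value is the modulus of the time-averaged phasor of the phase difference
#' `rho_x Phi_x - rho_y Phi_y` (normalized by the number of time samples so
#' it lies in `[0, 1]`), and the result is the mean over pairs. The estimate
#' saturates in `K` for `K >= 50`.
#'
#' By default the binned train enters the analytic-signal construction
#' without mean subtraction. For a sparse train, subtracting the mean leaves
#' a constant negative offset between spikes that dominates the real part of
#' the analytic signal and pins the phase near pi; pairs of independent
#' irregular trains then show a spurious common phase and the null level of
#' the estimator rises to ~0.4 regardless of synchrony. Without the offset
#' the real part is exactly zero between spikes, the discrete Hilbert kernel
#' alternates sign sample to sample, phases decorrelate quickly, and
#' independent trains give the expected `O(1/sqrt(T))` null while identical
#' trains still give exactly 1. The mirror-image caveat applies to *dense*
#' trains (mean rates approaching one spike per bin): there the
#' un-subtracted signal is itself nearly constant and pins the phase near
#' zero, so for high-rate regimes the mean-subtracted variant
#' (`demean = TRUE`) is the meaningful one. Neither construction is
#' uniformly valid across rate regimes; both are exposed.
#'
#' Only neurons with at least `min_spikes` spikes in the window are eligible;
#' pairs are drawn uniformly without replacement under the given seed.
#'
#' @param raster data.frame with `time_ms` and `neuron_id`.
#' @param N number of neurons.
#' @param K number of pairs (default 60).
#' @param T_window window length (ms), default 2000.
#' @param t0 window start (ms), default 0.
#' @param rho_x,rho_y frequency ratios (default 1).
#' @param min_spikes eligibility threshold (default 2).
#' @param demean subtract the train mean before the analytic signal
#'   (default `FALSE`; see Details).
#' @param seed seed for the pair draw.
#' @return list with `plv`, `K`, `T_window`, `n_eligible`.
#' @export
plv <- function(raster, N, K = 60, T_window = 2000, t0 = 0,
                rho_x = 1, rho_y = 1, min_spikes = 2, demean = FALSE,
                seed = 1L) {
  sel <- raster$time_ms >= t0 & raster$time_ms < t0 + T_window
  times <- raster$time_ms[sel]
  ids <- raster$neuron_id[sel]
  if (!length(times)) stop("no spikes in the PLV window")
  counts <- tabulate(ids, nbins = N)
  eligible <- which(counts >= min_spikes)
  if (length(eligible) < 2) stop("fewer than 2 neurons with enough spikes")

  n_bins <- floor(T_window)
  bin_of <- floor(times - t0) + 1L
  phases <- new.env(parent = emptyenv())
  phase_of <- function(j) {
    key <- as.character(j)
    ph <- phases[[key]]
    if (is.null(ph)) {
      x <- tabulate(bin_of[ids == j], nbins = n_bins)
      if (demean) x <- x - mean(x)
      ph <- Arg(analytic_signal(x))
      phases[[key]] <- ph
    }
    ph
  }

  with_seed(seed, {
    n_el <- length(eligible)
    n_pairs_avail <- n_el * (n_el - 1) / 2
    K_use <- min(K, n_pairs_avail)
    # draw K distinct unordered pairs via linear indices into the lower
    # triangle: q -> (i, j) with i < j
    pair_idx <- sample.int(n_pairs_avail, K_use)
    vals <- vapply(pair_idx, function(q) {
      j <- ceiling((1 + sqrt(1 + 8 * q)) / 2)
      i <- q - (j - 1) * (j - 2) / 2
      dphi <- rho_x * phase_of(eligible[i]) - rho_y * phase_of(eligible[j])
      Mod(mean(exp(1i * dphi)))
    }, 0)
    list(
      plv = mean(vals), K = K_use, T_window = T_window,
      n_eligible = length(eligible)
    )
  })
}

#' Mean synaptic input balance estimate
#'
#' Rough mean-field estimate of the time-averaged synaptic input to a neuron
#' receiving `C_ex` excitatory and `C_in` inhibitory inputs firing at mean
#' rates `nu_ex`, `nu_in` (Hz), at a representative voltage `v_ref`:
#' `I ~ g_ex C_ex nu_ex tau_ex (E_ex - v_ref) - g_in C_in nu_in tau_in
#' (E_in - v_ref)`.
#'
#' The formula is evaluated exactly as printed, with the second term
#' subtracted (`sign_convention = "as_printed"`). Since `E_in < v_ref` in the
#' regimes of interest, the printed minus sign makes the inhibitory term add
#' positive current; `sign_convention = "additive"` sums the two conductance
#' terms instead, which treats inhibition as hyperpolarizing.
#'
#' @param g_ex,g_in conductance increments.
#' @param C_ex,C_in input counts.
#' @param nu_ex,nu_in population mean rates (Hz).
#' @param tau_ex,tau_in decay constants (ms).
#' @param E_ex,E_in reversal potentials (mV).
#' @param v_ref representative voltage (mV).
#' @param sign_convention `"as_printed"` or `"additive"`.
#' @return the estimated mean input current (model units; rates in Hz and
#'   taus in ms contribute a factor 1e-3 each per spike count, kept as the
#'   product `nu * tau * 1e-3`).
#' @export
balance_estimate <- function(g_ex, g_in, C_ex, C_in, nu_ex, nu_in,
                             tau_ex = 5, tau_in = 6, E_ex = 0, E_in = -80,
                             v_ref = -65,
                             sign_convention = c("as_printed", "additive")) {
  sign_convention <- match.arg(sign_convention)
  term_ex <- g_ex * C_ex * (nu_ex * 1e-3) * tau_ex * (E_ex - v_ref)
  term_in <- g_in * C_in * (nu_in * 1e-3) * tau_in * (E_in - v_ref)
  if (sign_convention == "as_printed") term_ex - term_in else term_ex + term_in
}

#' Power-law exponent of a spectrum
#'
#' Least-squares slope of `log S` versus `log f` over a frequency band,
#' reported as the `1/f^n` exponent `n = -slope`. Intended to be applied to
#' the 20-point moving-average curve.
#'
#' @param spec a `spectrum_est`.
#' @param f_lo,f_hi band limits in Hz (defaults 10 and 200).
#' @return the exponent `n`.
#' @export
fit_powerlaw <- function(spec, f_lo = 10, f_hi = 200) {
  keep <- spec$f >= f_lo & spec$f <= f_hi & spec$S > 0
  if (sum(keep) < 3) stop("fewer than 3 usable in-band points")
  fit <- stats::lm(log(spec$S[keep]) ~ log(spec$f[keep]))
  -unname(stats::coef(fit)[2])
}

#' Per-neuron mean firing rates
#'
#' Spike counts divided by the analysed duration, in Hz.
#'
#' @param raster data.frame with `time_ms`, `neuron_id`.
#' @param N number of neurons.
#' @param t0,t_end analysed window (ms).
#' @return numeric vector of length `N` (Hz).
#' @export
neuron_rates <- function(raster, N, t0, t_end) {
  sel <- raster$time_ms >= t0 & raster$time_ms < t_end
  tabulate(raster$neuron_id[sel], nbins = N) / ((t_end - t0) * 1e-3)
}
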