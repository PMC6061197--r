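#' Synaptic parameter set
#'
#' Conductance-based synapse constants: increments `g_ex`, `g_in` added to
#' the postsynaptic conductances at presynaptic spikes, decay time constants
#' `tau_ex = 5 ms`, `tau_in = 6 ms`, reversal potentials `E_ex = 0 mV`,
#' `E_in = -80 mV`, and the synaptic noise intensity `D` of the
#' Ornstein-Uhlenbeck term driving each conductance.
#'
#' @param g_ex,g_in conductance increments per presynaptic spike.
#' @param tau_ex,tau_in decay time constants (ms), must be positive.
#' @param E_ex,E_in reversal potentials (mV).
#' @param D synaptic noise intensity, `>= 0`.
#' @return an object of class `synapse_params`.
#' @export
synapse_params <- function(g_ex = 0.15, g_in = 1, tau_ex = 5, tau_in = 6,
                           E_ex = 0, E_in = -80, D = 0) {
  stopifnot(tau_ex > 0, tau_in > 0, D >= 0, g_ex >= 0, g_in >= 0)
  structure(
    list(
      g_ex = g_ex, g_in = g_in, tau_ex = tau_ex, tau_in = tau_in,
      E_ex = E_ex, E_in = E_in, D = D
    ),
    class = "synapse_params"
  )
}

#' Synaptic current from a conductance pair
#'
#' `I_syn = G_ex (E_ex - v) + G_in (E_in - v)`.
#'
#' @param v membrane voltage (mV).
#' @param G_ex,G_in excitatory and inhibitory conductances.
#' @param params a [synapse_params()] object.
#' @return the synaptic current (model units).
#' @export
synaptic_current <- function(v, G_ex, G_in, params = synapse_params()) {
  .assert_finite(c(v, G_ex, G_in), "voltage or conductance")
  G_ex * (params$E_ex - v) + G_in * (params$E_in - v)
}

#' One stochastic-Heun step of the conductance dynamics
#'
#' Advances the pair `(G_ex, G_in)` by one step of the linear SDE
#' `dG = -G/tau dt + sqrt(2 D n) dW` (independent Wiener increments per
#' component, shared between predictor and corrector stage), then adds the
#' jump `g * (number of arriving presynaptic spikes)` and reflects at zero.
#' The noise variance of each component scales with that component's
#' in-degree `n`; a component with `n = 0` receives no stochastic term.
#'
#' This is the scalar reference implementation of the update used inside the
#' compiled network integrator; it is exposed so the conductance model can be
#' tested and inspected on its own.
#'
#' @param G_ex,G_in current conductances (`>= 0`).
#' @param dt step (ms), positive.
#' @param n_ex,n_in excitatory and inhibitory in-degrees (noise scaling).
#' @param spikes_ex,spikes_in number of presynaptic spikes arriving this step.
#' @param params a [synapse_params()] object.
#' @param reflect reflect at zero after the update (default `TRUE`).
#' @return named numeric vector `c(G_ex, G_in)`.
#' @export
conductance_step <- function(G_ex, G_in, dt, n_ex, n_in,
                             spikes_ex = 0, spikes_in = 0,
                             params = synapse_params(), reflect = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  stopifnot(n_ex >= 0, n_in >= 0, spikes_ex >= 0, spikes_in >= 0)
  step1 <- function(G, tau, n, g, k) {
    dW <- if (params$D > 0 && n > 0) {
      sqrt(2 * params$D * n) * sqrt(dt) * rnorm(1)
    } else {
      0
    }
    Gp <- G + dt * (-G / tau) + dW
    G <- G + 0.5 * dt * (-G / tau - Gp / tau) + dW
    G <- G + g * k
    if (reflect) G <- abs(G)
    G
  }
  c(
    G_ex = step1(G_ex, params$tau_ex, n_ex, params$g_ex, spikes_ex),
    G_in = step1(G_in, params$tau_in, n_in, params$g_in, spikes_in)
  )
}

#' Stationary statistics of the unreflected conductance noise
#'
#' The Ornstein-Uhlenbeck process `dG = -G/tau dt + sqrt(2 D n) dW` has
#' stationary mean 0 and variance `D n tau`. These closed forms are the
#' reference values for simulation checks; the reflecting boundary used in
#' simulations shifts the mean slightly upward and is not accounted for here.
#'
#' @param D noise intensity.
#' @param tau decay time constant (ms).
#' @param n in-degree scaling the noise variance.
#' @return list with `mean` and `variance`.
#' @export
ou_stationary_stats <- function(D, tau, n = 1) {
  list(mean = 0, variance = D * n * tau)
}
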