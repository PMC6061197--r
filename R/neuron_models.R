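#' @useDynLib updownnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft sd uniroot optimize approx rnorm runif rexp rpois
#'   ks.test quantile median density
#' @importFrom utils read.delim write.table head tail
NULL

# cached class table read from the bundled config
.neuron_class_env <- new.env(parent = emptyenv())

.neuron_class_table <- function() {
  if (is.null(.neuron_class_env$tab)) {
    path <- system.file("extdata", "neuron_classes.yaml", package = "updownnet")
    .neuron_class_env$tab <- yaml::read_yaml(path)
  }
  .neuron_class_env$tab
}

#' Neuron parameter set for an electrophysiological class
#'
#' Returns the dynamical constants of a two-variable neuron model for one of
#' the four electrophysiological classes used throughout the package:
#' regular-spiking (RS) and chattering (CH) excitatory neurons, fast-spiking
#' (FS) and low-threshold-spiking (LTS) inhibitory neurons. The voltage
#' equation constants (`alpha`, `beta`, `gamma`, `v_peak`) are shared by all
#' classes; `(a, b, c, d)` differ per class. Parameter sets are loaded from a
#' bundled plain-text config so they can be inspected and overridden.
#'
#' Units follow the dimensionless Izhikevich convention: `v` in mV, time in
#' ms; currents and the recovery variable `u` are model quantities without
#' physical units.
#'
#' @param class_label one of `"RS"`, `"CH"`, `"FS"`, `"LTS"`.
#' @param model_kind `"izhikevich"` (quadratic voltage equation) or `"adex"`
#'   (exponential voltage equation with leak; the recovery equation, reset
#'   rule and `(a,b,c,d)` are identical to the Izhikevich variant, and the
#'   leak reversal is tied to the reset voltage, `E_L = c`).
#' @return an object of class `neuron_params`.
#' @examples
#' p <- neuron_params("RS")
#' critical_currents(p)
#' @export
neuron_params <- function(class_label = c("RS", "CH", "FS", "LTS"),
                          model_kind = c("izhikevich", "adex")) {
  class_label <- match.arg(class_label)
  model_kind <- match.arg(model_kind)
  tab <- .neuron_class_table()
  cl <- tab$classes[[class_label]]
  p <- c(
    tab$common,
    list(
      a = cl$a, b = cl$b, c = cl$c, d = cl$d,
      class_label = class_label,
      role = cl$role,
      model_kind = model_kind,
      adex_gL = tab$adex$gL,
      adex_DeltaT = tab$adex$DeltaT,
      adex_vT = tab$adex$vT,
      adex_EL = cl$c,
      adex_offset = tab$adex$offset
    )
  )
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "<neuron_params> %s (%s, %s)\n  a=%g b=%g c=%g d=%g | alpha=%g beta=%g gamma=%g v_peak=%g\n",
    x$class_label, x$role, x$model_kind,
    x$a, x$b, x$c, x$d, x$alpha, x$beta, x$gamma, x$v_peak
  ))
  invisible(x)
}

.assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite %s", what), call. = FALSE)
  }
}

#' Instantaneous derivatives of the two-variable neuron model
#'
#' Right-hand side of the coupled voltage/recovery equations. For the
#' Izhikevich kind, `dv/dt = alpha v^2 + beta v + gamma - u + I`; for the
#' AdEx kind, `dv/dt = -gL (v - E_L) + gL DeltaT exp((v - vT)/DeltaT) +
#' offset - u + I`. Both kinds share `du/dt = a (b v - u)`.
#'
#' @param v,u membrane voltage (mV) and recovery variable.
#' @param I input current (model units).
#' @param params a [neuron_params()] object.
#' @return named numeric vector `c(dv_dt, du_dt)`.
#' @export
derivatives <- function(v, u, I, params) {
  .assert_finite(c(v, u, I), "state or current")
  dv <- if (params$model_kind == "izhikevich") {
    params$alpha * v^2 + params$beta * v + params$gamma - u + I
  } else {
    -params$adex_gL * (v - params$adex_EL) +
      params$adex_gL * params$adex_DeltaT *
        exp((v - params$adex_vT) / params$adex_DeltaT) +
      params$adex_offset - u + I
  }
  du <- params$a * (params$b * v - u)
  c(dv_dt = dv, du_dt = du)
}

#' Fire-and-reset rule
#'
#' Applied whenever the voltage reaches the spike cutoff `v_peak`:
#' `v -> c`, `u -> u + d`. Calling it below the cutoff is a contract
#' violation and raises an error.
#'
#' @inheritParams derivatives
#' @return named numeric vector `c(v, u)` after the reset.
#' @export
apply_reset <- function(v, u, params) {
  if (v < params$v_peak) {
    stop("apply_reset() called with v below the spike cutoff v_peak")
  }
  c(v = params$c, u = u + params$d)
}

#' Saddle-node and Andronov-Hopf threshold currents
#'
#' Closed forms for the Izhikevich model. The rest state disappears in a
#' saddle-node bifurcation at `I_sn = (beta - b)^2 / (4 alpha) - gamma`.
#' When `b > a` (true for all four bundled classes) the equilibrium loses
#' stability earlier, in a subcritical Andronov-Hopf bifurcation at
#' `I_H = ((beta - b)^2 - (a - b)^2) / (4 alpha) - gamma`.
#'
#' @param params a [neuron_params()] object of the Izhikevich kind.
#' @return list with elements `I_sn` and `I_H`.
#' @export
critical_currents <- function(params) {
  stopifnot(params$model_kind == "izhikevich")
  bb <- params$beta - params$b
  I_sn <- bb^2 / (4 * params$alpha) - params$gamma
  I_H <- (bb^2 - (params$a - params$b)^2) / (4 * params$alpha) - params$gamma
  list(I_sn = I_sn, I_H = I_H)
}

#' Resting state of a neuron at a constant input current
#'
#' The stable (left) intersection of the voltage nullcline with the recovery
#' nullcline `u = b v`. For the Izhikevich kind this is the left root of
#' `alpha v^2 + (beta - b) v + gamma + I = 0`; above the saddle-node current
#' no rest state exists and `NULL` is returned. For the AdEx kind the root is
#' found numerically by bracketed bisection (tolerance 1e-10 mV).
#'
#' @inheritParams critical_currents
#' @param I constant input current.
#' @return named numeric vector `c(v, u)` or `NULL` when no rest state exists.
#' @export
resting_state <- function(params, I = 0) {
  if (params$model_kind == "izhikevich") {
    A <- params$alpha
    B <- params$beta - params$b
    C <- params$gamma + I
    disc <- B^2 - 4 * A * C
    if (disc < 0) {
      return(NULL)
    }
    v <- (-B - sqrt(disc)) / (2 * A)
    return(c(v = v, u = params$b * v))
  }
  # adex: g(v) = dv/dt with u = b v; stable rest is the left zero of g
  g <- function(v) derivatives(v, params$b * v, I, params)[["dv_dt"]]
  # bracket: start well hyperpolarized, walk up to the minimum of g
  vmin <- optimize(g, c(-120, 0))$minimum
  lo <- -120
  if (g(lo) < 0 || g(vmin) > 0) {
    return(NULL)
  }
  v <- uniroot(g, c(lo, vmin), tol = 1e-10)$root
  c(v = v, u = params$b * v)
}

#' Phase-plane nullclines
#'
#' Samples the voltage nullcline `u_bar(v)` (a parabola for the Izhikevich
#' kind, exponential-plus-leak for AdEx, shifted upward pointwise by the
#' input current `I`) and the recovery nullcline `u_star(v) = b v` on a
#' voltage grid.
#'
#' @inheritParams resting_state
#' @param v_grid monotone numeric grid of voltages (mV).
#' @return list with `v`, `u_bar`, `u_star`, `I_used`.
#' @export
nullclines <- function(params, I = 0, v_grid = seq(-90, -30, by = 0.1)) {
  if (length(v_grid) == 0) stop("empty voltage grid")
  if (is.unsorted(v_grid) && is.unsorted(rev(v_grid))) {
    stop("v_grid must be monotone")
  }
  u_bar <- if (params$model_kind == "izhikevich") {
    params$alpha * v_grid^2 + params$beta * v_grid + params$gamma + I
  } else {
    -params$adex_gL * (v_grid - params$adex_EL) +
      params$adex_gL * params$adex_DeltaT *
        exp((v_grid - params$adex_vT) / params$adex_DeltaT) +
      params$adex_offset + I
  }
  list(v = v_grid, u_bar = u_bar, u_star = params$b * v_grid, I_used = I)
}
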