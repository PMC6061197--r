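# run a block of code under a temporary R RNG seed, restoring the prior state
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Network configuration
#'
#' Describes a sparse directed random network: `N` neurons, each ordered pair
#' connected independently with probability `p` (no self-loops), excitatory
#' and inhibitory subpopulations in proportion `exc_fraction : 1 -
#' exc_fraction` (default 4:1), and a class composition within each
#' subpopulation. With the defaults (`N = 2^10`, `p = 0.01`) the expected
#' in-degree is `p (N - 1) ~ 10`, the sparse regime studied throughout.
#'
#' @param N number of neurons.
#' @param p connection probability, `0 < p < 1`.
#' @param exc_fraction fraction of excitatory neurons (default 0.8).
#' @param exc_classes named fractions of excitatory classes within the
#'   excitatory subpopulation, e.g. `c(RS = 0.8, CH = 0.2)`; must sum to 1.
#' @param inh_classes same for the inhibitory subpopulation, e.g.
#'   `c(LTS = 1)` or `c(FS = 1)`.
#' @param seed RNG seed for wiring and class assignment.
#' @return an object of class `network_config`.
#' @export
network_config <- function(N = 2^10, p = 0.01, exc_fraction = 0.8,
                           exc_classes = c(RS = 1), inh_classes = c(LTS = 1),
                           seed = 1L) {
  stopifnot(N >= 2, p > 0, p < 1, exc_fraction > 0, exc_fraction < 1)
  check_comp <- function(x, roles, role) {
    if (abs(sum(x) - 1) > 1e-8) {
      stop(sprintf("%s class fractions must sum to 1", role))
    }
    tab <- .neuron_class_table()$classes
    for (nm in names(x)) {
      if (is.null(tab[[nm]]) || tab[[nm]]$role != role) {
        stop(sprintf("'%s' is not a bundled %s class", nm, role))
      }
    }
  }
  check_comp(exc_classes, role = "excitatory")
  check_comp(inh_classes, role = "inhibitory")
  structure(
    list(
      N = N, p = p, exc_fraction = exc_fraction,
      exc_classes = exc_classes, inh_classes = inh_classes,
      seed = as.integer(seed)
    ),
    class = "network_config"
  )
}

# deterministic integer counts from fractions (largest-remainder rounding)
.split_counts <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  counts
}

#' Build the random directed connectivity
#'
#' Draws an Erdos-Renyi directed graph (each ordered pair an edge with
#' probability `p`, self-loops excluded), assigns classes by the configured
#' composition with deterministic counts and a seeded shuffle, and tabulates
#' per-neuron excitatory/inhibitory in-degrees (`n_ex`, `n_in`), which scale
#' the synaptic noise variance.
#'
#' @param config a [network_config()] object.
#' @return an object of class `connectivity`: list with `N`, `edges`
#'   (two-column matrix `pre`, `post`, 1-based), `type_of` (per-neuron class
#'   label), `is_exc`, `n_ex`, `n_in`, and the config.
#' @export
build_network <- function(config) {
  with_seed(config$seed, {
    N <- config$N
    n_exc <- round(N * config$exc_fraction)
    n_inh <- N - n_exc
    exc_counts <- .split_counts(n_exc, config$exc_classes)
    inh_counts <- .split_counts(n_inh, config$inh_classes)
    labels <- c(
      rep(names(config$exc_classes), exc_counts),
      rep(names(config$inh_classes), inh_counts)
    )
    labels <- sample(labels) # seeded shuffle of class positions
    tab <- .neuron_class_table()$classes
    is_exc <- vapply(labels, function(l) tab[[l]]$role == "excitatory", TRUE)
    names(is_exc) <- NULL

    # vectorized edge draw over all ordered pairs, self-loops removed
    m <- matrix(runif(N * N) < config$p, N, N)
    diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE) # row = pre, col = post
    edges <- cbind(pre = idx[, 1], post = idx[, 2])

    n_ex <- tabulate(edges[is_exc[edges[, "pre"]], "post"], nbins = N)
    n_in <- tabulate(edges[!is_exc[edges[, "pre"]], "post"], nbins = N)

    structure(
      list(
        N = N, edges = edges, type_of = labels, is_exc = is_exc,
        n_ex = n_ex, n_in = n_in, config = config
      ),
      class = "connectivity"
    )
  })
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf(
    "<connectivity> N=%d, %d edges (mean in-degree %.2f), composition: %s\n",
    x$N, nrow(x$edges), nrow(x$edges) / x$N,
    paste(sprintf("%s=%d", names(table(x$type_of)), table(x$type_of)),
      collapse = " "
    )
  ))
  invisible(x)
}

#' Stimulation protocol
#'
#' A brief constant current `I_stim` applied to a randomly selected fraction
#' of neurons on `[0, t_stim]`; afterwards all external current is zero and
#' the network evolves freely. The protocol grid studied in the deterministic
#' setup spans amplitudes 10-20, durations 50-300 ms and fractions
#' 1, 1/2, 1/4, 1/8, 1/16.
#'
#' @param I_stim stimulation amplitude.
#' @param t_stim stimulation duration (ms).
#' @param fraction stimulated proportion of the network, in
#'   `c(1, 1/2, 1/4, 1/8, 1/16)`.
#' @param target_seed seed for the selection of stimulated neurons.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(I_stim = 15, t_stim = 100, fraction = 1,
                          target_seed = 1L) {
  if (!any(abs(fraction - c(1, 1 / 2, 1 / 4, 1 / 8, 1 / 16)) < 1e-12)) {
    stop("fraction must be one of 1, 1/2, 1/4, 1/8, 1/16")
  }
  structure(
    list(
      I_stim = I_stim, t_stim = t_stim, fraction = fraction,
      target_seed = as.integer(target_seed)
    ),
    class = "stim_protocol"
  )
}

#' Per-neuron stimulation amplitudes for a protocol
#'
#' Selects `floor(N * fraction)` neurons (seeded) and assigns them the
#' constant amplitude `I_stim`; all other neurons get 0. The current is
#' applied on `[0, t_stim]` by the simulator and is zero afterwards.
#'
#' @param protocol a [stim_protocol()] object.
#' @param connectivity a [build_network()] result.
#' @return numeric vector of length `N` of stimulation amplitudes.
#' @export
make_stimulus <- function(protocol, connectivity) {
  N <- connectivity$N
  k <- floor(N * protocol$fraction)
  I <- numeric(N)
  sel <- with_seed(protocol$target_seed, sample.int(N, k))
  I[sel] <- protocol$I_stim
  I
}
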