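# small shared fixtures for the simulation tests

small_net <- function(seed = 1, N = 200, p = 0.05,
                      exc_classes = c(RS = 1), inh_classes = c(LTS = 1)) {
  build_network(network_config(
    N = N, p = p, exc_classes = exc_classes,
    inh_classes = inh_classes, seed = seed
  ))
}

# the composition used in the intermittency study: 16% CH, 64% RS, 20% LTS
study_net <- function(seed = 11) {
  build_network(network_config(
    N = 2^10, p = 0.01,
    exc_classes = c(RS = 0.8, CH = 0.2), inh_classes = c(LTS = 1),
    seed = seed
  ))
}
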