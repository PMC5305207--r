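# Shared fixtures: random cycles/gradients for property-style tests and the
# standard succinate-experiment scenario.

# Random electrogenic transport cycle (1 substrate + 0-3 coupling ions).
rand_cycle <- function() {
  repeat {
    n_ions <- sample(0:3, 1L)
    terms <- list(species_term("S", sample(c(-2, -1, 0, 1), 1L),
                               sample(1:2, 1L), "substrate"))
    for (i in seq_len(n_ions)) {
      terms[[length(terms) + 1L]] <-
        species_term(paste0("ion", i), sample(c(-1, 1, 2), 1L),
                     sample(c(-2, -1, 1, 2, 3), 1L), "coupling_ion")
    }
    cyc <- transport_cycle(terms)
    if (abs(net_charge(cyc)) > 0.5) return(cyc)
  }
}

# Random positive gradients for every species of a cycle (ratios 10^-2..10^2).
rand_gradients <- function(cycle) {
  entries <- lapply(cycle$terms$name, function(nm) {
    c_out <- 10^stats::runif(1L, -4, -1)
    c_in <- c_out * 10^stats::runif(1L, -2, 2)
    c(c_in, c_out)
  })
  names(entries) <- cycle$terms$name
  do.call(gradient_set, entries)
}

# The standard three-voltage succinate scenario used across tests.
succinate_experiment <- function(seed, voltages = c(12, 48, 84), ...) {
  simulate_experiment(voltages, vcindy_cycle(), vcindy_gradients(),
                      params = flux_params(seed = seed, ...))
}

succinate_candidates <- lapply(1:4, function(n) c(n, 1))
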