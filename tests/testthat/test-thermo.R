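# The free-energy oracle: G = slope * sum(nu log10 r) + Q * V, computed
# directly from first principles, independent of reversal_potential().
oracle_free_energy <- function(cycle, gradients, voltage, slope = 60) {
  terms <- cycle$terms
  conc <- gradients$concentrations
  r <- conc$c_in[match(terms$name, conc$name)] /
    conc$c_out[match(terms$name, conc$name)]
  slope * sum(terms$stoichiometry * log10(r)) +
    sum(terms$stoichiometry * terms$valence) * voltage
}

std_grads <- function() vcindy_gradients() # Na 1:4, succinate 10:1

test_that("cycle free energy vanishes with no gradients and at E_rev", {
  flat <- gradient_set(Na = c(0.1, 0.1), succinate = c(1e-6, 1e-6))
  expect_equal(cycle_free_energy(vcindy_cycle(), flat, 0), 0)
  e <- reversal_potential(vcindy_cycle(), std_grads())
  expect_equal(cycle_free_energy(vcindy_cycle(), std_grads(), e), 0,
               tolerance = 1e-9)
  # above E_rev the outward cycle is favoured: G = Q*(V - E_rev) = +35.63
  g84 <- cycle_free_energy(vcindy_cycle(), std_grads(), 84)
  expect_gt(g84, 0)
  expect_equal(g84, 84 - e, tolerance = 1e-12)
})

test_that("the 3:1 succinate cycle reverses at +48 mV under the 1:4 / 10:1 gradients", {
  e <- reversal_potential(vcindy_cycle(), std_grads())
  expect_equal(e, 48.4, tolerance = 0.002)
  expect_equal(round(e), 48)
  flat <- gradient_set(Na = c(0.1, 0.1), succinate = c(1e-6, 1e-6))
  expect_equal(reversal_potential(vcindy_cycle(), flat), 0)
})

test_that("chemical terms of a 1:1 Na/neutral-sugar cycle can cancel exactly", {
  cyc <- transport_cycle(species_term("Na", 1, 1, "coupling_ion"),
                         species_term("galactose", 0, 1, "substrate"))
  g <- gradient_set(Na = c(0.01, 0.1), galactose = c(1e-3, 1e-4))
  expect_equal(reversal_potential(cyc, g), 0, tolerance = 1e-12)
  expect_equal(oracle_free_energy(cyc, g, 0), 0, tolerance = 1e-12)
})

test_that("electroneutral cycles raise instead of returning a voltage", {
  cyc21 <- transport_cycle(species_term("Na", 1, 2, "coupling_ion"),
                           species_term("succinate", -2, 1, "substrate"))
  g <- gradient_set(Na = c(0.025, 0.1), succinate = c(1e-6, 1e-7))
  expect_error(reversal_potential(cyc21, g), "electroneutral")
  expect_error(reversal_potential_eq1(2, 1, 0.25, 10), "electroneutral")
  expect_error(reversal_potential_eq1(4, 2, 0.25, 10), "electroneutral")
})

test_that("the divalent-anion closed form matches the general engine", {
  expect_equal(reversal_potential_eq1(3, 1, 0.25, 10), 48.3708,
               tolerance = 1e-4)
  expect_equal(reversal_potential_eq1(1, 1, 1, 1), 0)
  # frozen from the general-cycle oracle
  cyc <- transport_cycle(species_term("Na", 1, 1, "coupling_ion"),
                         species_term("S", -2, 1, "substrate"))
  g <- gradient_set(Na = c(0.4, 0.1), S = c(1e-5, 1e-4))
  expect_equal(reversal_potential_eq1(1, 1, 4, 0.1),
               reversal_potential(cyc, g))
  expect_equal(reversal_potential_eq1(1, 1, 4, 0.1), -23.8764,
               tolerance = 1e-4)
})

test_that("the neutral-substrate closed form matches the general engine", {
  expect_equal(reversal_potential_neutral_substrate(1, 1, 1, 1), 0)
  expect_equal(reversal_potential_neutral_substrate(1, 1, 0.1, 10), 0)
  expect_equal(reversal_potential_neutral_substrate(2, 1, 1, 100), -60)
  cyc <- transport_cycle(species_term("Na", 1, 2, "coupling_ion"),
                         species_term("G", 0, 1, "substrate"))
  g <- gradient_set(Na = c(0.1, 0.1), G = c(1e-2, 1e-4))
  expect_equal(reversal_potential_neutral_substrate(2, 1, 1, 100),
               reversal_potential(cyc, g))
})

test_that("Nernst potentials follow the -slope/z log10 ratio form", {
  expect_equal(nernst_potential(+1, 1), 0)
  expect_equal(nernst_potential(+1, 0.1), 60)
  expect_equal(nernst_potential(+2, 10), -30)
  expect_error(nernst_potential(0, 1), "nonzero")
})

test_that("equilibrium substrate ratios satisfy the zero-free-energy oracle", {
  # no ion gradient, no voltage: no concentrating power
  expect_equal(equilibrium_substrate_ratio(
    vcindy_cycle(), gradient_set(Na = c(0.1, 0.1)), 0), 1)
  # a 1:1000 inward Na+ gradient through a 3:1 cycle holds a 10^9 substrate
  # gradient at 0 mV (three ions, three decades each)
  r <- equilibrium_substrate_ratio(
    vcindy_cycle(), gradient_set(Na = c(1e-4, 0.1)), 0)
  expect_equal(r, 1e9, tolerance = 1e-9)
  full <- gradient_set(Na = c(1e-4, 0.1), succinate = c(r * 1e-9, 1e-9))
  expect_equal(oracle_free_energy(vcindy_cycle(), full, 0), 0,
               tolerance = 1e-9)
  # 3 Na+ : 1 monovalent anion, tenfold inward Na+, -60 mV
  cyc <- transport_cycle(species_term("Na", 1, 3, "coupling_ion"),
                         species_term("A", -1, 1, "substrate"))
  r2 <- equilibrium_substrate_ratio(cyc, gradient_set(Na = c(0.01, 0.1)), -60)
  expect_equal(r2, 1e5, tolerance = 1e-9)
  full2 <- gradient_set(Na = c(0.01, 0.1), A = c(r2 * 1e-9, 1e-9))
  expect_equal(oracle_free_energy(cyc, full2, -60), 0, tolerance = 1e-9)
  expect_error(equilibrium_substrate_ratio(
    vcindy_cycle(), gradient_set(K = c(0.1, 0.1)), 0), "Na")
})

test_that("static-head ion gradients balance the substrate gradient at 0 mV", {
  expect_equal(static_head_ion_gradient(1, 1), 1)
  # oracle check: put the returned ion ratio and the substrate ratio in a
  # cycle with the matching stoichiometry and confirm zero free energy
  for (case in list(c(3, 10), c(2, 5), c(1.5, 7))) {
    n_over_m <- case[1]; r_s <- case[2]
    r_ion <- static_head_ion_gradient(n_over_m, r_s)
    cyc <- transport_cycle(
      species_term("Na", 1, n_over_m, "coupling_ion"),
      species_term("S", 0, 1, "substrate"))
    g <- gradient_set(Na = c(r_ion * 0.1, 0.1), S = c(r_s * 1e-6, 1e-6))
    expect_equal(oracle_free_energy(cyc, g, 0), 0, tolerance = 1e-9)
  }
  expect_equal(static_head_ion_gradient(3, 10), 10^(-1 / 3), tolerance = 1e-12)
  expect_equal(static_head_ion_gradient(2, 5), 5^(-1 / 2), tolerance = 1e-12)
})

test_that("flux direction follows the sign of the cycle free energy", {
  expect_equal(flux_direction(vcindy_cycle(), std_grads(), 12), "influx")
  expect_equal(flux_direction(vcindy_cycle(), std_grads(), 84), "efflux")
  e <- reversal_potential(vcindy_cycle(), std_grads())
  expect_equal(flux_direction(vcindy_cycle(), std_grads(), e), "equilibrium")
})

test_that("free energy vanishes at the reversal potential for random cycles", {
  set.seed(42)
  for (i in 1:50) {
    cyc <- rand_cycle()
    g <- rand_gradients(cyc)
    e <- reversal_potential(cyc, g)
    expect_true(is.finite(e))
    expect_equal(cycle_free_energy(cyc, g, e), 0, tolerance = 1e-9)
    expect_equal(oracle_free_energy(cyc, g, e), 0, tolerance = 1e-9)
  }
})

test_that("swapping inside and outside negates the reversal potential", {
  set.seed(43)
  for (i in 1:25) {
    cyc <- rand_cycle()
    g <- rand_gradients(cyc)
    conc <- g$concentrations
    entries <- lapply(seq_len(nrow(conc)), function(k) c(conc$c_out[k], conc$c_in[k]))
    names(entries) <- conc$name
    g_swapped <- do.call(gradient_set, entries)
    expect_equal(reversal_potential(cyc, g_swapped),
                 -reversal_potential(cyc, g), tolerance = 1e-9)
  }
})

test_that("scaling one species on both sides leaves E_rev unchanged", {
  set.seed(44)
  for (i in 1:25) {
    cyc <- rand_cycle()
    g <- rand_gradients(cyc)
    conc <- g$concentrations
    k <- sample(nrow(conc), 1L)
    fac <- 10^stats::runif(1L, -2, 2)
    entries <- lapply(seq_len(nrow(conc)), function(j) {
      s <- if (j == k) fac else 1
      c(conc$c_in[j] * s, conc$c_out[j] * s)
    })
    names(entries) <- conc$name
    expect_equal(reversal_potential(cyc, do.call(gradient_set, entries)),
                 reversal_potential(cyc, g), tolerance = 1e-9)
  }
})

test_that("closed forms reduce the general engine over random ratios", {
  set.seed(45)
  for (i in 1:25) {
    n <- sample(1:5, 1L); m <- sample(1:3, 1L)
    r_na <- 10^stats::runif(1L, -2, 2); r_s <- 10^stats::runif(1L, -2, 2)
    g <- gradient_set(Na = c(r_na * 0.01, 0.01), S = c(r_s * 1e-6, 1e-6))
    if (abs(n / m - 2) > 1e-9) {
      cyc <- transport_cycle(species_term("Na", 1, n, "coupling_ion"),
                             species_term("S", -2, m, "substrate"))
      expect_equal(reversal_potential_eq1(n, m, r_na, r_s),
                   reversal_potential(cyc, g), tolerance = 1e-9)
    }
    cyc0 <- transport_cycle(species_term("Na", 1, n, "coupling_ion"),
                            species_term("S", 0, m, "substrate"))
    expect_equal(reversal_potential_neutral_substrate(n, m, r_na, r_s),
                 reversal_potential(cyc0, g), tolerance = 1e-9)
  }
})

test_that("for a positively charged cycle flux is inward below E_rev, outward above", {
  set.seed(46)
  for (i in 1:20) {
    cyc <- rand_cycle()
    if (net_charge(cyc) < 0) next
    g <- rand_gradients(cyc)
    e <- reversal_potential(cyc, g)
    for (dv in c(1, 10, 100)) {
      expect_equal(flux_direction(cyc, g, e - dv), "influx")
      expect_equal(flux_direction(cyc, g, e + dv), "efflux")
    }
  }
})
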