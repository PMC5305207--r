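---
title: "Determining transporter coupling stoichiometry from reversal potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining transporter coupling stoichiometry from reversal potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revpot)
```

## The model

A secondary active transporter with fixed stoichiometry moves a defined set
of species across the membrane each cycle: `n` coupling ions and `m`
substrate molecules for a symporter, with counter-transported species
entering with negative stoichiometric coefficients. At equilibrium the
electrochemical potential changes sum to zero over the cycle,

$$\sum_i \nu_i \,\Delta\mu_i \;=\; 0, \qquad
  \Delta\mu_i \;=\; RT\,\ln\frac{[c_i]_{in}}{[c_i]_{out}} + z_i F \,\Delta\Psi ,$$

with the membrane voltage defined as $\Delta\Psi = \Psi_{in} - \Psi_{out}$
(outside is ground). Dividing by $F$, converting to base-10 logarithms and
writing $Q = \sum_i \nu_i z_i$ for the net charge moved per cycle gives the
per-cycle free energy in "mV-equivalents" used throughout the package,

$$G \;=\; s \sum_i \nu_i \log_{10} r_i \;+\; Q\,\Delta\Psi,
  \qquad r_i = \frac{[c_i]_{in}}{[c_i]_{out}},$$

where $s$ is the Nernstian slope in mV per decade. $G<0$ drives the inward
cycle (influx), $G>0$ the outward cycle, and $G=0$ defines the reversal
potential

$$E_{rev} \;=\; -\frac{s}{Q} \sum_i \nu_i \log_{10} r_i ,$$

which exists only for electrogenic cycles ($Q \neq 0$); electroneutral
cycles raise an error everywhere in the package rather than returning a
number. For an $n\,\mathrm{Na}^+ : m\,\mathrm{S}^{2-}$ symporter this
reduces to the familiar closed form with denominator $n/m - 2$
(`reversal_potential_eq1()`), and for a neutral substrate to the form where
all transported charge rides on the ions
(`reversal_potential_neutral_substrate()`); both reductions are enforced by
property tests against the general engine.

Because $E_{rev}$ depends only on gradients, charges and $\nu_i$ — not on
any kinetic mechanism — observing the voltage at which net tracer flux
vanishes, bracketed by influx below and efflux above, identifies the
stoichiometric ratio directly.

### Conventions and assumptions

* **Slope fixed at exactly 60 mV/decade.** The method's printed design
  voltages (+48, 0/62/47, −42 …) are all computed with the round-number
  Nernstian slope; a strict $RT\ln 10/F$ at 25 °C (59.16 mV) would shift
  every predicted voltage by ~1.4 % and reproduce none of them. Temperature
  is therefore not a parameter; the slope can be overridden per call.
* **Ideal solutions.** Activities are taken equal to concentrations; no
  ionic-strength correction is applied, matching how such experiments are
  designed and analysed in practice.
* **Sign conventions.** Voltage is inside minus outside. An "inwardly
  directed" gradient of a species means higher concentration outside
  ($r<1$). ΔCPM is initial minus later counts, so *positive* ΔCPM means
  counts were lost (efflux) — the voltage–ΔCPM curve then rises through zero
  at $E_{rev}$ for $Q>0$, like an I–V relation.
* **Counter-transport** is encoded as $\nu_i < 0$; the equilibrium condition
  extends unchanged, which is how the glutamate-transporter-style cycle
  (`eaat3_cycle()`: 3 Na⁺ + 1 H⁺ in, 1 K⁺ out, glutamate⁻) is handled.

### A note on the static-head rearrangement

At $\Delta\Psi = 0$ the equilibrium condition for an $n{:}m$ cycle reads
$n \log_{10} r_{ion} + m \log_{10} r_S = 0$. Two rearrangements circulate in
the transport literature, differing in whether the ion gradient balancing a
substrate gradient carries the exponent $m/n$ or its inverse, and they are
easy to confuse. Only

$$r_{ion} = r_S^{-m/n}$$

satisfies the free-energy condition: the more ions coupled per substrate,
the *smaller* the opposing ion gradient needed (each substrate molecule
draws on $n/m$ ion translocations). Its inverse is the equally familiar
accumulation relation $r_S^{max} = (1/r_{ion})^{n/m}$ — a modest ion
gradient is amplified to a large substrate gradient. With three ions per
substrate, a tenfold outward substrate gradient is balanced by a mere
1:2.15 inward ion gradient, while a 1:1000 inward ion gradient would hold a
$10^9$-fold substrate gradient. `static_head_ion_gradient()` implements the
thermodynamically consistent form, and every equilibrium helper in the
package — including this one — is tested against the same zero-free-energy
oracle, so the relations cannot drift apart.

```{r static-head}
static_head_ion_gradient(3, 10)        # 1:2.15, not 1:1000
equilibrium_substrate_ratio(vcindy_cycle(),
                            gradient_set(Na = c(1e-4, 0.1)), voltage = 0)
```

The same machinery gives the textbook sanity check for a mammalian
glutamate-transporter cycle: with [Na⁺] 12/145 mM, [K⁺] 140/4 mM, pH
7.2/7.4 and −70 mV, the predicted accumulation ratio is ≈ 8 × 10⁶ —
million-fold concentrating power from physiological gradients.

## Designing an experiment

`predict_candidate_potentials()` evaluates each candidate $n{:}m$ under one
gradient set, flagging electroneutral candidates rather than dropping them
(they predict *no* finite reversal potential and can only ever be refuted).
`solve_gradients_for_targets()` inverts the closed form: choosing two
candidates and two target voltages yields a 2×2 linear system in
$\log_{10} r_{Na}$ and $\log_{10} r_S$, so gradients can be designed to
spread the candidate predictions apart. `check_separability()` enforces a
minimum pairwise separation, 15 mV by default — chosen because the
K⁺/valinomycin "chemical patch clamp" is coarse, and the closest candidate
pair a careful design should still resolve sits roughly 15 mV apart.

Voltages are set chemically: valinomycin makes the membrane K⁺-selective,
so the voltage sits at the potassium Nernst potential and
`potassium_for_voltage()` gives the external K⁺ for a target clamp
($k_{out} = k_{in} \cdot 10^{V/s}$). All solutions are osmotically balanced
with choline chloride under ideal van 't Hoff counting
(`balance_osmolarity()`; two particles per monovalent salt, configurable per
salt since real osmotic coefficients are solute-specific). Reported clamp
voltages are rounded to the nearest integer mV (halves away from zero) for
human-readable output; unrounded values are kept internally.

## The synthetic-data generator

`simulate_experiment()` emulates the data a proteoliposome tracer assay
produces, not the microscopic mechanism:

* **Flux law.** The population-mean internal substrate concentration obeys
  $$\frac{d[S]_{in}}{dt} = -k\,\sigma\,(1 - e^{-G/s}) - \lambda(t)\,[S]_{in},$$
  with $G$ recomputed along the trajectory as $[S]_{in}$ evolves (ion
  gradients and external substrate are clamped by the effectively infinite
  external volume). Only the equilibrium point and the flux signs are
  physically constrained; any law vanishing at $G=0$ with the sign of $-G$
  would do, and this near-equilibrium thermodynamic form is smooth, bounded
  for efflux, and exactly stationary at $E_{rev}$. The turnover scale
  $k$ (`rate_scale`, mol L⁻¹ s⁻¹, default 5×10⁻⁹) is set so that a course
  at ±36 mV from $E_{rev}$ changes by tens of percent over a two-minute
  assay, matching the dynamic range such experiments are run in. An
  optional saturation factor $\sigma = S_{cis}/(S_{cis}+K_m)$ uses the
  donor-side substrate concentration.
* **Leak.** A first-order loss $\lambda(t)$ on internal substrate switches
  on at `leak_onset` (default 30 s), representing the protein-mediated,
  late-developing leak seen at negative potentials; it is off by default
  and absent from protein-free controls (`rate_scale = 0, leak_rate = 0`
  gives flat trajectories). The ODE is integrated piecewise on either side
  of the onset so the solver never steps across the discontinuity.
* **Counting.** CPM = moles × specific activity × 2.22×10¹² dpm/Ci ×
  counting efficiency, over the population's total internal volume
  (10¹⁰ vesicles of 400 nm, the extrusion pore size — the true internal
  diameter is not knowable from the assay). Defaults describe 1 µM
  tritiated substrate at 60 Ci/mmol counted at 30 % efficiency, giving
  t = 0 levels around 13,000 CPM; carbon-14 work would use ≈0.055 Ci/mmol
  at 90 %. Replicate values are independent Poisson draws around the
  expected CPM.
* **Baseline jitter.** A per-course lognormal scale factor (mean 1, CV
  `baseline_jitter_cv`) reproduces the between-voltage variation in
  recovered counts that motivates early-timepoint normalization; it is 0 by
  default because the succinate-style assays show little of it.
* **Occupancy.** At 1 µM in a 400 nm vesicle the expected occupancy is
  ≈ 20 molecules (`expected_molecules_per_vesicle()`), so per-vesicle
  content is strongly Poisson; the generator works at the population mean,
  which is accurate because ~10¹⁰ vesicles are averaged on every filter.

What the generator deliberately does **not** emulate: alternating-access
kinetics, binding order, per-vesicle stochastic trajectories, filter-binding
artifacts, or rundown of the clamped gradients. Passing the recovery tests
therefore shows the *analysis pipeline* is sound under the stated noise
model, not that any particular mechanistic kinetic model fits real data.

## Inference

`fit_stoichiometry()` chains four steps, each exported on its own:

1. **Normalization** (optional): divide each course by its replicate-mean
   CPM at 5 s. Division (not subtraction) is used because the jitter it
   corrects is a recovery *scale* factor; a subtraction variant would not
   leave relative trajectories identical. Direction calls are provably
   invariant under this rescaling.
2. **Flux calls**: an OLS line through CPM vs time, pooled over replicates,
   tested two-sided at α = 0.05. Flux assays are traditionally judged by
   eye; the slope test is the minimal statistical formalization, and at
   ~13,000 counts Poisson noise is near-Gaussian and homoskedastic, so the
   t-test is well calibrated (verified on 1000 null simulations). When a
   leak is flagged, the window is restricted to ≤ 30 s, before the leak
   contributes.
3. **Reversal-potential estimate**: a no-flux call bracketed by
   opposite-direction calls gives the point estimate at that voltage;
   otherwise the zero crossing of mean ΔCPM is interpolated linearly
   between adjacent voltages; the bracket is always the nearest flux call
   on either side. Estimation refuses to run on one-sided data — without
   both influx and efflux, absence of flux cannot be distinguished from
   absence of transporter.
4. **Assignment/exclusion**: candidates whose prediction coincides (within
   10 mV) with a voltage where flux was decisively observed are excluded;
   among survivors the prediction nearest the estimate, and within 10 mV of
   it, is assigned. The 10 mV tolerance sits between the clamp's rounding
   error and the 15 mV design separation. "Unassigned" is a valid outcome.

**Two evidence thresholds.** Detection and exclusion are deliberately not
symmetric. A no-flux call is a *failure to reject* at α = 0.05; excluding a
candidate stoichiometry is a *positive claim* that flux occurred at its
predicted reversal potential, and is required to clear p < 0.01
(`exclusion_alpha`). With a single threshold, a run whose no-flux voltage
fluctuates to marginal significance (probability ≈ α by construction, since
that course carries no signal) would exclude the true candidate and void
the run; demanding decisive evidence for exclusion keeps the end-to-end
recovery rate at ≈ 1 − 0.01 rather than ≈ 1 − 0.05, without touching the
calibration of the detection test. Calls constructed by hand without
p-values are taken at face value.

### Numerical choices

* Equilibrium tolerance for `flux_direction()`: |G| < 10⁻⁶ mV-equivalents.
* The free-energy exponential is clamped at ±600 mV-equivalents to guard
  the integrator near substrate depletion; concentrations are clipped at
  zero with a warning if the solver ever overshoots.
* `solve_gradients_for_targets()` rejects systems with |det| < 10⁻¹⁰
  (proportional candidate rows constrain the same gradient combination).
* Ties in the nearest-candidate rule resolve to the first (smallest-n)
  candidate; in practice the 15 mV design separation makes ties
  unconstructable.

## Verification scale

The test suite exercises the oracle property ($G = 0$ at the computed
$E_{rev}$, to 10⁻⁹) over dozens of randomly generated multi-species cycles;
antisymmetry and scale invariance of $E_{rev}$; reduction of both closed
forms to the general engine; end-to-end recovery of the 3:1 assignment over
100 seeded triplicate experiments at 12/48/84 mV (with 1:1 never assigned);
and type-I calibration of the flux test on 1000 equilibrium courses. These
sizes keep the full suite under half a minute while leaving Monte-Carlo
margins wide relative to the thresholds tested.

## Known limitations

* The method itself applies only to electrogenic transporters, and the
  K⁺/valinomycin clamp assumes the transporter does not itself couple K⁺.
* The generator's flux law is phenomenological; rate-related quantities
  (slopes, ΔCPM magnitudes) are meaningful only relative to its parameters.
* The inference stage assumes the voltage is held throughout the assay;
  clamp rundown would bias the estimate toward later-time behaviour.
* Buffer tables produced by `design_experiment()` use ideal osmotic
  counting and are schema-complete rather than validated against any
  published composition table.
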