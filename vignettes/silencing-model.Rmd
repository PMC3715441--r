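---
title: "A five-state nucleosome model of budding-yeast epigenetic silencing"
author: "sirspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A five-state nucleosome model of budding-yeast epigenetic silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sirspread)
```

# The model

`sirspread` simulates silencing at a telomere-proximal chromatin
segment as a one-dimensional lattice of nucleosomes, each in exactly
one of five states: Sir-complex bound (`S`), unmodified (`U`),
H4K16-acetylated (`A`), H3K79-methylated (`M`), or doubly marked and
transcriptionally active (`E`). The state space encodes the two known
anti-silencing marks explicitly: acetylation (written by Sas2) and
methylation (written by Dot1) occupy different histone residues, so a
nucleosome can carry both — that combination is the active state `E`.

All rates are measured in units of a uniform mark-loss rate
(`lambda_loss = 1`), which lumps histone turnover, replication dilution
and other cell-cycle perturbations into a single continuous decay of
every mark back to `U`. The reaction channels
(`canonical_reaction_set()`) are:

| channel | rate | notes |
|---|---|---|
| `U -> S` | `alpha_sir_basal` | basal Sir binding, titrated |
| `U -> S` | `delta_sir_coop` x local S density | silencing polymerization, titrated |
| `U -> A`, `M -> E` | `gamma_sas2` | Sas2 acetylation |
| `U -> M`, `A -> E` | `beta0_dot1_basal` | basal Dot1 methylation |
| `U -> M`, `A -> E` | `beta_dot1_coop` x local E density | transcriptional feedback |
| `A -> U`, `E -> M` | `eta_sir2_coop` x local S density | Sir2 deacetylation |
| `S, A, M, E -> U` | 1 | mark loss |

Structural assumptions, made once and used consistently:

* **Sir binds only unmodified nucleosomes.** Both anti-silencing marks
  (and their combination) block Sir binding, so every path into `S`
  starts at `U`.
* **Sir2 removes the acetyl mark only**: `A -> U` and `E -> M`. The
  methyl mark is untouched by deacetylation.
* **The transcriptional feedback is driven by `E` neighbors only**,
  because only the doubly marked state is taken to be transcribing;
  methylation alone does not recruit more Dot1 activity.
* **Loss is single-step**: an `E` nucleosome decays directly to `U`
  without passing through `A` or `M`.
* **Sas2 uses one acetylation rate** for `U -> A` and `M -> E`.

Cooperative channels sense an exponentially weighted neighborhood
(`neighborhood_spec()`): weights proportional to
`exp(-|offset| / decay_length)` over `half_width` nucleosomes per side,
excluding the focal site (a nucleosome does not catalyze its own
transition), truncated and renormalized at the segment ends (the
lattice is a chromosome arm, not a ring). The defaults `half_width = 5`,
`decay_length = 2` model the polymer contact range of chromatin; they
set the unit of every correlation length the package reports, and only
trends — never absolute lengths — should be read off.

## Titration

The Sir pool is finite: with `n_total` copies and nuclear volume `v`,
the ambient density is `rho_free = (n_total - n_bound) / v`, and both
Sir-binding rates are multiplied by `rho_free / rho_ref`. Spreading
silencing binds Sir, depletes the pool, and slows further spreading — a
negative feedback that, in a bistable regime, parks the silencing front
where its velocity vanishes (the zero-velocity line). The bookkeeping
is exact integer arithmetic (`update_titration()`, tested for zero
drift over a million bind/unbind pairs); binding propensities vanish
identically when the pool is exhausted.

# Mean-field analysis

In the well-mixed limit every local density is replaced by the global
state probability, giving a smooth polynomial flow on the 4-simplex
(`meanfield_rhs()`). Fixed points are found by damped Newton iteration
on the reduced four-dimensional system (`p_u` eliminated) with the
analytic Jacobian, from 26 starts: the five pure-state corners, the
barycenter and twenty random simplex points. Roots are deduplicated at
sup-norm 1e-6, accepted only with residual below 1e-10 inside the
simplex, and classified by the largest real part of the reduced
Jacobian's eigenvalues (stable below -1e-8; roots within 1e-8 of zero
are flagged marginal and excluded from phase labels, since they sit on
a bifurcation boundary). The Newton engine is compiled; a hand-expanded
RHS/Jacobian is verified against the generic channel-assembled one in
the tests, and forward `deSolve` integration provides an independent
cross-check that random initial conditions relax onto reported stable
roots.

Labels follow occupancy: *silenced* if `p_s >= 0.5` with `p_e < 0.2`,
*active* symmetric, *bivalent* if both `p_s` and `p_e` exceed 0.2, else
*intermediate* (weight spread over `U`, `A`, `M`). The 0.5/0.2
thresholds translate "predominant" versus "co-occurring" occupancy;
they are configurable and recorded in every scan's metadata. Near the
dot1-null regime the weak silenced branch can sit just below 0.5 and
two stable roots both read "intermediate"; the phase class is then
`other` rather than a bistable label — the thresholds are deliberately
not tuned around this.

A coarse scan of the four cooperative rates over `[0, 10]^4` with small
basal rates (0.01) exhibits exactly four stable-state classes and both
bistability types (silenced-active and silenced-intermediate); this is
an acceptance-level regression. `critical_dot1_rate()` locates the
boundary between the two bistable types: with zero basal rates the
label of the non-silenced stable branch is a sharp step in
`beta_dot1_coop` (located by bisection); with positive basal rates the
step smooths into a crossover and the function reports the ambiguous
window instead.

# Lattice simulation

`run_gillespie()` executes the direct stochastic simulation algorithm
on the lattice: one reaction per event, chosen with probability
proportional to its propensity; exponential waiting times are recorded
but the sampling schedule is event-indexed (samples every
`sample_every` events after `burn_in`), matching the long-standing
convention for this class of models. The compiled core caches per-site
local densities and propensities and updates only the neighborhood of
each executed event; a full cache rebuild every 1e5 events removes
floating-point drift, and the tests check that a run crossing a rebuild
is bit-identical to one that does not. The first ten and last ten
nucleosomes are pinned to `S` and `E` respectively, mimicking the
telomeric nucleation center and a robustly active flank; pinned sites
exert cooperative influence and pinned `S` counts against the Sir pool.
Runs are bit-reproducible from the seed. A lattice whose total
propensity reaches zero is reported with a frozen flag and the
remaining scheduled samples repeat the frozen configuration.

Event-indexed sampling has one statistical subtlety: time averages
require weighting by waiting times. The one-site birth-death oracle in
the test suite does exactly that; at exhaustion the bind/unbind chain
alternates strictly, so diagnostics there use an odd sampling stride.

# The wild-type operating point

The biochemical rates of the real system are unknown, so the package
defines its own wild-type preset (the `rate_params()` defaults):

```
alpha_sir_basal = 0.01   delta_sir_coop = 8   gamma_sas2 = 3
beta0_dot1_basal = 0.05  beta_dot1_coop = 20  eta_sir2_coop = 10
n_sir_total = 750        v_nucleus = 200      rho_ref = 1
```

The choices encode, in order of importance:

1. **Bistability with a self-pinning front.** At the pool-adjusted
   ambient density (`rho_free ~ 1.5`) the mean-field system is
   silenced-active bistable, and on the lattice the titrated front
   stalls mid-segment. The pool size and volume place the stall near
   lattice center with a restoring feedback of one density unit per two
   hundred converted nucleosomes.
2. **Nucleation-limited basal binding.** `alpha_sir_basal` is two
   orders below the cooperative rate so that silencing grows from the
   nucleation center rather than by spontaneous interior seeding —
   compact domains — yet is large enough that holes opened by mark loss
   near the pin eventually reseed.
3. **A robust active phase.** `gamma_sas2 = 3` and `beta_dot1_coop =
   20` keep unmodified nucleosomes rare inside active domains, which
   both resists Sir invasion and suppresses patchy ectopic silencing.

Basal rates are kept small (0.01-0.05) because the sharp transitions of
the idealized model become crossovers as basal rates grow, and
robust bistability needs them small.

# Front tracking and the zero-velocity line

`front_position()` returns the largest site whose moving-average
S-indicator (11-site window) is at least one half — the outermost edge
of majority-silenced chromatin. `front_velocity()` fits a line to
positions versus event index. Because the pinned front is a slowly
mixing, mean-reverting random walk, a whole-trace OLS standard error
would be far too small; the slope and error are instead computed by
batch-mean regression (ten blocks), so the error reflects block-scale
fluctuations. A front whose last samples sit against a pinned region is
flagged `boundary_absorbed` rather than assessed for stationarity.

`zero_velocity_line()` sweeps one enzymatic rate and lets the titration
dynamics re-equilibrate at each value, starting each point from the
previous point's final configuration (adiabatic continuation). Each
point records the self-adjusted mean free-Sir density, the effective
basal binding level `alpha x rho/rho_ref`, the front velocity with its
error, and the mean-field phase class at the titration-scaled rates.
Stationarity is asserted as `|v| < max(0.5, 2 se)` (sites per million
events). Because the front's excursions relax over millions of events,
meaningful velocity tests need paper-scale windows: the acceptance
checks use 1e7-event sweep runs and 3e7-event fresh-seed confirmation
runs started from the equilibrated configuration — at those lengths the
wild-type confirmation velocities are of order unity. A bisection-mode
utility (`zero_velocity_bisect()`) cross-checks the self-adjusted
stall by scanning fixed ambient densities for the velocity sign change.

# Observables

`density_profiles()` gives per-site mark frequencies;
`bound_fraction()` the time-averaged bound share of the pool;
`domain_sir_density()` the plateau height of the silenced domain,
defined as the mean S occupancy over interior sites where S is the
majority mark on time average (sites-by-count definitions proved
unstable against long-lived holes).

`s_power_spectrum()` estimates the spatial power spectrum of the
mean-subtracted S-indicator over the unpinned interior, averaging a
Hann-tapered periodogram across the stored samples (the samples are the
averaged segments); a sine-taper multitaper option is available for
parity with multitaper workflows, with the bias/variance tradeoff
controlled by the taper count. `correlation_length()` fits
`G(q) = c1 / (c2 + q^2)` for `0 < q <= pi/2` and reports
`xi = 1 / sqrt(c2)`.

Two numerical choices matter here:

* **The fit is unweighted by default.** Periodogram noise is
  multiplicative (the standard error of `G` is proportional to `G`),
  so inverse-variance weighting is relative-error fitting: the many
  high-`q` points of the flat within-domain noise floor then dominate
  and the fitted `c2` collapses to the floor's curvature, destroying
  `xi`. Absolute-error fitting keeps the low-`q` Lorentzian peak — the
  part that carries the correlation length — in charge. On binary
  Markov fields with known `xi` the unweighted fit recovers
  `xi in {2, 5, 10, 20}` within a few percent; inverse-variance
  weighting remains available as an option for floor-free spectra.
* **The fit range stops at half-Nyquist** to limit
  lattice-discreteness bias in the tail; configurable.

The synthetic fixtures calibrate this pipeline end to end: two-state
Markov fields with flip probability `p` have analytic correlation
length `-1 / log(1 - 2p)`; exact Lorentzian spectra must invert to
their `xi` to numerical precision; sharp step fronts anchor the front
estimator.

# What the synthetic data do and do not show

The Markov-field fixtures emulate exactly one feature of real
silencing data: exponentially decaying two-point correlations of a
binary occupancy signal. Passing the recovery checks therefore
validates the estimator, not the biology: real chromatin data carry
nonstationary domain structure, replication-phase mixtures, and
ChIP-style convolution with fragment-length kernels, none of which are
modeled. Likewise the simulator's agreement with mean-field in the
well-mixed limit validates the stochastic kernel, not the locality
structure of real chromatin contacts. All correlation-length and
phase-boundary statements are trend-level, and their absolute scales
depend on the unknown wild-type parameters and on the neighborhood
range.

A related point for the well-mixed regression: the stochastic
stationary mean differs from the deterministic fixed point by a
demographic O(1/L) correction (about 1e-3 at L = 500). The equivalence
checks run at L = 1500, where that correction sits below the
statistical resolution of a three-standard-error comparison at the run
lengths used.

# Perturbation scenarios

`scenario_preset()` encodes the classic experiments relative to wild
type: `dot1_null` (both Dot1 rates zero), inhibition and
overexpression sweeps of Dot1, inhibition sweeps of Sir2 and Sas2, and
Sir overexpression (1.5x pool). The acceptance-level trends, each run
over five seeds, are:

* **Sir2 inhibition** drags the system along the zero-velocity line
  out of the wild-type bistable region into a *bivalent-monostable*
  regime, with the ambient Sir density rising throughout (inhibiting
  the deacetylase releases Sir into the free pool).
* **Dot1 inhibition** lowers the in-domain Sir density while raising
  the chromatin-bound fraction — the counter-intuitive signature of
  fragmented, delocalized silencing — and collapses the correlation
  length of the silenced mark.
* **Dot1 overexpression** keeps correlations comparable to wild type:
  silencing becomes patchy but the patches are large and long-lived.

At this operating point the Dot1-inhibition sweep ends with a single
stable state whose silenced occupancy sits just under the 0.5 label
threshold, so the sweep's terminal phase class reads `silenced-mono`
rather than a silenced-intermediate bistable label; the underlying
two-branch structure is visible in the four-dimensional scan, where
the silenced-intermediate class appears at nearby parameter points.

# Configuration and outputs

Run configurations are YAML files (`run_config()`,
`write_run_config()`; YAML was chosen as the structured-text format
because it round-trips typed sections losslessly with the installed
toolchain). Every driver writes TSV tables plus a JSON manifest
containing the resolved parameters, seed and package version —
sufficient to re-run any output bit-identically. The `--paper-scale`
flag switches the schedule to the long protocol (1e7 events, 2e5
burn-in, samples every 2000 events, i.e. about 5000 stationary
samples); desk-scale defaults are 1e6 events.

# Known limitations

* Cell division is modeled as continuous mark loss, not as discrete
  halving events; spatially varying loss and 3D telomere clustering
  are out of scope.
* The five-state alphabet averages over multi-level acetylation and
  methylation and omits other marks (ubiquitylation, sumoylation,
  H2A.Z).
* The mean-field classifier's fixed thresholds make phase labels near
  threshold crossings sensitive to parameter noise; the scan metadata
  records the thresholds so sensitivity can be assessed.
* Velocity-based stationarity tests on single runs retain a tail risk:
  the front's slowest excursions relax over tens of millions of
  events, and a single window can catch one mid-flight. Ensemble
  confirmation (several seeds) is the robust pattern and is what the
  acceptance checks do for the trend assertions.
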