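# sirspread

Stochastic and mean-field simulation of multi-mark epigenetic silencing
in budding yeast.

## The scientific problem

Telomere-proximal genes in *Saccharomyces cerevisiae* are silenced by
Sir proteins (Sir2/3/4) that nucleate at the chromosome end and spread
along chromatin, while two anti-silencing histone marks — H4K16
acetylation (written by Sas2) and H3K79 methylation (written by Dot1) —
oppose Sir binding. `sirspread` implements a minimal five-state
nucleosome model of this system. Each nucleosome is in exactly one
state:

| code | state |
|------|-------|
| S | Sir-complex bound (silenced) |
| U | unmodified |
| A | H4K16-acetylated |
| M | H3K79-methylated |
| E | transcriptionally active (acetylated **and** methylated) |

States interconvert through basal and cooperative reactions. With all
rates in units of the uniform mark-loss rate λ = 1, the channels are

* basal Sir binding `U → S` at rate α and cooperative Sir binding
  `U → S` at rate δ·⟨S⟩ ("silencing polymerization") — both
  proportional to the ambient free-Sir density ρ/ρ_ref (titration);
* Sas2 acetylation `U → A`, `M → E` at rate γ;
* Dot1 methylation `U → M`, `A → E`, basal at β₀ plus the
  transcriptional feedback β·⟨E⟩ driven by active neighbors;
* cooperative Sir2 deacetylation `A → U`, `E → M` at rate η·⟨S⟩;
* mark loss `S, A, M, E → U` at rate 1.

⟨X⟩ is the local density of mark X in an exponentially weighted window
of neighboring nucleosomes. The free-Sir pool is finite:
ρ = (N_Sir − n_bound)/V, so spreading silencing depletes the pool and
feeds back on the binding rates.

The package provides:

* **Mean-field phase analysis** — fixed points of the well-mixed
  five-state ODE system by multi-start Newton iteration with analytic
  Jacobians, linear stability, phase labels (silenced / active /
  intermediate / bivalent), and 1–4-dimensional phase-diagram scans
  that exhibit both bistability types (silenced–active and
  silenced–intermediate).
* **Gillespie lattice simulation** (compiled core) — event-driven
  dynamics on a 1D chromatin segment with pinned telomeric boundaries
  (left end held in S, right end in E) and exact titration bookkeeping.
* **Front tracking** — silencing-front position and velocity, and the
  zero-velocity line traced by letting the titrated pool self-adjust as
  one enzymatic rate is swept.
* **Observables** — per-site density profiles, chromatin-bound Sir
  fraction, spatial power spectra of the silenced mark, and the
  correlation length ξ from the Lorentzian fit G(q) = c₁/(c₂ + q²),
  ξ = 1/√c₂.
* **Scenario presets** for the classic perturbations: `dot1_null`,
  Dot1 inhibition/overexpression sweeps, Sir2 and Sas2 inhibition
  sweeps, Sir overexpression.

## Worked example

```r
library(sirspread)

## titrated lattice run: the finite Sir pool pins the silencing front
cfg <- lattice_config(length = 1000, pin_left = 10, pin_right = 10,
                      initial_state = "half", seed = 7)
tr <- run_gillespie(cfg, rate_params(), n_events = 1e7, burn_in = 5e6,
                    sample_every = 2000)
v <- front_velocity(front_positions(tr), tr$event)
round(c(velocity = v$velocity, se = v$velocity_se,
        rho_free = mean(tr$rho_free), bound = bound_fraction(tr)), 3)
#> velocity       se rho_free    bound
#>    4.882   11.637    1.517    0.596

## mean-field phase at the self-adjusted ambient Sir density
set.seed(1)
phase_report(rate_params(), rho_free = 1.52)
#> Phase: silenced-active-bistable
#>        p_s     p_u     p_a      p_m      p_e  max_re stable marginal    label
#> 1 0.881440 0.08212 0.02483 0.008683 0.002929 -0.4454   TRUE    FALSE silenced
#> 3 0.304802 0.08190 0.02587 0.317385 0.270046  0.2130  FALSE    FALSE bivalent
#> 2 0.002301 0.05329 0.01015 0.200416 0.733844 -0.3460   TRUE    FALSE   active

## correlation length of the silenced mark
trajectory_correlation_length(tr)
#> Lorentzian fit: xi = 26.191 nucleosomes (c1 = 0.01687, c2 = 0.001458, rmse = 0.662)
```

The titration effect parks the silencing front mid-lattice: the front
velocity is statistically zero (≈ 5 ± 12 sites per million reactions)
and the free-Sir density has self-adjusted from its nominal value 1 up
to ρ ≈ 1.5 — exactly into the regime where the mean-field system is
bistable between a silenced state (p_S ≈ 0.88) and an active state
(p_E ≈ 0.73), separated by an unstable bivalent saddle. Sir occupancy
along the lattice is correlated over tens of nucleosomes (ξ ≈ 26).

## Command line

```sh
sirspread meanfield-scan --config cfg.yaml --out results/
sirspread simulate --seed 7 --out results/ --paper-scale
sirspread zero-velocity --config sweep.yaml --out results/
sirspread perturb --preset sir2_inhibition_sweep --out results/
sirspread fixtures --fixture-kind markov --out fixtures/
```

(installed at `<library>/sirspread/exec/sirspread`; run via `Rscript`.)

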