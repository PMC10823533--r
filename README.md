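# hoprates

Surface-hopping simulations of electron-transfer rates in the two-state
Brownian-oscillator spin-boson model, for people who want to study — or
stress-test — mixed quantum–classical dynamics in the regime where Marcus
theory is the exact classical benchmark.

A single solvent polarization coordinate `Q` moves between two
equal-curvature Marcus parabolas

    V_r(Q) = (1/2) Ω² Q²,   V_p(Q) = (1/2) Ω² (Q − Q₀)² − ε,   Q₀ = √(2Λ)/Ω,

coupled by a constant diabatic coupling Δ and damped by an Ohmic bath
(`J(ω) = γω`), integrated as a Langevin equation.  Everything is in
reduced units (β = ħ = m = 1).  In the weak-coupling limit the classical
forward rate is Marcus theory,

    k_MT = (Δ²/ħ) √(πβ/Λ) exp(−β(Λ−ε)²/4Λ),

and the package measures how well two trajectory surface-hopping methods
reproduce it (and each other) from direct population dynamics:

* **FSSH** — Tully's fewest-switches surface hopping: stochastic hops with
  probabilities built from the electronic coherence; wave function never
  reset, so the active surface can drift out of sync with the amplitudes
  (the overcoherence / inconsistency error).
* **MASH** — the mapping approach to surface hopping: deterministic hops
  whenever the Bloch-vector component S_z changes sign, with initial
  electronic conditions sampled from the active hemisphere with density
  ∝ |S_z|.  Inconsistency is impossible by construction.

Both share the same nuclear integrator (BAOAB), the same exact two-level
electronic propagator, Boltzmann initial conditions restricted to the
reactant region, momentum rescaling along the coupling at hops with
reflection of frustrated hops, and an optional energy-gap-triggered
decoherence correction (applied only where the gap exceeds 4 k_BT).
Observables: product-population curves with hop-count decompositions,
plateau-slope rates (window t ∈ [10, 20] βħ), full-decay fits with
half-lives, and the analytic Marcus benchmark.

## A worked example

Activationless electron transfer (ε = Λ), weak coupling, MASH:

```r
library(hoprates)
m <- sb_model(lam = 12, eps = 12, delta = 10^(-1.4), omega = 0.25,
              gamma = 0.25)
spec <- ensemble_spec("MASH", n_traj = 1e5, dt = 0.01, t_max = 20, seed = 1)
curve <- run_ensemble(spec, m)
print(curve)
plateau_rate(curve)
marcus_rate(m)
```

prints

```
Product-population curve (MASH, 100,000 trajectories)
  t in [0, 20] beta*hbar (201 samples); final <Pp> = 0.0279
  hops: 147333, frustrated: 17874, decoherence events: 0
Rate constant: k = 0.0009376 (1/beta*hbar)  [plateau_slope, MASH]
  stderr = 3.9e-05 (4.2%)
  fit window: [10, 20]
Rate constant: k = 0.0008109 (1/beta*hbar)  [marcus, Marcus]
```

The plateau-slope rate sits ~16% above the Marcus value — the expected
small MASH overestimate at the activationless point, where the avoided
crossing coincides with the reactant-well minimum.  The same protocol
with FSSH overshoots several times more strongly, and at ε = 0 FSSH
*under*shoots because it loses the two-hop reactive pathway
(`hop_decomposition()` shows which trajectories carry the flux).

## Command line

```sh
exec/hoprates run   --config run.cfg               # one ensemble -> CSV + JSON
exec/hoprates scan  --config run.cfg --variable eps
exec/hoprates decay --config run.cfg --decoherence on
```

The config is a small TOML-like file with `[model]`, `[ensemble]`,
`[init]`, `[scan]` and `[output]` sections; see `?parse_run_config`.

## Benchmark script

`scripts/acceptance.R` re-runs the package's headline benchmarks from
scratch at acceptance-grade trajectory counts — MASH vs Marcus deviations
for the symmetric, activationless and deep-inverted models, the FSSH
overshoot at the activationless point, and the FSSH underestimate of the
golden-rule rate in the symmetric model — and writes the measured numbers
to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It takes on the order of 15 minutes on one CPU; every number is computed
from fresh seeded simulations (no stored results).

## What to read next

The methods vignette (`vignettes/surface-hopping-rates.Rmd`) documents
the model, both algorithms, the numerical choices (integrator splitting,
exact electronic propagator, time-step convergence — MASH is converged at
dt = 0.01 βħ while FSSH rate benchmarks need dt ≤ 0.0025 βħ), the
initial-condition samplers, the decoherence correction, and the
limitations (classical nuclei only, one nuclear dimension, constant
diabatic coupling).
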