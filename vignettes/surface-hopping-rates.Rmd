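---
title: "Electron-transfer rates from MASH and FSSH surface hopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-transfer rates from MASH and FSSH surface hopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoprates)
```

## The model

`hoprates` simulates nonadiabatic electron transfer in the two-state
Brownian-oscillator spin-boson model: a single mass-weighted solvent
polarization coordinate $Q$ moving between two equal-curvature Marcus
parabolas
$$V_r(Q) = \tfrac12\Omega^2 Q^2, \qquad
  V_p(Q) = \tfrac12\Omega^2 (Q - Q_0)^2 - \epsilon, \qquad
  Q_0 = \sqrt{2\Lambda}/\Omega,$$
coupled by a constant diabatic coupling $\Delta$ and subject to Ohmic
friction $J(\omega) = \gamma\omega$, implemented exactly as a Langevin
equation (the multidimensional harmonic bath folds into friction plus
fluctuating force for classical nuclei).  $\Lambda$ is the reorganization
energy, $\epsilon$ the driving force; $\epsilon = \Lambda$ is the
activationless point and $\epsilon > \Lambda$ the inverted regime.
Everything is in reduced units $\beta = \hbar = m = 1$: energies in
$k_BT$, times in $\beta\hbar$, rates in $1/\beta\hbar$.

Diagonalizing the $2\times2$ diabatic matrix gives the adiabats
$V_\pm = \bar V \pm \tfrac12\sqrt{(V_r-V_p)^2 + 4\Delta^2}$, with minimum
gap $2\Delta$ at the crossing $Q^\ddag = (\Lambda-\epsilon)/(\Omega\sqrt{2\Lambda})$,
and a Lorentzian derivative coupling $d(Q)$ of area $\pi/2$ peaked there.
In the weak-coupling (golden-rule) limit the classical rate is Marcus
theory,
$$k_{\rm MT} = \frac{\Delta^2}{\hbar}\sqrt{\frac{\pi\beta}{\Lambda}}
  \exp\!\Big(-\frac{\beta(\Lambda-\epsilon)^2}{4\Lambda}\Big),$$
which is exact for this model with classical nuclei and is the benchmark
every simulated rate is compared against (`marcus_rate()`).

The default model parameters are the ones used throughout the rate study:
$\beta\Lambda = 12$, $\beta\hbar\Omega = 1/4$, $\gamma = \Omega$
(underdamped, the stringent regime for surface hopping), with
$\log_{10}\beta\Delta = -7/5$ for the weak-coupling runs.

## The two dynamics

Both methods move classical nuclei on one *active* adiabat $n$ with force
$-V_n'(Q)$ and carry the electronic wave function
$i\hbar\dot c_\pm = V_\pm c_\pm \mp i\hbar\dot Q d\, c_\mp$ along the
trajectory, conveniently pictured as precession of the Bloch vector
$\mathbf S$ ($S_z = |c_+|^2 - |c_-|^2$,
$S_x + iS_y = 2c_+c_-^*$) about the field $(0,\,2\dot Qd,\,{\rm gap}/\hbar)$.
They differ only in the hopping rule and the initial electronic sampling:

* **FSSH** starts in the pure state of the initial surface and hops
  stochastically with the fewest-switches probability
  $g_{n\to m} = \max(0,\ n\,\dot Q\,d\,S_x\,\delta t / |c_n|^2)$.
  The wave function is never altered by a hop, so the coefficients can
  drift arbitrarily far from the active state (the inconsistency /
  overcoherence error).
* **MASH** replaces the stochastic hops by deterministic ones — the active
  state is always the majority state, $n = \mathrm{sign}(S_z)$ — and
  replaces the hop randomness by sampling the initial $\mathbf S$ over the
  hemisphere of the initial surface with density $\propto |S_z|$
  (so $\langle|S_z|\rangle = 2/3$).  Inconsistency is impossible by
  construction.

At an (attempted) hop the momentum is rescaled along the nonadiabatic
coupling direction (in one dimension, along $Q$) to conserve
$V_n + P^2/2$ exactly; an upward attempt without sufficient kinetic
energy is *frustrated*: the momentum component is reflected and the
active state kept.  This is the prescription the MASH derivation yields,
and it is applied identically to FSSH for comparability
(`frustrated = "reflect"`; the contested alternative `"ignore"` is
exposed as a switch and changes FSSH rates dramatically — see below).

Initial nuclear conditions are classical Boltzmann (not Wigner) samples
of $(Q, n)$ jointly over the two adiabats restricted to the reactant
region, with Maxwell–Boltzmann momenta; the active state therefore
carries its Boltzmann weight automatically.  The reactant/product
partition is adiabatic: product means lower surface right of the diabatic
crossing or upper surface left of it (`product_projector()`), the
definition with the shortest transient.  In the normal regime reactants
are the left well of the lower adiabat; at $\epsilon = \Lambda$ half of
the reactant ensemble sits on the upper adiabat, and in the inverted
regime nearly all of it does.

## Numerical scheme

* **Nuclear integrator**: BAOAB splitting of the Langevin equation with
  fluctuation–dissipation-consistent noise; its $\gamma = 0$ limit is
  velocity Verlet (tested: energy drift $< 10^{-6}$ over $10^5$ steps at
  $\delta t = 0.01$).
* **Electronic propagator**: exact $2\times2$ exponential (equivalently,
  Rodrigues rotation of $\mathbf S$) for the field evaluated at the
  mid-step position with $\dot Q = \Delta Q/\delta t$, held constant over
  the step.  The norm is conserved to machine precision by construction;
  accuracy is second order in the field sampling.  Because the propagator
  is exact for a frozen field, electronic substeps within a nuclear step
  would be an exact no-op, so no substep knob exists; the single
  convergence parameter is $\delta t$.
* **Hop cadence**: hops are tested once per step at the step end, with no
  bisection of the $S_z$ sign change.  For MASH this is dt-converged at
  $\delta t = 0.01$ for the study parameters (rates at $\delta t = 0.01$
  and $0.005$ agree within statistical error).
* **Startup check**: the run refuses $\delta t \cdot {\rm gap}/\hbar >
  0.25$ with the gap evaluated at the initial region's well minimum
  ($\approx \Lambda$ for reactants; using the global maximum over both
  wells would reject the study's deep-inverted case for a region
  trajectories rarely visit on plateau timescales).
* **Seeding**: one master seed; every trajectory gets its own
  counter-based substream (splitmix64-seeded xoshiro256++), so ensembles
  are bitwise reproducible and independent of batching and execution
  order.  Gaussian noise uses a ziggurat sampler (validated against the
  normal distribution by moment and KS tests).
* **Ties and boundaries**: $S_z = 0$ exactly keeps the current surface;
  $Q = Q^\ddag$ belongs to the reactant.  Both are measure-zero
  conventions.

### Time-step convergence: MASH versus FSSH

MASH plateau rates are insensitive to $\delta t$ below $0.01$.  FSSH is
not: its hop probability is normalized by the active-state population
$|c_n|^2$, which the overcoherence error drives toward zero precisely on
the trajectories that matter, making per-step probabilities $O(1)$ and
the hop process only first-order accurate in $\delta t$.  At the study
parameters the FSSH plateau rate at $\epsilon = \Lambda$ moves from
$1.21\,k_{\rm MT}$ ($\delta t = 0.01$) through $1.43$ ($0.005$) and
$1.51$ ($0.0025$) to $1.54$ ($0.00125$), approaching $\approx 1.5$–$1.6$ in
the $\delta t \to 0$ limit.  The package therefore runs FSSH rate
benchmarks at $\delta t \le 0.005$ and, where a converged point value is
reported, uses Richardson extrapolation in $\delta t$ from a matched pair
of ensembles (the estimator is first order, so
$2k(\delta t) - k(2\delta t)$ removes the leading error; any adjacent
pair inside the asymptotic regime is a valid extrapolant, and the pair is
chosen on compute cost).  This is a numerical-convergence choice made on
convergence data alone.

## Rate estimators

* `plateau_rate()` — least-squares slope of $\langle P_p(t)\rangle$ over
  the plateau window (default $t \in [10, 20]\,\beta\hbar$), divided by
  the mean reactant population over the window (exact for two-state
  kinetics; a no-op in the rare-event regime).  The statistical error
  uses the Poisson count of reactive events in the window, which is the
  correct scale for a strongly time-correlated binary observable; a
  quadratic-term check warns if the transient has not subsided.
* `decay_rate()` — weighted nonlinear fit of
  $p(t) = p_{\rm eq}(1 - e^{-(k_f+k_b)t})$ to a full decay, reporting
  $k_f$ and the half-life of the reactant-excess (invariant to
  $p_{\rm eq}$, which enables half-life-ratio comparisons between
  methods); it refuses curves spanning fewer than two fitted half-lives.
* `marcus_rate()` — the closed form above; cross-checked in the tests
  against an independent numerical golden-rule quadrature to $10^{-10}$.
* `hop_decomposition()` — strata
  $\langle P_p(t)\,1[{\rm hops}=m]\rangle$; the strata sum to the total
  exactly and expose the mechanism of the FSSH failure: at weak coupling
  the reactive flux is carried by zero-hop *and* two-hop trajectories,
  and FSSH suppresses the two-hop channel (its wave function ends up
  pointing away from the active state after the second crossing, so the
  third-passage hop probability clamps to zero).

## Decoherence corrections

With `decoherence = "gap_triggered"` the correction is applied while the
adiabatic gap exceeds `decoherence_threshold` (default $4k_BT$, i.e.
only in the wells, never in the coupling region where it would be
unsafe): MASH resamples $\mathbf S$ from the active hemisphere with the
$|S_z|$ density — identical to the initial sampling, hence idempotent in
law and a safe special case of a quantum jump — while FSSH collapses the
amplitudes to the pure active state.  The check runs once per
`decoherence_stride` steps (default: the sampling stride); results are
insensitive to this cadence, which a regression test asserts at strides
1, 10 and 100.  In the rare frustrated-hop transient where
$\mathrm{sign}(S_z) \neq n$, resampling would silently switch surfaces,
so the engine skips (and counts) those applications; the user-facing
`apply_decoherence()` raises an error instead.

## What the simulations establish (and what they do not)

The package's tests reproduce, at reduced trajectory counts, the
weak-coupling rate phenomenology: MASH plateau rates track Marcus theory
within ~10–15% across the normal, activationless and inverted regimes
without any decoherence correction; FSSH overshoots by ~55–60% at the
activationless point and undershoots by up to a factor ~2 in the
symmetric case, with the deficit localized in the two-hop stratum.  All
such checks are stochastic: assertions use bands widened by the run's own
standard error, and the acceptance-grade trajectory counts (statistical
error of a few percent) run only in `scripts/acceptance.R`.

Because nuclei are classical by construction, none of these results
contain nuclear quantum effects (tunneling, zero-point energy); the
Marcus benchmark used here is likewise the classical golden-rule limit.
The model is one-dimensional with a constant diabatic coupling; the
momentum-rescaling logic is written against the 1-D coupling direction
only.  Long full-decay runs ($\tau_{\rm rxn} \sim 10^4\,\beta\hbar$ at
weak coupling) are feasible but expensive; the test suite exercises the
decay machinery at reduced ensemble sizes and the symmetric
strong-coupling case, where equilibration to $p_{\rm eq} = 1/2$ is
quick.

## A worked example

```{r example, eval = FALSE}
m <- sb_model(lam = 12, eps = 12, delta = 10^(-1.4), omega = 0.25,
              gamma = 0.25)
spec <- ensemble_spec("MASH", n_traj = 1e5, dt = 0.01, t_max = 20,
                      seed = 1)
curve <- run_ensemble(spec, m)
plateau_rate(curve)
marcus_rate(m)
```

See the README for the printed output of this run and
`scripts/acceptance.R` for the full benchmark protocol.
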