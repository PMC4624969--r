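---
title: "Invasion dynamics under quenched random fitness and cell motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invasion dynamics under quenched random fitness and cell motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranfield)
```

## The model

`moranfield` simulates competition between two phenotypes — residents (type A)
and mutants (type B) — on a square lattice with von Neumann neighbourhoods and
reflecting boundaries. The population is constant: every site holds exactly
one cell. The central modelling idea is that fitness is a property of
*position*, not of the cell: site $i$ confers proliferation rate $r_{A,i}$ on
a resident and $r_{B,i}$ on a mutant occupying it. These per-site rates are
drawn once from a chosen distribution and then frozen (a *quenched* random
field), which represents micro-environmental heterogeneity — nutrient or
oxygen gradients, acidity, drug concentration — varying in space but changing
slowly relative to the selection time scale.

Dynamics follow death-birth updating. At each update a site is chosen
uniformly at random to die (all cells share one death rate, probability $1/N$
each). The vacancy is then filled by an elementary event drawn over its
occupied neighbours $j$:

* type-$T$ neighbour $j$ **divides** into the vacancy with probability
  $w\, r_{T,j} / N_r$,
* type-$T$ neighbour $j$ **migrates** into the vacancy with probability
  $w\, m_T / N_r$,

with normalisation $N_r = \sum_k w\,(r_{T(k),k} + m_{T(k)})$ over the occupied
neighbours $k$. A division completes the update; a migration relocates the
vacancy to the migrant's old site and the draw repeats there, so a single
update can involve a cascade of moves before a birth finally restores the
population to $N$. Motilities $m_A$, $m_B$ are spatially uniform. Fitness is
site-bound throughout: an offspring (or migrant) arriving at site $i$
henceforth competes with the rate that site confers on its type. The
simulation runs until an absorbing state — all-mutant (*fixation*) or
all-resident (*extinction*) — and the invasion probability $\rho$ is the
probability of fixation for a single mutant placed uniformly at random.

The edge weight $w$ is stored as the constant $1/4$ even on boundary sites.
Because $w$ multiplies every term of both numerator and denominator above, any
per-vacancy constant — including $1/\mathrm{degree}$ — yields the same event
distribution; a unit test asserts this equivalence on corner, edge and centre
vacancies.

## Fitness distributions

Five spec constructors cover the study designs:

| constructor | field | parameters (defaults) |
|---|---|---|
| `fitness_constant(mean)` | homogeneous | — |
| `fitness_uniform(mean, width)` | i.i.d. $U[\langle r\rangle-\Delta, \langle r\rangle+\Delta]$ | requires $\langle r\rangle-\Delta \ge 0$ |
| `fitness_triangular(lower, upper, mode)` | i.i.d. triangular | `mode = 1` |
| `fitness_bimodal(r1, r2, x)` | two-valued, exact count | — |
| `fitness_checkerboard(r_low, r_high)` | deterministic parity pattern | — |

Two choices deserve comment. First, bimodal fields assign the advantaged value
$r_2$ to *exactly* $\mathrm{round}(xN)$ sites (round half up, so $x = 0.5$ on
$N = 441$ gives 221 sites) chosen uniformly without replacement: the fraction
$x$ describes the composition of the system, and per-site Bernoulli draws
would add spurious composition noise between configurations. Second, the
triangular spec defaults its mode to 1, the resident reference fitness; with
supports such as $[0.90, 1.25]$ the mode pins the central value to neutrality
while the mean $(a + c + b)/3$ shifts slightly away from 1, which is exactly
the skewness effect the triangular design probes. The mode remains a free
parameter. Negative fitness is rejected outright; zero fitness is legal and
means a cell that can die but never reproduce.

## Estimation protocol

`estimate_fixation()` implements the full protocol: draw `n_configs`
independent quenched field pairs, run `n_iters` absorption runs against each
(all-resident start, one uniformly placed mutant), and average the
per-configuration fixation fractions. Defaults are `n_iters = 10000` — the
scale at which the reference results were produced — and `n_configs = 10`,
a concrete choice where only "several configurations" is specified. The
reported `spread` is the standard deviation of per-configuration fractions,
the quantity drawn as error bars in this literature; it mixes
between-configuration variability with within-configuration binomial noise,
so the per-configuration binomial standard error is recorded alongside it and
`combined_se()` gives the standard error of the pooled mean. One master seed
deterministically spawns per-configuration seeds, so estimates are
bit-reproducible; execution is sequential.

`sweep_fixation()` repeats the protocol along a grid of one parameter
(uniform width `delta`, bimodal fraction `x`, mutant motility `m_B`, or
uniform mean `r_B_mean`) and returns a tibble with an `autoplot()` method.

## Numerical and design choices

* **Compiled kernel, shared RNG.** The update loop is C++ (Rcpp) but consumes
  R's own uniform stream, one draw per death and per elementary event, via
  inversion on the cumulative event weights. A pure-R reference
  implementation consumes draws in the identical order; a test replays both
  from one seed and requires identical trajectories. Because the migration
  kernel interleaves zero-width migration entries when $m_A = m_B = 0$, the
  plain and migration kernels are also draw-for-draw identical there — the
  reduction property is exact, not statistical.
* **Degenerate vacancies.** If no neighbour of a fresh vacancy can divide or
  migrate ($N_r = 0$, possible when zero-fitness cells surround it), the
  update is a null update: the dead cell is restored and the clock advances.
  This keeps the population constant and gives the correct limits (residents
  with $r_A \equiv 0$ can never exclude a mutant; the exact oracle treats the
  same situation as a self-loop). A vacancy that becomes stuck *mid-cascade*
  cannot be restored and raises an error instead; it is reachable only in
  zero-fitness/zero-motility corners that config validation rejects.
* **Caps.** A cascade is capped at `cascade_cap = 1e6` elementary events
  (motile cells over a zero-fitness field would otherwise wander forever);
  absorption is capped at `max_updates = 100 N^2`, generous against the
  observed absorption times (neutral fixations on the 21×21 grid take on the
  order of $10^6$ updates). Both raise errors distinguishable from
  absorption, the latter carrying the partial state for diagnostics.
* **Exact oracle.** For lattices up to 14 sites,
  `exact_fixation_probability()` enumerates all $2^N$ occupancy states,
  assembles the sparse one-update transition matrix from the same event
  probabilities, and solves the absorbing-chain linear system. It covers only
  $m = 0$: with motility each update is itself an absorbing sub-chain over
  vacancy positions, and migration correctness is instead pinned by the
  reduction identity, normalisation tests and hand-enumerated single-update
  probabilities.
* **Closed forms.** `moran_fixation(r, N)` evaluates
  $(1 - 1/r)/(1 - r^{-N})$ through `log`/`expm1`, which is stable through
  $r = 1$ (both parts vanish linearly; the neutral value is $1/N$).
  `bimodal_moran_approx()` is the well-mixed mean-field reference
  $1 - 1/\langle r\rangle$, clamped at 0 where the mean fitness is below 1 —
  the formula goes negative there while a probability cannot.

## What the generator emulates — and what it does not

The synthetic fitness fields are spatially i.i.d. (or deterministic
patterns). Real micro-environments are spatially *correlated* — hypoxic
regions, vascular gradients — and may drift in time; neither correlation
structure nor temporal variation is modelled, and mutation, variable death
rates and empty-site dynamics are likewise out of scope. Passing tests
therefore demonstrate the behaviour of the idealised quenched-disorder model
(heterogeneity suppresses selection; discrete disorder creates a
connectivity threshold near the checkerboard composition; motility restores
invasion by letting mutants bridge disconnected advantaged islands), not
quantitative predictions for any particular tissue.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to hold
Monte Carlo error comfortably inside the statistical tolerances: 50,000 runs
for the neutral benchmark (binomial SE ≈ 0.0002); 10 configurations × 1,000
runs for the uniform-disorder points; 10 × 2,000 for the triangular point;
5 × 2,000 for threshold and weak-selection sweeps. The bundled
`*_paper.yaml` config reproduces the full 10,000-iteration protocol for
anyone wanting the original scale.

## A worked example

```{r example, eval = FALSE}
lat <- build_lattice(21, 21)
est <- estimate_fixation(
  spec_B = fitness_uniform(1.5, 1.5),  # mutant fitness uniform on [0, 3]
  spec_A = fitness_constant(1),
  motility = motility_params(),
  lattice = lat, n_configs = 10, n_iters = 1000, seed = 5)
glance(est)
autoplot(sweep_fixation("m_B", c(0, 1, 5), lat,
                        spec_B = fitness_uniform(1.5, 1.5),
                        n_configs = 5, n_iters = 1000, seed = 9))
```

## Known limitations

Square lattices only (no hexagonal/arbitrary graphs or unstructured meshes);
death-birth updating only (no birth-death variant); fixation *times* are
recorded (`n_updates`, `n_elementary`) but not analysed; the exact oracle
does not treat motility; and the well-mixed bimodal approximation is expected
to fail for strong heterogeneity (e.g. $\{0.5, 1.5\}$), where localisation of
advantaged sites dominates — that disagreement is a finding of the model, not
a defect of the approximation's implementation.
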