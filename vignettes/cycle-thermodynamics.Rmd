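---
title: "Thermodynamics of reversible uni-uni catalytic cycles"
author: "uniCycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of reversible uni-uni catalytic cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniCycle)
```

## The model

A uni–uni enzyme converts one substrate molecule S into one product
molecule P per catalytic cycle. uniCycle models such enzymes as a
single reversible cycle over n = 2, 3 or 4 functional states (free
enzyme plus one to three complexes), with pseudo-first-order rate
constants $k_1 \dots k_{2n}$ in s$^{-1}$: odd indices drive the cycle
forward (state $i \to i{+}1$), even indices backward. Binding steps
carry concentration dependence through $k_i = k_i^{*}[\mathrm{L}]$,
where $k_i^{*}$ is a second-order constant in M$^{-1}$s$^{-1}$ and L is
the substrate, the product, or — in the buffer-modified carbonic
anhydrase scheme — the proton-accepting buffer, which enters both
directions of the enzyme-recovery step.

At steady state the occupancies follow from the King–Altman/Hill
diagram method: $p_i = \Sigma_i / \Sigma$, where $\Sigma_i$ sums, over
all directed spanning trees rooted at state $i$, the product of edge
rate constants, and $\Sigma = \sum_i \Sigma_i$. For a single cycle of
$n$ states each rooted sum has exactly $n$ terms (one per deleted cycle
edge). The net cycle flux is

$$J = \frac{k_1 k_3 \cdots k_{2n-1} - k_2 k_4 \cdots k_{2n}}{\Sigma}$$

in s$^{-1}$ per enzyme; it is negative when the cycle runs backward.
`directionalSums()` enumerates the trees generically for any supported
$n$ rather than transcribing per-scheme formulas. This matters: a
widely circulated transcription of the four-state denominator repeats
two terms of the first rooted sum in the fourth and fails to reproduce
the reference flux and dissipation values that the correct enumeration
hits (the triosephosphate isomerase reference state gives
$J = 14.4\ \mathrm{s}^{-1}$ with the enumeration, $10.9\ \mathrm{s}^{-1}$
with the transcribed form). A regression test pins both facts.

`steadyStateOracle()` provides an independent verification path: it
solves the stationary master equation by dense linear algebra (with one
step of iterative refinement, because rate sets spanning six decades
make the system ill-conditioned) and agrees with the diagram method to
$10^{-10}$ relative on occupancies. Flux agreement is measured against
the gross one-way flux scale $k_1 p_1 + k_2 p_2$: near equilibrium the
net flux is a catastrophic cancellation of the gross terms, and no
method retains $10^{-10}$ of *that* difference in double precision.

## Forces, entropy production, performance parameters

All thermodynamic quantities are expressed per RT, so temperature never
enters numerically (the registry keeps it as a text label). The step
force is $X_i/RT = \ln\!\big(k_{2i-1} p_i / (k_{2i} p_{i+1})\big)$; the
occupancy ratios telescope, so the step forces sum algebraically to the
total force $X_{tot}/RT = \ln\!\big(\prod k_{odd} / \prod k_{even}\big)$.
Total entropy production per R is the bilinear product
$P = J \cdot X_{tot}/RT$ in s$^{-1}$ ("dissipation/RT"), decomposed into
per-step contributions $P_i = J \cdot X_i/RT$. $P \ge 0$ always, since
$J$ and $X_{tot}$ share their sign in a single cycle.

The forward performance parameters use the per-scheme closed forms:
$k_{cat} = k_3$ (two states), $k_3 k_5/(k_3+k_4+k_5)$ (three),
$k_3k_5k_7/(k_3k_5+k_3k_6+k_3k_7+k_4k_6+k_4k_7+k_5k_7)$ (four); the
specificity constant $k_{cat}/K_M$ divides the forward rate-constant
product by $[\mathrm{S}]$ times the substrate-rooted diagram sum, so
the $[\mathrm{S}]$ hidden in $k_1$ cancels and a true second-order
constant results. $K_M$ is computed as $k_{cat}$ divided by the
specificity: the compact textbook $K_M$ expressions for the three- and
four-state schemes are typographically fragile, while both factors here
are unambiguous (the two-state form $[\mathrm{S}](k_2+k_3)/k_1$ is kept
as an explicit cross-check). Forward-defined $k_{cat}$, $K_M$ and
$k_{cat}/K_M$ are reported for either sign of the force, with the sign
flagged per record, because negative-force states are legitimate sample
points even though the forward definitions lose their usual meaning
there.

Two overall equilibrium-constant conventions coexist in the source
tables and both are first-class outputs: `kApp`, the product of the
step constants $K_i = k_{2i-1}/k_{2i}$ (concentration-dependent, equal
to $\exp(X_{tot}/RT)$), and `kChem`, the same product with the
second-order constants substituted in the binding steps
(concentration-independent). The triosephosphate and ketosteroid
isomerase tables print `kChem`; the carbonic anhydrase, beta-lactamase,
beta-galactosidase and glucose isomerase tables print `kApp`. The
registry records the convention per enzyme, verified against
$\exp(X_{tot}/RT)$.

## The enzyme registry

Ten literature parameter sets ship as a plain JSON fixture
(`inst/extdata/enzymes.json`): triosephosphate isomerase (four states),
ketosteroid isomerase (four; two published columns, the globally
optimized one as default), carbonic anhydrase I, II and the T200H
mutant of II (four states, buffer-modified scheme), the PC1, RTEM and
Lac-1 A-class beta-lactamases (three states), beta-galactosidase and
glucose isomerase (two states). Values are stored exactly as printed;
`referenceRateSet()` uses the printed pseudo-first-order values
digit-for-digit, while `buildRateSet()` re-derives binding constants
from second-order constants and concentrations (used by the
concentration scans).

One curated inconsistency: the beta-galactosidase table prints
$k_4 = 10^{-5}\,$s$^{-1}$ alongside $k_4^{*} = 10$ M$^{-1}$s$^{-1}$ and
$[\mathrm{P}] = 10^{-7}$ M, which would give $10^{-6}$ s$^{-1}$. Its
own derived values ($K_{eq} = 2\times10^{7}$, $X_{tot}/RT = 16.81$,
$P = 2553$ s$^{-1}$) all require $k_4 = 10^{-5}$, i.e. an effective
product concentration of $10^{-6}$ M, so the printed pseudo-first-order
value wins in the reference rate set and the discrepancy is documented
here rather than silently repaired.

## Noise on rate constants

`applyNoise()` multiplies selected constants by random factors: the
Box–Muller normal deviate $g = \sqrt{-2\ln s_1}\cos(2\pi s_2) +
\mathrm{shift}$ (or the sine branch), or a uniform multiplier. The
uniform range is U(0, 2) — mean one — as a documented convention, since
only "uniform noise" is specified by the modeling tradition this
follows. A positive shift (+1 or +2) moves the bulk of the multipliers
away from zero. One draw may be shared by all masked constants
("shared", the regime in which noise cancels in every rate-constant
ratio) or drawn per constant.

Constraints are enforced after multiplication:

* **fixed_step_equilibria** recomputes every backward constant from the
  observed step equilibrium constants, pinning each $K_i$ and hence the
  total force. Combined with a shared draw the entire rate set rescales
  by $g$, so flux, $k_{cat}$, $k_{cat}/K_M$ and $P$ all carry one common
  fold factor per sample and the efficiency–dissipation relation is a
  machine-precision line through the origin.
* **fixed_total_force** perturbs one step's equilibrium constant and
  rescales the *backward* constant of a partner step so that
  $\ln \prod K_i$ is restored exactly. Compensating through the
  backward constant is deliberate: for triosephosphate isomerase it
  reproduces the characteristic optimum — noise on the substrate-release
  constant $k_2$ trades $K_1$ against $K_4$ (via $k_8$) and dissipation
  peaks at $P \approx 39.6\ \mathrm{s}^{-1}$ at an intermediate
  $K_4 \approx 10$, whereas compensating through the forward constant
  gives a monotone profile with no interior optimum.
* **replace_nonpositive_with_observed** reverts any constant whose
  multiplier is not strictly positive (the practical rule for
  unshifted, per-constant noise).
* **none** errors on a nonpositive result.

Under the two equilibria-preserving constraints a nonpositive
multiplier cannot be repaired (about 2% of draws even at shift +2);
such draws are rejected and redrawn, which remains bit-reproducible
under the recorded seed. Identical seeds give identical sample tables.

## Scans, sampling, fits

`stepwiseScan()` walks one transition constant arithmetically
(optionally holding its step equilibrium constant fixed by co-scaling
the partner constant); `concentrationScan()` trades substrate for
product at a conserved $[\mathrm{S}]+[\mathrm{P}]$ pool, rebuilding the
binding constants each row; `noisySample()` evaluates independent
constrained draws. Each row of the resulting `SampleTable` is a full
quasi-steady-state observable block recomputed from that row's rate
constants — nothing is cached across rows, and a test re-derives rows
from their stored constants.

The canonical 1000-step product-release scan for triosephosphate
isomerase (k7 from 10 to 10000 s$^{-1}$ in steps of 10) reaches a
maximal efficiency of $1.25\times10^{6}$ M$^{-1}$s$^{-1}$, a 1.59-fold
gain over the reference $7.86\times10^{5}$. On its positive-force rows
the efficiency–dissipation relation is tightly linear: the
free-intercept fit gives $R^2 = 0.952$ here versus $0.944$ reported for
the same construction in the literature — the published subset boundary
for "positive force" is not recoverable and sits a few rows below
$X_{tot}/RT = 0$, so the package uses the principled $X_{tot}/RT > 0$
cut and accepts the percent-level difference. $R^2$ is reported from a
free-intercept fit by default; the through-origin variant uses the
uncentered total sum of squares so that it stays in [0, 1].

A note on "perfect proportionality": for the coupled $k_7$–$k_8$
fixed-$K_4$ scan the specificity-to-dissipation ratio retains a
sub-percent drift (the six untouched constants do not rescale with the
pair), so its through-origin $R^2$ is about $1 - 4\times10^{-6}$ —
perfect at plot precision, not at machine precision. Exact invariance
of the ratio, to $10^{-10}$, belongs to the shared-draw
all-equilibria-fixed regime, and the tests distinguish the two.

`bestPoint()` breaks ties toward the earliest step so reports are
reproducible; `foldReport()` expresses a candidate state as fold
factors over the observed one. Published fold factors from noisy runs
depend on unavailable generator seeds, so the package's own stochastic
checks assert the property — severalfold co-increase of best efficiency
and dissipation under unconstrained per-constant noise at $10^4$
samples — rather than exact folds.

## The discrete stochastic simulator

`abmRun()` is a tick-based, integer-count simulator of the same cycle:
per tick and per enzyme state, the molecules taking the forward and
backward transitions are drawn from one multinomial with per-molecule
probabilities $k \cdot \Delta t$ (binomial thinning, tau-leaping-like),
with pseudo-first-order rates recomputed from the current free-ligand
counts. This is a deliberate reimplementation of the agent-based
tradition on the model's own terms: per-agent random walks are not part
of the model's evidence base, while multinomial ticking preserves the
stated per-tick semantics, exact integer conservation of both enzyme
forms and ligands (hard assertions, not tolerances), and convergence to
the master equation. The buffer in the carbonic anhydrase scheme is
held at its fixed concentration (well-buffered: 50 mM against
micromolar turnover). A stability bound $\max_i k_i \Delta t \le 0.1$
is enforced with an actionable error. Draws exceeding the available
free-ligand count are clamped and counted.

One global `countsScale` (molecules per molar) maps counts to
concentrations for every species — the reference count set
(S, P, E) = (40000, 64, 50) at $10^9$ per M corresponds to 40 µM,
0.064 µM and 0.05 µM. Per-tick observables are evaluated from the
nominal rates at the current concentrations via the deterministic
closed forms, not estimated from stochastic counts.

Because enzymes start free, product release lags while the complexes
fill, so the whole-run conversion average (`abmFluxEstimate()`)
underestimates the steady flux by roughly the pipeline fill.
`abmFluxSlope()` fits the free-product count over the later half of the
run instead and is unbiased; with $5\times10^4$ enzymes and 4000 ticks
of 1 µs it recovers the deterministic $J = 14.42\ \mathrm{s}^{-1}$
within Monte-Carlo error (the convergence test uses four seeds and a
three-standard-error band).

## What the generator emulates, and what it does not

The synthetic exploration machinery emulates quasi-steady-state
jumping: each scan row or noisy draw is an independent steady state of
the instantaneous rate constants. It does not emulate temporal
correlation of fluctuations (dynamic disorder), crowding, spatial
structure, or physically derived noise kernels; the noise is a
sampling device for rate-constant space, exactly as in the tradition it
models. Passing tests therefore demonstrate the thermodynamic
structure of the model — proportionality regimes, force bookkeeping,
conservation — not fidelity to any particular cellular noise source.
Multi-cycle free-energy transducers (pumps, motors) are out of scope.

## Problem sizes and numerics

Default study sizes follow the reference constructions: 1000-step
deterministic scans, $10^3$–$10^4$ noisy samples, $10^3$–$10^4$ ticks
for stochastic runs. The test suite scales the heaviest checks to run
comfortably on one CPU (3000 random solver-equivalence cases, one
$10^4$-sample noisy run, four stochastic replicates); these sizes are
the package's own choices and match the regimes the reference results
were computed in. Diagram sums are accumulated in double precision —
rate magnitudes up to $10^9$ give tree products up to about $10^{36}$
for four states, far inside double range. Degenerate inputs
(nonpositive rates, empty masks, zero substrate, empty tables,
degenerate fit abscissae) raise typed errors rather than propagating
NaN.
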