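---
title: "Compositional disorder as an early-warning signal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional disorder as an early-warning signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodisorder)
```

## The scientific problem

Communities of species competing for similar resources reorganise in a
characteristic sequence as environmental forcing intensifies.  Three
functional roles structure that sequence:

* **keystones** — slow self-replication compensated by strong
  competitive dominance; they regulate everything beneath them;
* **weeds** — fast self-replication at the cost of weak competitive
  ability; they bloom when regulation fails;
* **canaries** — slow self-replication *and* weak competitive ability;
  fugitives that deliver no impact on anyone and are the first
  casualties of degradation.

As habitat quality declines, canaries go first, keystones prevail for a
while, and the eventual keystone collapse releases the weeds in a
critical transition to a different sustained state.  Identifying these
roles taxon-by-taxon is rarely possible in fossil data, but a
community-level signature is visible without any taxonomy: while
keystones prevail, fluctuations of *compositional disorder* (the
nestedness temperature of a sliding window of samples) and of
*biodiversity* (Hill's N2) run in opposite phase, so the correlation of
their first differences turns negative; when weeds take over it turns
positive again.  The package implements the full chain: the
deterministic competition model, a stochastic community simulator, the
disorder and diversity measures, the sequential correlation diagnostic,
and break-point detection.

## The competition model

Each species has pre-competition birth and death rates $c_i$ and $d_i$
(per unit time), an intrinsic lifetime fitness $R_i = c_i/d_i$, and a
habitable-environment fraction $h_i \in [0, 1]$.  Species $j$ impacts
species $i$ at per-capita rate $\alpha_{ij}$, calibrated against the
intraspecific impact $\alpha_{ii} = 1$.  Abundances $n_i$ are fractions
of pristine capacity and obey

$$\dot n_i = \Big[c_i\big(h_i - \textstyle\sum_j \alpha_{ij} n_j\big) - d_i\Big]\, n_i ,$$

with carrying capacity $k_i = h_i - d_i/c_i$ before interspecific
competition.  The published rendering of this rate equation is
typographically ambiguous; the form above is the unique reading
consistent with $k_i = h_i - d_i/c_i$ and with the two-species
equilibrium
$n_i^\* = (k_i - \alpha_{ij} k_j)/(1 - \alpha_{ij}\alpha_{ji})$,
so it is the one implemented (`growth_rate()`, with the closed forms in
`pairwise_equilibrium()` and `fugitive_equilibrium()`).

Equilibria are clipped at zero: a species whose formula value is
negative is excluded, and its competitor rests at its own $k$.  A
fugitive (canary) with $\alpha_{13} = \alpha_{23} = 0$ coexists at
$n_3^\* = k_3 - \alpha_{31} n_1^\* - \alpha_{32} n_2^\*$.

```{r lv}
ex <- three_species_example(h = 1)
pairwise_equilibrium(ex$traits, ex$alpha)$n_star
scan <- extinction_scan(ex$traits, ex$alpha)
scan$thresholds
```

Numerics: `integrate_to_steady_state()` uses `deSolve::lsoda` with
geometric checkpoints, declares steady state when
$\max_i |\dot n_i| < 10^{-9}$ (horizon $10^5$ time units), and never
returns negative abundances.  Extinction thresholds treat an
equilibrium below $10^{-8}$ as extinct and refine the crossing in $h$
by root-finding to $10^{-6}$.  The same $h$ is applied community-wide
in scans — degradation hits everyone — though per-species $h$ is
supported by the types.

## Nestedness temperature ("degrees of disorder")

A 15-sample window of the community is coded as an $m \times n$ 0/1
incidence matrix (presence = abundance strictly above 0; an optional
minimum-percentage threshold exists but is off by default).  Species
absent from the whole window are dropped — they carry no information
for that window — while empty samples are kept, because an empty sample
is an observation.  The matrix is packed canonically: rows by richness,
columns by incidence, both descending, with deterministic tie-breaks
(incidence-weighted orthogonal marginal, then the 0/1 pattern, then
label), so any row/column permutation of the same data packs to the
identical matrix.

In the packed unit square (cell centres $x = (i-0.5)/m$ down the rows,
$y = (j-0.5)/n$ along the columns), presences are expected on one side
of the **fill line**, the superellipse $x^p + y^p = 1$.  Its exponent
solves $\int_0^1 (1-(1-x)^p)^{1/p}\,dx = \phi$ for the observed fill
$\phi$ (the two integrals are equal by symmetry), by monotone
bracketing on $\log p$ to $10^{-8}$ in area.  A cell on the wrong side
of the line is a **surprise** only if it also witnesses a genuine
violation of nestedness in the packed matrix — a presence with an
absence above it in its column or to its left in its row, or dually for
absences.  Each surprise is scored by its squared distance from the
fill line along the slope-one diagonal through the cell, normalised by
that diagonal's length inside the square, and

$$T = \frac{100}{0.04145} \cdot \frac{1}{mn} \sum_{\text{surprises}} d^2 ,$$

capped at 100, where 0.04145 is the mean squared normalised deviation
of the theoretical maximally unexpected matrix — the standard
calibration of the nestedness-temperature lineage, so a checkerboard
scores in the 90s and a random half-filled matrix near 60.

Two design choices deserve emphasis.  First, the structural-violation
condition makes every subset-chain matrix score **exactly** 0°.  A pure
fill-line rule cannot do that: the fill-line family has one shape per
fill, while subset chains have arbitrary richness staircases, so some
perfectly nested cells always land on the "wrong" side of the smooth
line and legacy implementations return small nonzero temperatures for
perfectly nested data.  Treating those cells as surprises would measure
the mismatch between a staircase and a one-parameter curve family, not
disorder.  Second, packing is the canonical marginal sort stated above,
not a heuristic optimisation.  The widely used reference implementation
(`vegan::nestedtemp`) instead optimises an incidence-weighted objective
with randomised tie-breaking, which leaves non-monotone marginals on
essentially every random matrix.  With identical packing the two
scorings rank random matrices with Spearman correlation above 0.99
(this is a documented test); end-to-end, packing differences cap rank
agreement near 0.9.  Exact numerical parity with any legacy
implementation is therefore not promised — the invariants are: 0° for
subset chains, permutation invariance, boundedness in $[0, 100]$, and
monotone response to added surprises.

## Biodiversity

Hill's N2 — the effective number of common species — is computed on
square-root transformed percentage abundances:
$p_i = \sqrt{a_i} / \sum_j \sqrt{a_j}$, $N_2 = 1/\sum_i p_i^2$, so
$1 \le N_2 \le$ richness, with equality at perfect evenness.  Each
windowed disorder value is paired with the N2 of the window's *most
recent* section: the biodiversity resulting from that disorder.
Richness is carried alongside as a second channel throughout.

## The sequential correlation diagnostic

Both paired channels are first-differenced (the paleo series are
stationary only in the means of first differences, and differencing
removes any slow covariate that would otherwise masquerade as signal).
For each date, Pearson's product-moment coefficient is computed over
two partitions: the **pretransition** set — the 15 most recent paired
points, hence 14 usable difference pairs — and the **lead-in** set of
all strictly earlier difference pairs, reported once at least 5 exist.
A window of 15 *points* yields 14 *differences*; that reading is
adopted throughout.  Two-sided p-values use the t-transform of r with
$n-2$ degrees of freedom; no multiple-testing correction is applied
across dates, and the diagnostic is documented as exploratory.  A
zero-variance channel yields a missing coefficient, never zero.

Because every computation uses only section order — never the numeric
date values — all correlation outputs are exactly invariant under any
strictly monotone re-dating of the core.  Sediment compaction, or any
other distortion of the age-depth relation, cannot touch them; this is
asserted bit-for-bit in the tests.

The regime classifier formalises the narrative reading of the
coefficient pairs as an explicit rule table (defaults `strong = 0.3`,
`alpha = 0.05`; both are module settings, not published constants):
significantly negative pretransition coefficient at least `strong`
below the lead-in → keystone-favoured; significantly positive and above
the lead-in → weed-favoured; non-significant but at least `strong`
above the lead-in → canary-favoured (loosely interacting); anything
else indeterminate.

## Break points and forecasts

`stars_detect()` re-implements the sequential t-test regime-shift
algorithm from its published description: a candidate shift when a
value deviates from the current regime mean beyond the critical
difference of a two-sided t-test at level $\alpha$ with $2\ell - 2$
degrees of freedom ($\ell$ = cutoff, default 5), confirmed only if the
Huber-weighted regime-shift index stays positive over the next $\ell$
points (candidates too close to the series end cannot be confirmed and
are not reported).  Regime means are Huber-weighted with parameter 1 by
default.  The per-window noise scale uses the median (consistency-
corrected) of window variances rather than the mean, so the windows
that straddle a genuine shift do not inflate the threshold.

Serial correlation is handled by default with a variance-inflation
correction: the lag-1 coefficient is estimated from the autocorrelation
of first differences — insensitive to mean shifts, estimated by a
Huber-robust regression slope so the single outlying difference at a
break carries almost no weight — and the critical difference is
inflated by the exact factor for an $\ell$-point mean of AR(1) noise.
A prewhitening filter ($x_t - \hat\phi x_{t-1}$) is available but not
the default, because filtering shrinks a genuine step by $1-\phi$ while
shrinking the noise only by $\sqrt{1-\phi^2}$, costing real detection
power.  Exact numeric parity with the original regime-shift software is
not promised; calibration is asserted by simulation (false-alarm rate
near $\alpha$ on white noise; over 95% detection of a 3-SD sustained
step in AR(0.3) noise over 60-point series).

`fit_forecast()` is plumbing around `stats::arima`: the differencing
order comes from a Phillips-Perron unit-root test on the pre-split
segment, AR/MA orders from AIC over a small grid, and post-split
observations falling outside the 95% prediction interval flag a
transition-consistent excursion.

## The stochastic community simulator

The agent-based simulator renders the rate equation in discrete
stochastic form.  In a timestep of length `dt` (default 0.5), each
individual dies with probability `dt * d(t)` and each survivor
reproduces with probability
`dt * c_i * max(0, h - sum_j alpha_ij * n_j / capacity)`, so the
expected per-capita change matches the deterministic rates to first
order in `dt` (asserted against the exact one-step expectation in the
tests).  The community is well-mixed and open: every timestep one new
species may invade (default probability 1 per step, 6 founding
individuals), drawing its role uniformly — canaries' rapid extinction
then *emerges* from their traits rather than being imposed.  Impacts
come from a role-pair base table (keystones deliver 1.5 onto weeds and
receive 0.01; canaries receive 0.5/0.3 and deliver exactly 0; within-
role competition 0.7) scaled by per-species multipliers drawn from
[0.9, 1.1].

The forcing schedule has three consecutive periods (default 240, 360,
360 steps after a 150-step equilibration burn-in): constant death rate
$d_0 = 0.10$; a deterministic square-wave toggle of amplitude 0.06
around the same mean; and the same toggle around a mean rising to 0.45.
A stochastic toggle mode (random block signs) is available; the
deterministic square wave is the default.  The toggle half-period (90
steps) matches the span of one 15-census disorder window, so the
windowed temperature responds to the toggle without lag — with shorter
toggles the window integrates over the forcing and the correlation
washes out.  Censuses are taken every 6 steps; each replicate's
°disorder series (15-census windows) is paired with same-census N2,
first-differenced, and correlated within each period; 15 replicates are
aggregated with Student-t 95% confidence intervals.

The community capacity default (600 individuals) is deliberately small:
the diagnostic's positive baseline correlation under constant forcing
comes from invasion-extinction turnover moving richness and disorder
together, and each arrival must be large enough *as a fraction of the
community* to register in N2.  At capacities of a few thousand the
arrivals vanish into the percentages and the baseline correlation sits
at zero.  These defaults reproduce the qualitative period signature —
correlation non-negative under constant forcing, negative under
toggling, positive under toggling-and-rising forcing, with weeds
overtaking keystones in period 3 and canaries always rarest — which is
the acceptance surface; magnitudes are not calibrated to anything.

## Synthetic cores

`generate_core()` produces dated, depth-tagged community series with a
*known* disorder-biodiversity phase relation, so the whole diagnostic
chain is testable end to end without any external data.  The design
emulates: multi-decadal cores with unequal date increments (a
compaction mode widens old increments; `perturb_dates()` re-maps dates
of any core monotonically), persistent versus ephemeral species, and
alternating ordered-accumulation / disordered-turnover phases.

Three lessons from failed simpler designs shaped the generator; they
are worth recording because they are properties of the measures, not of
the implementation.  (1) The windowed temperature is an integral over
15 sections, so it *lags* any per-section driver; with a forcing cycle
equal to twice the window length the lag vanishes (the window-count of
disordered sections becomes triangular with extrema at the phase
boundaries), hence the default cycle of 30 sections.  (2) Loss of
random *identity* without re-entry is still nested — shrinking subsets
form subset chains — so "disordered loss" must churn composition
(members flicker out and are replaced), not merely shrink it.
(3) Richness-driven biodiversity alone decouples from the temperature
in first differences; the generator therefore holds section richness
roughly constant and drives N2 through evenness: a bloom-forming
dominant whose weight is solved per section (a quadratic in its
square-root weight) so that N2 hits a deterministic target, linear in
the same trailing-window flicker fraction (concave exponent 0.4) that
the temperature responds to.  In anti-phase mode N2 falls to a floor of
2.5 effective species at peak turnover; in-phase mode reverses the
target; disordered mode draws it at random.

With the defaults (8 persistent + 24 ephemeral species, churn 0.5,
observation noise 0.005), anti-phase cores of 90 sections yield a
significantly negative final pretransition coefficient in 93 of 100
seeds, and in-phase cores the positive mirror image — the generator's
defining contract.  What passing these tests shows about real data is
deliberately limited: the generator produces the phase structure the
diagnostic looks for, so the tests verify *recovery*, not ecological
realism; taxon-specific dynamics, seasonality, and mixed or drifting
phase relations are all outside its scope.

## Problem sizes and reproducibility

Every stochastic component is seed-deterministic (`with_seed`
restores the caller's RNG state).  The test suite uses: 100 random
communities for the equilibrium/ODE cross-check, 1000 random matrices
for the temperature bounds, 100 seeds per phase mode for signal
recovery, 20 simulator seeds of 15 replicates for the period sign
pattern, and 1000 simulated series each for the break-point
calibration and detection checks.  `scripts/acceptance.R` regenerates
the nested-matrix fixture from the supplied seed and recomputes its
temperature through the full pipeline.

## Known limitations

* Temperatures are not numerically interchangeable with legacy
  nestedness-temperature software (packing and the subset-chain-exact
  zero differ by design, as documented above).
* The closed-form community equilibrium covers the two-residents-plus-
  fugitives structure of the conceptual model only.
* Abundance-dependent impact coefficients (which can produce
  discontinuous switches between stable states) are not modelled.
* The regime rule table is an explicit formalisation of a narrative
  criterion; its `strong` margin is a tunable default, and labels
  should be read as hypotheses, not detections.
* `stars_detect()` reports no break within `cutoff` points of the
  series end, by construction.
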