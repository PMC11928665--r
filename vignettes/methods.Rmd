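---
title: "Phase models, outlier down-weighting and density summaries: the methods behind chronophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase models, outlier down-weighting and density summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronophase)
```

## What the package computes

chronophase turns determination-level radiocarbon compilations into
calendar-age chronologies. Three layers of machinery stack up:

1. **Calibration** maps a conventional radiocarbon age (CRA) x ± σ onto a
   discrete calendar-age PDF through a piecewise-linear calibration curve
   μ(θ) ± σ_c(θ).
2. **Phase models** combine many calibrated likelihoods with archaeological
   structure — unordered groups (phases) delimited by start/end boundaries,
   optionally ordered within sequences — and are sampled by
   Metropolis-within-Gibbs.
3. **The timeline pipeline** applies this per site, feeds the site-level
   posteriors into category-level single-phase models, and compares the
   resulting start boundaries against the Antarctic Cold Reversal
   (14,500–13,000 cal BP) and Younger Dryas (13,000–11,700 cal BP), both
   entered as fixed uniform intervals.

All ages are in cal BP (years before AD 1950), larger = older.

## The likelihood

Calibration uses the error-in-variables density

$$p(\theta \mid x) \propto
  \frac{\exp\{-(x-\mu(\theta))^2 / 2(\sigma^2+\sigma_c(\theta)^2)\}}
       {\sqrt{\sigma^2+\sigma_c(\theta)^2}},$$

evaluated at the centres of a regular grid (default 5 yr — an order of
magnitude below the 10-yr reporting convention, at negligible cost) and
normalised. The 1/√(σ²+σ_c²) factor matters on steep curve segments and is
standard practice. Grid cells are globally aligned at resolution·(k+½), so
every PDF the package produces can be conformed cell-wise with every other.
A determination whose support misses the curve entirely raises an error:
silent truncation would bias boundary estimates, so out-of-range is always
fatal.

Marine dates subtract a local reservoir offset ΔR from the CRA and add its
uncertainty in quadrature (positive ΔR = locally older water). Sites inside
the hemispheric mixing band (default 25° S to 15° N, configurable) use a
uniform curve mixture: stand-alone calibration marginalises the mixing
fraction m ~ U(0,1) by midpoint quadrature (101 nodes; at least 21), while
inside the MCMC m is a per-determination latent parameter updated by
Metropolis, which is exact rather than approximate.

Chronometric ages already on the calendar scale (OSL, U-series) enter as
normal likelihoods directly and never pass through a curve.

## Priors and the uniform phase

Given boundaries a > b, a phase's n events are i.i.d. U(b, a). We adopt the
standard uniform-span construction: the joint prior over (a, b, t₁…tₙ) is
proportional to (a−b)^−(n−1) on the ordered support, which is equivalent to
events uniform given the boundaries with the group span itself near-uniform
— without it, longer phases would be penalised simply for containing more
dates. The alternative reading (flat prior on the boundary pair, joint
exponent −n) is available as `span_prior = "naive"` and is exercised by
`sensitivity_run()`. All parameters live inside a support window, by
default the union of the event likelihood supports (the calibration curve's
span for radiocarbon events); a likelihood-free model must state its window
explicitly.

**Outliers.** Every dated event may carry an outlier attachment. The
calendar-scale preset (`general`, the workhorse) activates with prior
probability 0.05 — the conventional platform default, exposed in
`sampler_settings(outlier_prior=)` — and shifts the event by t₅-distributed
noise scaled by 10^u years with u ~ U(0,4) shared across the model. The
measurement-scale preset (`ssimple`) shifts the CRA by standard-normal
multiples of its quoted σ and is reserved for replicate measurements;
replicates (shared sample id) are pooled by inverse-variance weighting
first, with the chi-square consistency statistic T = Σ(xᵢ−x̄)²/σᵢ² reported
against the 5% quantile at n−1 degrees of freedom.

## The sampler

Compiled Metropolis-within-Gibbs, one parameter at a time per sweep:

* event and boundary ages: random-walk Metropolis, truncated by the order
  constraints (sequence chain, boundary containment);
* outlier indicators: for `ssimple`, collapsed Gibbs with the shift
  integrated out analytically (it is conjugate), then an exact normal draw
  of the shift; for `general`, a Metropolized joint flip that proposes the
  shift from a griddy data-informed density spanning the window, so a
  grossly offset date can activate in a single move rather than waiting for
  the age and shift to co-adapt;
* a likelihood-preserving swap between an active event's age and its shift
  (the effective age t + δ is held fixed), which lets a contaminated date
  relocate into the phase bulk so the boundaries can contract;
* the shared log₁₀ scale u and the mixing fractions m: random-walk
  Metropolis with reflection at their bounds.

Proposal scales are tuned toward 0.2–0.5 acceptance during the warm-up
(default 30,000 iterations, checked every 200) and frozen afterwards, so
every retained sample comes from a fixed kernel satisfying detailed
balance. Initial values are the events' calibrated medians, boundaries one
grid cell outside their group, with a monotone repair pass along the
sequence; an impossible ordering raises an error naming the offending pair.

All randomness flows through R's RNG, so `set.seed()` makes a run
bit-identical on one platform and statistically equivalent elsewhere. This
was chosen over a hand-rolled counter-based per-parameter stream: it
delivers the reproducibility that matters while keeping the package on the
standard RNG infrastructure.

**Convergence.** `check_convergence()` follows the pass protocol: after the
warm-up, passes of 3,000 retained iterations accumulate, and after each
pass every continuous parameter's marginal is estimated twice — from the
first and the second half of the accumulated chain — and the overlap
integral ∫min(f̂₁, f̂₂) computed from kernel density estimates on a shared
grid. The run stops when the minimum overlap exceeds 0.95, doubling the
pass interval while it does not, up to a hard cap (2²⁰ iterations) that
flags rather than fails. Sequential halves were chosen over interleaved
ones deliberately: interleaved halves of a drifting or slowly
mode-switching chain are nearly identical and would report spurious
convergence, which is precisely the pathology the check must catch. A
zero-variance (frozen) chain scores 0 for the same reason.

## Density summaries

`sum_distribution()` is the cell-wise average of PDFs — quick, noisy, no
dependence model. `kde_model()` is the model-based summary: each event's
true age is a parameter constrained by its PDF, the ages are treated as
dependent draws from a normal-kernel density of each other (leave-one-out),
and the bandwidth is h = s·h_Silverman with shaping factor s ~ U(0,1)
updated by Metropolis against the KDE pseudo-likelihood. Snapshots of the
kernel density are recorded every 10 retained iterations (the cadence
behind the snapshot mean ± 1σ band; the exact cadence is a free choice and
this one keeps snapshots nearly independent at the default iteration
counts).
The point estimate is the snapshot mean. Silverman's rule is
h = 0.9·min(s, IQR/1.34)·n^(−1/5).

`difference()` cross-correlates two mass vectors under independence and
reports P(a − b > 0), counting half of the zero-lag cell so identical
symmetric inputs give exactly ½; positive means the first argument is
older. `overlap_probability()` partitions a start posterior's mass into
before/within/after a named interval; the ACR/YD presets are fixed
constants, never sampled.

## Site rules and category integration

`site_model_from_record()` applies three mutually exclusive rules per site:
(1) dated stratigraphic levels with a known total order become a sequence
of boundary-delimited uniform phases — the whole site is modelled,
including layers outside the analysis window, because neighbouring layers
constrain each other; (2) two or more dates without a usable order become a
single uniform phase ("usable" is operationalised as a recorded total order
over ≥ 2 dated layers — anything weaker, including partially floating
layers, falls to rule 2); (3) a lone cultural measurement passes through as
its calibrated PDF, unmodelled. Sediment/geological ages participate as
constraints but are never cultural components. Component age estimates for
rules 1–2 are Date queries: uniform draws between the current boundary pair
at each retained iteration, which is exactly the posterior of an undated
event in the phase.

A component joins the analysis set when its 95.4% range intersects
14,500–11,700 cal BP; the inclusion window is a package decision (no
numeric rule is published for it) and is a visible parameter of
`run_site_stage()`. Category models are single uniform phases whose event
likelihoods are the component PDFs; a component with several lithic labels
enters each corresponding category once; the high-altitude threshold is
≥ 2,500 m a.s.l. (inclusive); the poleward subset keeps components strictly
south of 40° S. Start-boundary posteriors are lightly kernel-smoothed
(default 3 grid cells = 15 yr) before interval extraction, so single-cell
histogram noise cannot fragment the reported intervals; reported CIs are
the hull of the 95.4% HPD set, rounded to 10 years, printed older →
younger, with the possibly disjoint set kept alongside. Overlap
probabilities are reported raw, with no multiple-testing correction —
they are descriptive quantities, and thresholding them into overlap/no
overlap verdicts is left to the analyst.

## The synthetic generator

Tests and the acceptance script run entirely on synthetic data with known
truth. `gen_calibration_curve()` builds μ(θ) = θ plus an AR(1) wiggle
(correlation 0.95 at the knot spacing, stationary sd = `wiggle_sd`), with
per-knot errors within ±20% of `error_level`. `gen_site()` draws event ages
uniformly within true layer spans and pushes them through the curve with
measurement noise; a configurable fraction is further shifted by
calendar-scale contamination. `gen_database()` assembles ~150 sites and
(typically) 1,800–2,000 ages in the loader schema, with the reporting gaps
the real compilation documents: C:N ratios reported for 11% of bone dates,
charcoal species unreported for 94%, >90% of ages radiocarbon. Province
proportions, coordinates, altitudes and the ~21 megafauna-flagged
components mirror the published dataset's shape; where the source gives no
per-category sizes these mixes are invented and documented as such. Truth
tables are written separately from the database CSV so the pipeline can
never see them.

What the generator does **not** emulate: spatial autocorrelation of sites,
laboratory inter-comparison offsets, curve plateaus of the real IntCal
family, and heaping of archaeological attention on famous sites. Passing
tests therefore demonstrate that the machinery recovers known structure
under realistic noise and missingness — not that any particular real-world
estimate is correct.

## Problem sizes and numerical choices

The shipped test-suite and acceptance-script sizes are the package's
choices for routine verification: site-level and category-level MCMC at
2,000–15,000 warm-up / 6,000–20,000 retained iterations, the
coverage check at 100 replicates of 20-event phases, the KDE recovery at
170 components, the end-to-end run at 60–150 sites. The statistical
defaults (30,000 warm-up, passes of 3,000, threshold 0.95) remain the
documented protocol and are what `sampler_settings()` returns.

Ties in HPD extraction break toward older ages. Interval rounding moves
half-way endpoints outward so coverage never shrinks. The `difference`
computation trims to the joint support before cross-correlating. The
category stage needs no calibration curves (its likelihoods are already
calendar PDFs), so its registry is empty.

## Known limitations

* Sparsely dated layers give outliers leverage: with ~5 dates in a phase
  the span prior's penalty for stretching is weak, and a +2,000-yr
  contaminant may be absorbed by widening rather than down-weighted. With
  ~8–10 dates per phase activation is near-certain. This mirrors the
  general point that single-date layers yield accurate but imprecise
  estimates; the pipeline flags low-n categories (n < 5).
* Nested multi-sequence trees and non-uniform phase shapes (trapezoids,
  exponential boundaries) are out of scope; `validate_model()` accepts
  general trees but the sampler compiles only single-sequence models.
* Agreement indices of the reference platform (A_model etc.) are not
  computed; convergence overlap and outlier posteriors are the diagnostics.
* The start boundary of a small, unconstrained category has a long old
  tail (visible in poleward-of-40°S runs): that is the honest posterior
  under the span prior, not an artefact to be clipped.
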