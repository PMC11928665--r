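# chronophase

Bayesian chronological modelling of radiocarbon dates in R: calibration,
uniform phase models with start/end boundaries and outlier down-weighting,
MCMC kernel-density summaries of date sets, and a multi-site pipeline that
estimates when human activity began per category of archaeological evidence
relative to the Antarctic Cold Reversal (ACR, 14,500–13,000 cal BP) and the
Younger Dryas (YD, 13,000–11,700 cal BP).

## Who this is for

Archaeologists and chronologists who need to turn determination-level
radiocarbon compilations (lab ID, CRA ± error, material, stratigraphic
unit, site metadata) into statistically defensible calendar-age timelines —
the kind of analysis usually run through OxCal-style platforms — with every
step scriptable, testable and reproducible from R.

## The model

A conventional radiocarbon age x ± σ is related to calendar age θ (cal BP)
through a calibration curve μ(θ) ± σ_c(θ) by the error-in-variables
likelihood

    p(x | θ) ∝ exp( −(x − μ(θ))² / 2(σ² + σ_c(θ)²) ) / sqrt(σ² + σ_c(θ)²).

Marine samples are corrected by a local reservoir offset ΔR (mean
subtracted, uncertainty added in quadrature); sites in the hemispheric
mixing band are calibrated under a uniform mixture m·μ_N + (1−m)·μ_S with
m ~ U(0,1).

Groups of events form **uniform phases**: given a start boundary a and end
boundary b, events are i.i.d. U(b, a), and the joint prior over (a, b,
events) is proportional to (a−b)^−(n−1) on the ordered support, so the
group's span is not penalised by its own sample size. Sequences order
phases (and bare events) oldest to youngest. Any dated event may carry an
outlier attachment: with prior probability 0.05 the event is shifted on the
calendar scale by t₅-distributed noise with scale 10^u yr, u ~ U(0, 4), so
misfitting dates are down-weighted rather than discarded. The posterior is
sampled by Metropolis-within-Gibbs (compiled core), with convergence
assessed by the overlap of half-chain marginal densities (threshold 0.95)
in passes that grow geometrically from 3,000 iterations.

Sets of related dates are summarised two ways: a plain Sum (cell-wise
average) and an MCMC kernel density model (normal kernel, Silverman
bandwidth h = 0.9·min(s, IQR/1.34)·n^(−1/5) scaled by a U(0,1) shaping
factor, events treated as dependent), which resists the over-smoothing of a
fixed-bandwidth KDE.

## Worked example

```r
library(chronophase)
set.seed(7)

# a synthetic southern-hemisphere calibration curve and ten dates from a
# uniform phase truly spanning 14000-13000 cal BP
curve <- gen_calibration_curve(c(20000, 8000), 20, wiggle_sd = 15,
                               error_level = 15, seed = 11,
                               label = "south", hemisphere = "south")
site <- gen_site(list(c(14000, 13000, 10)), curve, lab_error = 35,
                 site = "DEMO", seed = 12)

events <- lapply(seq_len(nrow(site$ages)), function(i)
  cal_event(site$ages$lab_id[i],
            det = determination(site$ages$cra[i], site$ages$error[i],
                                curve_key = "south"),
            outlier = outlier_spec("general", 0.05)))
model <- cal_sequence("DEMO", cal_boundary("start"),
                      do.call(cal_phase, c(list("occupation"), events)),
                      cal_boundary("end"))

trace <- sample_posterior(model, list(south = curve), sampler_settings())
start <- smooth_pdf(posterior_pdf(trace, "start"))
round_interval(hpd_interval(start, 0.954))
#>      older younger
#> [1,] 14520   13820
#> [2,] 13770   13510
```

The brackets are the 95.4% highest-posterior-density set for the start
boundary, rounded to 10 years and printed older → younger in cal BP. It
splits into two ranges because the synthetic curve wiggles near the phase
onset (the radiocarbon analogue of a plateau); the hull 14,520–13,510
covers the true start of 14,000 used to simulate the data. Against the ACR
preset:

```r
overlap_probability(start, interval_definition("ACR"))
#>   p_before   p_within    p_after
#> 0.04116719 0.95883281 0.00000000
```

i.e. the phase most likely began during the ACR. The full pipeline
(`load_database()` → `assign_curves()` → `run_timeline()`) applies the same
machinery per site (multi-phase, single-phase or single-date, depending on
the stratigraphic record), then integrates the component posteriors into
category-level single-phase models (province, lithic technology, altitude
≥ 2,500 m a.s.l., megafauna exploitation) and reports each category's start
interval with its ACR/YD overlap probabilities.

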