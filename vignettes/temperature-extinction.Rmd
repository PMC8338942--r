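---
title: "Quantifying temperature change and marine extinction across deep time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temperature change and marine extinction across deep time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermext)
```

## The question and the procedure

Abrupt climate change — warming and cooling alike — is a leading candidate
mechanism for marine mass extinction. `thermext` quantifies that link over
stage-level time bins of the Phanerozoic by chaining four analyses:

1. **Proxy to SST.** Geochemical proxy measurements (carbonate and conodont
   $\delta^{18}$O, TEX$_{86}$) are screened with the standard literature
   rules and converted to sea-surface temperature through linear
   calibrations whose coefficients carry Gaussian uncertainty, propagated
   by Monte Carlo. The conodont phosphate thermometer is
   $$\mathrm{SST} = 118.7(\pm 4.9) - 4.22(\pm 0.20)\,
     (\delta^{18}O_{con} - \delta^{18}O_{sw}),$$
   with $\delta$ in per mil. Seawater $\delta^{18}O_{sw}$ is $-1$‰ (VSMOW)
   in ice-free intervals and $+1$‰ during glacial maxima, overridable per
   bin.
2. **Largest excursion per bin.** Within each bin the largest temperature
   excursion is located and summarised by its magnitude
   $\Delta T = T_1 - T_0$, duration $\Delta t = t_0 - t_1$ (ages in Ma
   decrease toward the present, so durations are positive) and rate
   $R = \Delta T / \Delta t$, with Monte Carlo uncertainties from the data
   scatter around the endpoints.
3. **Extinction rates.** Genus-level occurrence records yield per-bin
   extinction rates through the gap-filler and three-timer estimators,
   $$r_{GF} = \ln\!\frac{2T + pT}{3T + pT + GF}, \qquad
     r_{3T} = \ln\!\frac{2T_i}{3T} + \ln\!\frac{3T}{3T + pT},$$
   where $2T_i$, $3T$, $pT$ and $GF$ count genera present in consecutive
   bins, present across a gap, and so on. "log" is the natural logarithm,
   as in the three-timer literature these estimators come from.
4. **Statistics.** Spearman rank correlations relate $|\Delta T|$ and
   $|R|$ to the extinction rates over all bins and over the standard
   subsets (warming only, cooling only, excluding the Big-Five bins,
   excluding deep-water records, rates below 10&nbsp;°C/Myr), with
   confound checks (bin duration vs extinction; $|\Delta T|$ vs event
   timespan), a Fisher-z / Pearson–Filon comparison of the warming and
   cooling coefficients, autocorrelation checks, and classification of
   each event against the mass-extinction thresholds
   ($|\Delta T| > 5.2$&nbsp;°C and $|R| > 10$&nbsp;°C/Myr, strict).

## Event detection in detail

A bin's series is lightly smoothed (running median, window 3) and every
ordered sample pair is scanned. A pair is a feasible excursion if the
smoothed series between its endpoints never reverses against the trend by
more than one third of the candidate magnitude — this keeps two opposite
excursions from being chained into one. Among feasible pairs the largest
absolute smoothed difference wins; exact ties go to the shorter duration
(the faster event).

Because the magnitude-maximal pair under noise tends to grab extreme
samples far out on the flat approaches, the endpoints are then localised:
among feasible pairs within a noise-sized slack of the maximum (three
robust noise SDs, estimated from successive differences, capped at 20% of
the maximum), the shortest-duration pair is selected. A noise-free series
has zero slack, so clean data keep the exact maximal pair.

$T_0$ and $T_1$ are means of the `endpoint_group_size` (default 3) samples
nearest each endpoint *on its outer side* — at or before the onset, at or
after the termination — so each group averages locally flat data rather
than the ramp itself. Uncertainties resample each endpoint group with
replacement, perturb each draw by its per-sample SST standard deviation
(and its age within bounds, when bounds are supplied), and recompute
$\Delta T$, $\Delta t$ and $R$ per draw; the duration uncertainty
therefore combines endpoint-group spread with age-model width, and draws
with non-positive duration are dropped and counted.

Degenerate inputs behave predictably: a constant series yields a zero
event flagged `degenerate`; fewer than `min_samples` (default 4) samples
yield no event and the bin is excluded downstream, as is any bin failing
the resolution screen of 2 measurements per Myr.

Events that cross a bin boundary belong to the bin containing their onset
(the older bin) and are flagged: short boundary excursions start near the
end of the older bin and impact its fauna first. An onset exactly on a
shared boundary age also goes to the older bin (half-open convention).
When several proxy series cover one bin, events are detected per series
and their $\Delta T$, $\Delta t$, $R$ averaged (signed), with standard
deviations combined in quadrature over the series count.

## Screening rules and their cut-offs

All rules use strict inequalities — a value exactly at a cut-off is
retained. Carbonate trace-element diagenesis rejects on the conjunction
[Mn] > 250 ppm **and** [Sr] < 400 ppm (a config switch allows OR);
evaporite or upwelling facies reject outright; the tropical window rejects
|paleolatitude| > 40° with a per-sample override list (one mid-latitude
site at 42.71°N is legitimately retained this way). TEX$_{86}$ samples are
additionally screened on BIT > 0.4, MI > 0.5, $\Delta$RI > 0.3,
%GDGT-0 > 67 and fCren′ > 0.25, with the ring index computed as the
abundance-weighted mean ring count and RI$_{TEX}$ as the published
quadratic $-0.77\,x + 3.32\,x^2 + 1.59$. A rule whose inputs are missing
is skipped and logged, never fired.

## The calibration simplification

The compiled analysis this package operationalises used Bayesian
calibration models for carbonate $\delta^{18}$O and TEX$_{86}$. Those are
replaced here by configurable linear calibrations with Gaussian parameter
uncertainty: the pipeline's uncertainty structure (per-measurement SST
standard deviations feeding event detection) is preserved, and the
coefficients live in configuration so a user can emulate any published
model's central tendency. The conodont equation's printed form multiplies
the $\delta$ difference by 1000; applied to per-mil inputs that yields
physically absurd temperatures, so the factor is read as converting
fractional $\delta$ to per mil and the implementation computes the
published per-mil form directly. Intercept and slope draws are taken as
independent; the source calibration publishes no parameter covariance.

## What the synthetic generators emulate

`generate_climate_series()` builds each bin as baseline SST plus an
optional ramp excursion (signed magnitude over a duration, onset defaulting
to 60% through the bin) with Gaussian measurement noise, sampled at a
background density (default 3/Myr, comfortably above the 2/Myr screen)
plus a high-resolution window across the event — emulating how boundary
events are studied in densely sampled sections. After the ramp the signal
holds briefly, then recovers 60% of the way to baseline, so the recovery
limb is strictly smaller than the ramp and the injected event is
unambiguously the largest. The truth table records the injected
$(\Delta T, \Delta t, R)$.

`generate_occurrences()` simulates genus lifespans forward: a genus extant
in bin $b$ dies before $b+1$ with probability $q_b$, richness is topped
back up by origination (stationary richness isolates the extinction
signal), and extant genera are sampled with a fixed probability. Coupling
to climate uses a logistic link on the *standardised* event magnitudes,
$q_b = \mathrm{logit}^{-1}(\mathrm{logit}(q_0) + \beta z_b)$: the
standardisation keeps $q_b$ away from the degenerate ends of (0,1) — where
cohort counts vanish and the estimators blow up — whatever the °C scale of
the injected events, and gives $\beta$ a unit-free meaning. With perfect
sampling the expected gap-filler rate is $-\ln(1-q)$, which the tests
verify. One bin before and two after the scheme are simulated as padding
(ids `pre1`, `post1`, `post2`), mirroring a real occurrence download that
extends beyond the temperature window; without padding the scheme's edge
bins have undefined rates, which is also the behaviour the estimators
report.

`generate_gdgt()` emits compositions that pass every screening rule
(jittered around a composition solved to sit well inside all cut-offs)
plus contaminated variants, each constructed to violate exactly one named
rule while every other index keeps a margin.

What the generators do **not** emulate: preservation and sampling
heterogeneity through time, geographic structure, real diversity
dynamics, correlated proxy biases, or age-model errors correlated across
samples. Passing tests therefore demonstrate that the machinery recovers
known structure under the stated statistical conditions — not that real
Phanerozoic data satisfy those conditions.

## Statistical choices

Spearman's $\rho$ is Pearson's correlation of average ranks (tie-aware).
Two-sided $P$ values use the $t$ approximation for $n \ge 10$ and exact
enumeration of all rank permutations below that. No multiple-testing
correction is applied by default, matching the compiled analysis's
convention; Holm correction is available to users via `p.adjust`. The
warming/cooling comparison defaults to the independent-samples Fisher-z
test; the classical Pearson–Filon variance form is provided as an option
because the compiled analysis names that test, but its printed statistics
are not reproducible from the printed $\rho$ and $n$ by any standard
two-correlation formula, so no numeric agreement is asserted. The cooling
subset correlates signed (negative) magnitudes, so extinction increasing
with cooling magnitude appears as negative $\rho$. Autocorrelation uses
the overall-mean sample ACF of extinction rate, $\Delta T$ and
$\ln |R|$. Extinction-rate error bars come from a bootstrap over
occurrence records — the displayed errors of the compiled analysis state
no procedure, so the record-level bootstrap is this package's choice,
reported as such.

Gap-filler membership reads the definition literally: present in bins
$i-1$ and $i+2$, absent in $i+1$, regardless of bin $i$ (a config switch
additionally conditions on absence in $i$). Negative gap-filler rates are
reported as-is with a flag; clamping at zero is opt-in.

## Problem sizes used by the test-suite

The property suites run at sizes chosen to give stable statistics at
interactive speed: 1,000 random presence matrices (up to 30 genera × 10
bins) for the cohort-count oracle; 100 seeds for event-recovery bias and
for the coupled-study structure (45 bins, 400 genera, coupling 0.9); 500
replicates for the null-calibration uniformity check (300 genera). The
bundled bin fixture transcribes the 2012 geologic time scale's stage
boundaries; its mean bin duration is 9.71 Myr. The exact numeric edges
used by the compiled analysis are recoverable only from its source data,
so individual boundaries may differ at the 0.1-Myr level — none of the
packaged checks depend on those edges beyond the bin count and
contiguity.

## Known limitations

Endpoint localisation assumes the excursion is ramp-like at the sampling
resolution; oscillatory excursions inside one bin are reported as their
largest monotone limb. The age model consumes dated constraints — it does
not re-derive them — and treats per-sample age uncertainties as
independent. The extinction estimators are genus-level and make no
subsampling standardisation; origination rates are out of scope. The
pipeline's correlation outputs are rank-based associations, not causal
estimates.
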