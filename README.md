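# thermext

Quantifying the relationship between temperature change and marine
extinction across the Phanerozoic, for paleobiologists and paleoclimate
researchers working with geochemical proxy series and fossil occurrence
data.

Deep-time extinction studies repeatedly implicate rapid warming and
cooling, but testing that link quantitatively requires a chain of
machinery: converting raw proxy measurements to sea-surface temperature
with honest uncertainties, isolating the largest temperature excursion in
each stage-level time bin, estimating extinction rates from incomplete
occurrence records, and correlating the two while controlling for the
obvious confounds. `thermext` implements that chain end to end, plus
synthetic-data generators with known ground truth so every stage is
testable without any external download.

## The quantities at the core

For each of 45 stage-level time bins (Katian–Hirnantian `Or5` through
Aquitanian–Burdigalian `Ng1`), the largest temperature excursion is
summarised by

- magnitude **ΔT = T₁ − T₀** (°C, signed; warming positive),
- duration **Δt = t₀ − t₁** (Myr; ages in Ma decrease toward the present),
- rate **R = ΔT / Δt** (°C/Myr),

with T₀ and T₁ estimated as means of sample groups on the flat approaches
to the excursion, and uncertainties from Monte Carlo resampling of those
groups. Conodont δ¹⁸O converts to SST via
`SST = 118.7(±4.9) − 4.22(±0.20) · (δ¹⁸Ocon − δ¹⁸Osw)` with the parameter
uncertainties propagated by Monte Carlo; TEX₈₆ and carbonate δ¹⁸O go
through configurable linear calibrations after the standard screening
rules (Mn/Sr diagenesis, abnormal-salinity facies, tropical latitude
window, and the BIT / MI / ΔRI / %GDGT-0 / fCren′ lipid indices).

Extinction rates per bin come from genus-level occurrences via the
gap-filler and three-timer estimators

    r_GF = ln( (2T + pT) / (3T + pT + GF) )
    r_3T = ln( 2T_i / 3T ) + ln( 3T / (3T + pT) )

where 2Tᵢ, 3T, pT and GF count genera sampled in consecutive-bin
patterns. Spearman rank correlations then relate |ΔT| and |R| to the
rates over all bins and the standard subsets (warming/cooling split,
Big-Five exclusion, deep-water exclusion, sub-threshold rates), and each
event is classified against the mass-extinction thresholds |ΔT| > 5.2 °C
and |R| > 10 °C/Myr.

## A worked example

Build a synthetic study in the Phanerozoic configuration — five bins
carrying large fast excursions over a low-amplitude background, extinction
probabilities coupled to the excursion magnitudes — and run the whole
pipeline:

```r
library(thermext)
bins <- load_bin_scheme()
big5 <- c("Or5", "D4", "P5", "T5", "K8")
evs  <- data.frame(bin_id = big5,
                   magnitude = c(-8.4, -5.8, 10.4, 7.4, -6.2),
                   duration  = c(0.35, 0.3, 0.2, 0.25, 0.3))
set.seed(99)
other <- setdiff(bins$bin_id, big5)
bg <- data.frame(bin_id = other,
                 magnitude = runif(40, 1, 4) * sample(c(-1, 1), 40, TRUE),
                 duration  = runif(40, 1, 4))
cfg <- read_run_config(list(
  synth = list(events = rbind(evs, bg), coupling = 0.9,
               base_extinction_prob = 0.15, sampling_prob = 0.9,
               n_genera = 400),
  event = list(mc_draws = 200L), n_boot = 50L, seed = 7))
run <- run_pipeline(cfg)
print(run)
```

```
Climate-change / extinction pipeline run
  bins: 45 (Or5..Ng1), seed 7
  events detected: 45 bins (0 excluded by resolution screen)
  extinction rates: 45 bins defined (gap-filler)
  |delta_T| vs extinction: rho = 0.687, P = 1.91e-07, n = 45
```

The five engineered bins — and only those — land in the threshold regime,
with magnitudes and rates close to the injected truth:

```r
run$event_table[run$event_table$class == "big_five_regime",
                c("bin_id", "delta_T_c", "delta_t_myr", "rate_c_per_myr",
                  "direction", "class")]
```

```
 bin_id delta_T_c delta_t_myr rate_c_per_myr direction           class
    Or5 -8.409036   0.3500000      -24.02582   cooling big_five_regime
     D4 -5.778099   0.2625000      -22.01181   cooling big_five_regime
     P5  9.945851   0.2250000       44.20378   warming big_five_regime
     T5  7.456852   0.1875000       39.76988   warming big_five_regime
     K8 -6.308892   0.3245588      -19.43836   cooling big_five_regime
```

The correlation suite shows the expected structure: a strong positive
association between |ΔT| and extinction rate that weakens but survives
excluding the five extreme bins, a positive warming-side and negative
cooling-side correlation (signed magnitudes), and no association with bin
duration (the confound check):

```
            label         rho      p_value  n defined
           all_dT  0.68664976 1.911552e-07 45    TRUE
            all_R  0.46305873 1.359480e-03 45    TRUE
       warming_dT  0.73333333 3.534246e-04 19    TRUE
       cooling_dT -0.60957265 9.471012e-04 26    TRUE
 excl_big_five_dT  0.55377832 2.098052e-04 40    TRUE
  rate_below_10_R  0.23575215 1.430629e-01 40    TRUE
  duration_vs_ext -0.09306539 5.431506e-01 45    TRUE
```

`summary(run)` prints the full event and correlation tables, and
`plot(run)` draws the three-panel |ΔT| / |R| / extinction-rate overview.
Individual stages are exported directly: `screen_measurement()`,
`linear_sst_mc()`, `detect_largest_event()`, `extinction_rates()`,
`correlation_suite()`, and the generators `generate_climate_series()`,
`generate_occurrences()`, `generate_gdgt()`.

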