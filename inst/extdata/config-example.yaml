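# Example run configuration for thermext::read_run_config().
# Every field is optional; omitted fields take the documented defaults,
# which reproduce the standard screening cut-offs and thresholds.

# bin_scheme: path/to/bins.csv   # default: packaged 45-bin GTS2012 scheme
# proxy_table: path/to/proxies.csv
# occurrence_table: path/to/occurrences.csv

# Synthetic-data section (used when no proxy/occurrence tables are given);
# fields mirror synthetic_config().
synth:
  baseline_sst: 24        # degC
  noise_sd: 0.5           # degC measurement noise
  sampling_density: 3     # background samples per Myr
  event_oversampling: 8   # samples per ramp duration across injected events
  n_genera: 400
  base_extinction_prob: 0.2
  sampling_prob: 0.9
  coupling: 0             # logistic coupling of extinction to |delta_T| (z-scale)

thresholds:
  mn_ppm: 250             # carbonate diagenesis: Mn above this AND
  sr_ppm: 400             #   Sr below this (strict inequalities)
  bit: 0.4                # terrestrial GDGT input
  mi: 0.5                 # methane index
  delta_ri: 0.3           # ring-index offset
  pct_gdgt0: 67           # %GDGT-0
  f_cren: 0.25            # crenarchaeol regioisomer fraction
  abs_paleolat: 40        # tropical/subtropical window, degrees
  mn_sr_conjunction: true # false = reject on either trace-element criterion

event:
  endpoint_group_size: 3  # samples averaged per endpoint
  min_samples: 4
  mc_draws: 500
  max_reversal_frac: 0.33333
  smooth_window: 3
  trim_frac: 0.2

classify:
  mag: 5.2                # degC,   |delta_T| threshold (strict)
  rate: 10                # degC/Myr, |R| threshold (strict)
  span: 0.4               # Myr, short-timespan flag

min_density: 2            # measurements per Myr resolution screen
n_boot: 100               # bootstrap draws for rate uncertainties
estimator: gf             # gf | 3t
big_five_bins: [Or5, D4, P5, T5, K8]
drop_deep_water: false
seed: 1
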