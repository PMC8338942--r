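Package: thermext
Title: Temperature Change and Marine Extinction Rates in Deep Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the relationship between temperature change and marine
    extinction over Phanerozoic time. Converts geochemical proxy data (carbonate
    and conodont oxygen isotopes, TEX86) to sea-surface temperature with Monte
    Carlo parameter-uncertainty propagation and literature screening rules;
    detects the largest temperature excursion in each of 45 stage-level time
    bins and reports its magnitude, duration and rate with uncertainties;
    estimates genus-level extinction rates from fossil occurrence data using the
    gap-filler and three-timer estimators; and runs rank-correlation and
    threshold analyses linking climate excursions to extinction. Includes
    seed-deterministic synthetic-data generators with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
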