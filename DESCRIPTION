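Package: fedmeta
Title: Federated Meta-Analysis of Multi-Site Negative-Symptom Summary Statistics
Version: 1.0.0
Authors@R: person("Avery", "Quinn", email = "avery.quinn@example.org",
    role = c("aut", "cre"))
Description: Simulates and executes decentralized multi-site analyses of
    clinician-rated negative-symptom data (SANS) in which sites never share
    record-level data. Each site maps its local file to a canonical schema,
    computes factor and composite symptom scores, and releases only
    standardized gender effects (Cohen's d with sampling variance and group
    counts); a central aggregator pools them by random-effects meta-analysis
    (DerSimonian-Laird or REML) with heterogeneity statistics, forest
    displays and site-outlier checks. Includes a privacy audit of every
    message, an iterative federated regression mode (exact sufficient
    statistics or gradient rounds), and a synthetic seven-site consortium
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
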