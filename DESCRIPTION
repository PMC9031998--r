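Package: epochscore
Title: Automatic Quality Scoring of Resting-State M/EEG Epochs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Objective, data-driven scoring of fixed-length epochs of
    resting-state M/EEG recordings. Each epoch receives a score measuring how
    similar its Welch power spectral density is to the spectra of all other
    epochs of the same recording (Spearman correlation, averaged within and
    then across channels), so that atypical -- typically artifactual -- epochs
    can be ranked last and excluded reproducibly. The package also provides
    relative band power features, phase lag index connectivity, an exhaustive
    epoch-selection sweep with paired Cohen's d effect sizes, a synthetic
    multichannel EEG generator with known ground truth (1/f background, alpha
    oscillation, injectable artifacts), EDF and delimited-text input/output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
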