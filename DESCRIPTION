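Package: gaersim
Title: Mean-Field Simulation and EEG-fMRI Analysis of Absence Seizure Responsiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sensory responsiveness during absence seizures
    in the GAERS rat model. Implements a conductance-based mean-field model of
    coupled excitatory/inhibitory AdEx populations with spike-frequency
    adaptation, whole-brain network simulations on a directed connectome with
    square-pulse sensory stimulation, a kernel-method LFP proxy, automated
    spike-and-wave discharge detection with interval merging rules, an 8-way
    stimulation-block taxonomy, and a mass-univariate fMRI GLM with third-order
    gamma basis functions, F/T contrasts, permutation cluster correction,
    framewise displacement and motion scrubbing. Synthetic-data generators
    (connectomes, SWD-laden EEG, stimulation schedules, 4D fMRI with known
    effects) make the whole chain testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
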