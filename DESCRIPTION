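Package: eegentropy
Title: Sample Entropy and Multiscale Entropy Analysis of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the complexity of multichannel EEG
    recordings with sample entropy and multiscale entropy. Implements the
    template-matching entropy estimators from first principles (with a
    compiled inner loop), an EEG conditioning chain (common-average
    re-referencing, zero-phase band-pass filtering, resampling, resting and
    stimulus-locked epoching, amplitude-based artifact rejection and subject
    inclusion rules), a synthetic three-group cohort generator with
    controllable band-limited complexity and entropy-behavior coupling, and
    the group-statistics layer used in case-control EEG complexity studies
    (Levene checks, one-way and split-plot ANOVA with Bonferroni pairwise
    tests, Cohen's d, and entropy-performance Pearson correlations per
    electrode and scalp region).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
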