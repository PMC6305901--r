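Package: perturbstance
Title: Neuromechanical Analysis of Perturbed Upright Stance
Version: 0.1.0
Authors@R:
    person("Perturbstance", "Developers", email = "maintainer@perturbstance.dev",
           role = c("aut", "cre"))
Description: Tools for analysing postural responses to support-surface
    translations during unilateral stance. Implements phase-windowed
    integrated surface EMG (pre-activation and short-, medium- and
    long-latency reflex windows plus the belated muscle response), maximal
    voluntary contraction normalization, soleus H-reflex and M-wave
    peak-to-peak extraction with recruitment-curve based stimulus
    calibration, centre-of-pressure and joint-goniometry summaries,
    condition normalization, repeated-measures ANOVA with
    Greenhouse-Geisser correction and partial eta squared, Spearman
    correlations with Benjamini-Yekutieli false-discovery-rate control,
    and a forward simulator that generates whole synthetic cohorts
    (subjects x conditions x trials) with a known ground truth so that
    every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
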