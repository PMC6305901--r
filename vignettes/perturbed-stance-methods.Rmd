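---
title: "Methods: neuromechanical analysis of perturbed upright stance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuromechanical analysis of perturbed upright stance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(perturbstance)
```

# The measurement problem

When the support surface under a standing person translates abruptly,
the nervous system mounts a stereotyped, phase-structured recovery:
spindle-driven short-latency reflexes (SLR, 30-60 ms after platform
onset), polysynaptic medium- and long-latency responses (MLR 60-85 ms,
LLR 85-120 ms), and a belated muscle response (BMR) that lasts until the
centre of pressure (COP) reaches its peak excursion. How this response
is organised depends on whether the person could anticipate the
perturbation: a correctly cued (*predicted*) translation, an uncued
(*unpredicted*) one, and a miscued (*cheated*) one produce graded
differences in muscle pre-activation, reflex gain, COP displacement and
joint excursions.

This package implements the complete measurement chain for such
experiments — and, because no public dataset of this kind exists, a
forward simulator that generates whole cohorts with known ground truth,
so that every stage of the chain is testable end to end.

# Trial geometry and conventions

* Every analysed trial is a **600 ms epoch**: 100 ms before to 500 ms
  after perturbation onset. On the 1 kHz grid (EMG, goniometry,
  platform) that is 600 samples with 1-based sample 101 at *t* = 0; on
  the 100 Hz COP grid, 60 samples with sample 11 at *t* = 0. The COP
  channel is cut on its own grid at the sample nearest onset (at most
  5 ms skew); we deliberately do not resample, because interpolation
  would bias peak-to-peak and extremum measures.
* All phase windows are **half-open** `[start, end)` in ms: PRE
  `[-100, 0)`, SLR `[30, 60)`, MLR `[60, 85)`, LLR `[85, 120)`, BMR
  `[120, COP-peak latency)`. Half-open windows make integrals tile
  exactly (`[a,b) + [b,c) = [a,c)`), which is asserted as a property
  test. The 0-30 ms gap is intentional.
* **Sign convention**: posterior displacement (platform and COP) is
  negative, anterior positive. A backward pre-lean therefore has a
  negative COP onset value, and posterior COP peaks are negative.
* The BMR window ends at the *trial's own* COP peak latency. Trials
  whose COP peak falls at or before 120 ms have no BMR window and are
  excluded from BMR analysis only (a per-cohort switch to a fixed
  endpoint exists via `emg_feature_table(bmr_end =)`).

# The forward model (synthetic cohorts)

`generate_cohort()` draws a cohort in two layers.

**Subject layer.** For each subject and condition, the subject-level
value of every summary the pipeline later estimates (COP onset/90
ms/120 ms/peak/peak latency, per-joint onset/excursion/latency, per
muscle-and-phase EMG activity in %MVC, per-phase H-reflex modulation)
is drawn from a configured mean ± SD. The defaults encode the
anticipation gradient of the study the package models: backward lean
(-0.7 cm) under correct cueing versus forward lean (+0.7 cm) under
miscueing; COP peaks growing from -2.5 to -3.7 cm and peak latency from
230 to 344 ms; tibialis anterior pre-activation rising from 0.05 to
0.31 %MVC under miscueing while soleus LLR/BMR activity rises from
0.41/0.34 to 0.65/0.61 %MVC; H-reflexes suppressed in the SLR (factor
0.70 when cheated) and facilitated in the LLR (factor 1.40), with the
MLR facilitated only for unpredicted trials. The H factors are a
package choice consistent with the qualitative pattern (no numbers are
published for them); everything else comes from the study's printed
tables.

**Correlation structure.** Within a condition, one shared
standard-normal latent per subject carries the between-variable
dependence (a Gaussian copula). A variable with target Spearman
correlation ρ against the COP peak receives loading
λ = 2 sin(πρ/6) / λ_peak on the latent, which reproduces ρ exactly in
population for Gaussian marginals. The anchor pair (COP onset, COP
peak) is −0.699 predicted and +0.771 cheated; further loadings cover
the published COP-peak-anchored correlations (e.g. H-reflex LLR −0.747
cheated). This single-factor construction cannot reproduce a full
arbitrary correlation matrix — correlations between two non-anchor
variables are implied products — and targets requiring |λ| > 1 raise an
error naming the offending pair. The latency-anchored published values
are deliberately not targeted (they are mutually inconsistent with the
peak-anchored ones under any single-factor model). The unreported
(peak, peak-latency) correlation is set once to −0.5: delayed
compensation co-occurs with larger posterior excursion.

**Trial layer.** Around the subject values, each trial gets independent
jitter chosen once as realistic for this kind of recording: COP onset
0.1 cm, COP peak 0.3 cm, peak latency 20 ms within-subject SD; 10%
multiplicative jitter on per-trial EMG amplitude targets; 8% on H and
5% on M amplitudes; COP sensor noise 0.03 cm; goniometer noise 0.1°;
potentiometer noise 0.005 cm (a 50 µm-class sensor). Waveforms:

* **Platform**: raised-cosine ramp of 3 cm completed in 210 ms (the
  published amplitude/duration), held, with a slow return well before
  the next trial. The published mean velocity (1.8 m/s) and peak
  acceleration (12.6 m/s²) are *not* reproducible from any smooth
  3 cm / 210 ms ramp; amplitude and duration are treated as primary and
  realized velocity/acceleration are merely reported.
* **EMG**: band-limited (10-500 Hz) Gaussian noise whose envelope
  σ(t) is calibrated per muscle so that the expected mean rectified
  amplitude over each analysis window equals the subject's target
  (E|N(0,σ²)| = σ√(2/π); a 4×4 linear solve maps window targets onto
  Gaussian burst envelopes at the reflex-peak latencies 45/72/100 ms
  plus a smoothed BMR plateau). This makes the ensemble-recovery
  invariant exact in expectation rather than approximate.
* **Evoked potentials**: stimulation artifact, M-wave and H-reflex are
  biphasic Gabor wavelets inserted into the soleus channel at
  stimulus +1, +13 and +38 ms, each scaled so its realized peak-to-peak
  equals the configured amplitude exactly.
* **MVC**: three 3 s plateau holds per muscle with 5% rep-to-rep
  scaling; the extraction rule (best rep, 100 ms window around the
  rectified peak) mirrors the analysis side.

**What the generator does not emulate** — and hence what a green test
does not establish: motion artifacts and electrode lift-off,
non-Gaussian EMG amplitude distributions, electromechanical coupling
between the channels within a trial (channels are conditionally
independent given the subject values), post-activation depression of
the H-reflex, habituation across trials, and any forward dynamics of
the standing body. Tests prove the *pipeline* recovers what the
generator put in; they cannot prove the generator is the world.

Reproducibility: one root seed; per-subject streams derived with
`child_seed()` (a fixed LCG hash), so identical configurations give
byte-identical cohorts and adding subjects never reshuffles earlier
ones' draws.

# Analysis choices

* **Onset detection**: candidates are rising crossings of a baseline
  band (median ± 5% of full excursion, the package default — no
  detection rule is published), confirmed by requiring the deviation to
  build to half the excursion within 500 ms (this rejects threshold
  chatter on the slow return stroke), with a 1 s refractory period.
  Because a smooth ramp starts quadratically, a threshold crossing lags
  the true onset by tens of ms; each candidate is therefore refined by
  regressing √deviation on time over the 2-15% band and extrapolating
  to zero. On synthetic recordings this lands within ±1-2 ms of truth.
* **Reflex-peak latencies** come from the rectified ensemble mean of
  ≥ 2 unstimulated posterior trials, smoothed with a 15 ms moving
  average before the per-window argmax. The kernel width matters: any
  kernel comparable to the window widths (25-35 ms) mixes neighbouring
  reflex components into each window and drags the argmax to a window
  edge, so the kernel is set to about twice the burst SD and strictly
  below the narrowest window.
* **MVC normalization** uses the peak-window rule: the repetition with
  the highest rectified amplitude, integrated over the 100 ms around
  its peak, converted to a mean amplitude. (The alternative 1-minute
  integration mentioned in the source protocol conflicts with 3 s holds
  and is not implemented.) Note the selection step biases the reference
  upward by a few percent — an inherent property of max-selection
  normalization, present in the real protocol too.
* **Time-normalized EMG** is reported in mV (mV·s divided by s); the
  source's printed unit "mV/s" is dimensionally inconsistent with that
  operation.
* **H/M extraction**: M-wave in `[stim+5, stim+25)` ms, H-reflex in
  `[stim+25, stim+55)` ms (standard soleus latencies; configurable),
  both plain peak-to-peak of the raw trace; amplitudes above 25 mV are
  treated as artifact saturation and the trial is flagged out. H
  amplitudes are additionally expressed as % of the subject's
  predicted-condition mean per phase.
* **Calibration** interpolates the ascending H limb linearly and
  returns the lowest intensity where H = 25% of M-max; M-max is the
  maximum sampled M amplitude.
* **COP peak** is the *largest-magnitude signed* deviation from the
  onset value in `[0, 500)` ms, ties to the earliest sample — so a
  trial that starts in a forward lean still reports its posterior peak
  with sign intact. Fixed-latency values (90/120 ms) are emitted both
  onset-referenced (used for statistics) and absolute.
* **rmANOVA**: univariate within-subject decomposition from orthonormal
  contrast scores; each effect is tested against its own
  subject-interaction error term; Mauchly's test on the contrast
  covariance; Greenhouse-Geisser df correction applied only when
  Mauchly's p < 0.05 (Huynh-Feldt intentionally not implemented);
  ηp² = SS_effect/(SS_effect+SS_error). When the contrast covariance is
  singular (n − 1 ≤ number of contrasts) Mauchly's statistic is
  undefined and reported `NA`. Replicates within a cell are averaged
  before the decomposition; unbalanced designs fail loudly with the
  offending subjects listed (statistics are then run on complete
  cases by the caller).
* **Spearman correlations**: midranks for ties; exact two-sided p by
  full permutation enumeration for n ≤ 10 (cached null distribution;
  enumeration is chunked by leading element to bound memory), t
  approximation above. Zero-variance input yields an undefined flag,
  not a number.
* **FDR**: Benjamini-Yekutieli step-up with the harmonic-sum penalty
  c(m) = Σ 1/i, valid under arbitrary dependence; all Spearman tests of
  one condition's family are corrected together (the family definition
  is a package choice — none is published — and is config-exposed).
  Note that the per-subject normalization to the predicted condition is
  *not* rank-preserving across subjects (each subject has its own
  divisor), so correlations on normalized and raw values can differ;
  the package computes its correlation family on raw subject-level
  values.

# Numerical edge cases

Degenerate inputs are contracts, not surprises: zero-amplitude
platforms, empty intensity grids, windows outside the epoch, zero MVC,
unstimulated trials passed to the H/M extractor, flat traces passed to
onset detection, and unreachable calibration targets all raise typed
errors (`ps_*` condition classes). Flat ensembles in reflex-peak
detection return the earliest sample of each window with a
low-confidence flag. All argmax ties break to the earliest sample.

# Limitations

The statistical module covers the designs this pipeline needs (one or
two within-subject factors); it is not a general ANOVA engine — no
between-subject factors, no Huynh-Feldt, no multilevel models. The
generator's anterior trials exist for protocol bookkeeping and carry
mirrored COP kinematics but no direction-specific neuromuscular
response model, mirroring the analysed design (posterior trials only).
Published group-level results from a 29-subject human sample are
targets for *distributional* recovery, not trial-level replication.
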