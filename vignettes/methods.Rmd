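---
title: "Methods: stimulus acoustics and representational analyses for vocalization fMRI"
author: "vocfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus acoustics and representational analyses for vocalization fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocfmri)
```

# What the package computes

`vocfmri` implements the analysis chain of a block-design auditory fMRI
experiment in which awake macaques hear five categories of sound — three
conspecific vocalizations (coos, screams, aggressive calls) and two
non-vocalization controls (other-animal calls, nature sounds) — plus
time-domain scrambled versions of each. The chain has five stages:

1. **Stimulus acoustics** — gammatone auditory spectrograms, modulation
   power spectra (MPS), a per-stimulus feature set (RMS level, F0 mean and
   SD, harmonic-to-noise ratio, power-spectrum SD and CV, duration,
   spectral centroid), acoustic dissimilarity matrices, dendrograms with
   cophenetic validation, and nonparametric centroid statistics.
2. **Scrambling** — multiband time-domain scrambling that preserves the
   long-term spectrum while destroying temporal fine structure, with QC.
3. **GLM / ROI** — a voxel-wise GLM with an MION (iron-oxide contrast
   agent) response kernel, simplified cross-validated noise-PC denoising,
   contrast t-maps, two-step split-half ROI selection, percent signal
   change, FIR time courses, and Friedman/Wilcoxon condition statistics.
4. **MVPA** — leave-one-run-out linear-SVM classification of β patterns
   (3-class vocalization type; pairwise original vs scrambled), chance
   tests, and cross-classifier comparisons.
5. **RSA** — neural dissimilarity matrices, non-metric 2D embedding, and
   multiple-regression RSA against two target models with repeated
   hold-out.

Because the animal data are external, every stage is exercised on
synthetic data with known ground truth; the synthetic generators are
first-class, tested code.

# Synthetic stimuli

`generate_stimulus()` synthesizes each category from a small recipe whose
targets are the published category means: fundamental frequency `f0_hz`,
periodicity `harmonicity` (the 0–1 harmonic-to-noise scale), spectral
centroid `centroid_khz`, and RMS level `rms_db`. All recipes share one
spectral-envelope device: components are weighted by `exp(-f / lambda)`
with `lambda` equal to the target centroid, which places the
amplitude-weighted mean frequency near the target without any
optimization loop. Category character comes from the mixture:

* **coo** — harmonic stack on a slowly jittered, stable F0 (jitter SD
  0.2%); mostly periodic.
* **scream** — higher F0, strong shaped-noise floor with high-frequency
  emphasis (its centroid target, 5 kHz, is the emphasis).
* **aggressive** — noise and a weak harmonic residue, both gated by a
  ~30 Hz raised-cosine pulse train (pulsed bursts); least periodic of the
  vocalizations.
* **animal** — harmonic stack with 6 Hz vibrato plus moderate noise.
* **nature** — shaped broadband noise only.

The mixing weights are `sqrt(harmonicity)` and `sqrt(1 - harmonicity)` on
RMS-normalized components, so the target periodicity maps directly onto
the energy split. Generation is bit-reproducible for a fixed seed
(`withr::with_seed` inside the generator; the caller's RNG stream is left
untouched).

These are caricatures, deliberately: they reproduce the category-level
*contrasts* (coos most periodic, screams highest centroid, aggressive
calls pulsed and noisy) but not the within-category variability,
formant structure, or amplitude contours of real recordings. Tests that
pass on them certify the analysis code, not claims about real macaque
calls.

# Run designs

`generate_run_design()` produces the 10-condition block design: each run
contains every condition `reps = 2` times in 21 s blocks of 42 events at
500 ms onset asynchrony, each block followed by 15 s of silence, with
`n_dummies = 5` dummy volumes at TR 3 s before the first block.

Counterbalancing uses a Latin square built by cyclic shifts of a seeded
random first row. Serial position is defined as a block's position within
its repetition cycle (1..10); each run consumes `reps` consecutive rows of
the square, and rows recycle, so across `n_conditions / reps` runs the
square is fully used and every condition occupies every serial position
equally often. The exhaustive-count property is asserted in the tests
(10 runs, reps 2: every condition exactly twice per position).

The arithmetic length of a run (5 dummies + 20 × 36 s = 735 s = 245
volumes) differs slightly from the acquisition length quoted for the
original scanner runs (243 pulses); since the discrepancy cannot be
resolved from the description, the generator computes the natural length
and exposes `n_vols` as an override rather than assuming an intent.

# Auditory spectrograms and modulation power spectra

The filterbank is a 4th-order gammatone bank with center frequencies
equally spaced on the ERB-rate scale (Glasberg & Moore), implemented as
FIR truncations of the gammatone impulse response applied by FFT
convolution, each kernel normalized to unit gain at its center frequency.
Envelopes are half-wave rectified band signals averaged in 10 ms frames
every 5 ms.

`compute_mps()` follows the chain: log envelope, mean removal, 2D
autocorrelation (zero-padded, so linear rather than circular), 2D FFT
magnitude, expressed in dB relative to the peak. Peak referencing makes
the MPS invariant to global waveform gain. Two demeaning conventions are
exposed because they answer different questions: `"global"` (default)
keeps each channel's stationary level, so a stationary sound concentrates
power at 0 Hz temporal modulation; `"channel"` also removes each
channel's temporal mean, isolating genuine temporal modulation (an
amplitude-modulated tone then peaks exactly at ± its modulation rate).
The spectral-modulation axis is expressed in cycles/kHz via the mean
channel spacing; since ERB spacing is not linear in Hz this is an
approximation, adequate for the categorical comparisons made here.
Averaging across stimuli (`average_mps()`) happens in linear power on the
absolute scale and is re-referenced afterwards. The half-maximum contour
is the −6.02 dB level set (half power).

# Acoustic features

F0 and HNR come from framewise normalized autocorrelation (25 ms frames,
10 ms hop, search range 100–2000 Hz). The peak is located on the biased
autocorrelation — its inherent lag taper suppresses spurious long-lag
subharmonic peaks — and the peak value is then corrected by `n / (n - l)`
for the taper, so a pure tone scores ≈ 1. Frames with peak ≥ 0.3 count
as voiced; F0 statistics pool voiced frames, HNR is the mean voiced peak
(0–1 scale, matching the magnitudes of the packaged category table; a dB
scale would be inconsistent with those values). With no voiced frames the
F0 fields are `NA` and HNR is 0.

The spectral features are defined as: centroid = amplitude-weighted mean
frequency (kHz); PSSD = power-weighted SD of frequency; PSCV = SD/mean of
spectral magnitude across bins. The published table prints PSSD in "Hz"
with values near 15–20, which cannot be the power-weighted SD of a
kHz-wide spectrum; the estimator used there is not recoverable from the
description, so this package keeps the principled definition and treats
the packaged table itself (not re-derivation of its values) as the input
to downstream aggregation — which is also why the packaged table ships as
a fixture.

`aggregate_category_features()` averages per category and then averages
category means within the vocal (3) and non-vocal (2) groups. On the
packaged table this reproduces the printed group PSSD/PSCV values
(20.8 / 15.56 / 2.7). Note the printed vocal-PSCV group mean (5.4) is not
the mean of the tabled category values (4.82); per-stimulus averaging in
the original is the likely cause, and the package reports the computed
value.

# Dissimilarity matrices and dendrograms

Feature RDMs use correlation distance (1 − Pearson r) between category
vectors. The feature RDM is computed on category means with per-feature
z-scoring across categories (`standardize = TRUE`): without it, F0
magnitudes (hundreds of Hz) dominate every other feature. Whether the
original analysis standardized, or averaged per-stimulus RDMs instead, is
not stated; the z-scored category-mean recipe is the package's choice and
reproduces the published cophenetic correlation (0.799 vs 0.80 printed).

Dendrograms use average linkage (UPGMA) by default — conventional for
cophenetic validation and configurable — and cophenetic correlation is
the Pearson correlation between original and tree-implied distances. RDM
pairs are compared by Spearman correlation of strictly-lower triangles.

Centroid statistics: Friedman over the condition-by-stimulus table
(stimuli matched across conditions by rank position), then pairwise exact
Wilcoxon signed-rank with Bonferroni correction over all 45 pairs. A
sample-size consequence worth knowing: with 10 stimuli per condition the
smallest attainable two-sided exact signed-rank p is 2/2^10, which after
×45 correction is 0.088 — no pair can be declared significant at 0.05.
The omnibus Friedman carries the inference at that n; the pairwise table
becomes informative from n ≈ 12 matched stimuli upwards.

# Scrambling

Each gammatone band is filtered forwards and backwards (zero phase),
cut into 30 ms raised-cosine segments with 50% overlap, the segments
permuted uniformly and independently per band (seeded), re-overlap-added
with window-sum compensation, and the bands summed. Segment length
defaults to 30 ms: short enough to destroy syllabic and modulation
structure, long enough for band-level stationarity; band count defaults
to 32.

Summing independently shuffled tapered segments adds overlapping content
with independent phases, which systematically loses a few dB where
windows and bands overlap. Since the method's defining property is
preservation of the long-term spectrum, the final step restores it
explicitly: a smoothed (~1/12 octave) gain curve matches the output's
long-term magnitude spectrum to the input's, leaving phase — and hence
the scrambled temporal structure — untouched. QC (`scramble_qc()`)
verifies both halves of the contract: per-band long-term levels within
~1 dB, broadband envelope correlation collapsed (an amplitude-modulated
tone with segments much shorter than the modulation period drops well
below 0.5).

# GLM, denoising, ROIs

The MION kernel is a gamma variate (shape 2, scale 4 s; mode at 4 s,
under 10% of peak by 30 s), normalized to unit sum. Raw MION signal
decreases on activation; the pipeline stores activation-positive values,
and `mion_sign_flip` converts where raw-polarity data are simulated or
analysed. Condition regressors are fractional-TR block boxcars convolved
with the kernel; silence is left unmodelled as the implicit baseline;
drift is a centered polynomial basis (order 2 by default) so the
intercept estimates the silent baseline level; dummy volumes are excluded
from all fits. Fits are ordinary least squares per voxel, stacked across
runs for fixed effects (condition columns shared, drift/nuisance columns
block-diagonal), with t-maps from the usual contrast variance formula.

Noise-PC denoising implements the simplified procedure: voxels with
negative leave-one-run-out cross-validated task R² (after per-run drift
removal) form the noise pool; per-run principal components of the pool
are added one at a time; k is chosen at the maximum mean cross-validated
R², stopping when the improvement drops below 0.1 percentage point; the
denoised data subtract the projection onto the selected components. An
empty pool yields k = 0 and a warning, leaving the data untouched — which
also guarantees that data orthogonal to the components pass through
unchanged.

Percent signal change per condition and run is 100 × β / baseline from a
per-run fit, averaged across runs with the SEM; the silent baseline maps
to 0 by construction. FIR time courses use one regressor per TR lag per
condition over the block-plus-silence window (12 lags at TR 3). Because
contiguous blocks tile every frame, the FIR basis spans the intercept;
the model therefore omits the intercept and references the estimates to
the trimmed end of the silent period (the final lags), which is also the
natural reading of a "silent baseline" that excludes the immediate
post-block hemodynamic tail. The mean course is smoothed with a centered
zero-padded 3-point moving average.

ROI selection is the two-step split-half rule. Step 1, on the combined
map: voxel threshold at a Bonferroni familywise surrogate (random-field
theory is out of scope), 6-connected clusters of ≥ 10 voxels, then a
Benjamini–Hochberg filter on cluster-mass p-values. The cluster-mass p
uses an exponential-excess approximation: above threshold u, t-excesses
are treated as i.i.d. exponential with rate equal to the t-distribution
hazard at u, so a k-voxel cluster's mass is Gamma(k, rate) under the
null. Step 2: a cluster survives only if every split-half map (per
subject and hemisphere, computed from the selection half of runs) is
suprathreshold at p < 0.001 uncorrected somewhere inside it. Split halves
default to odd/even run indices; selection and analysis halves are
disjoint by construction. ROI condition statistics reuse the Friedman /
signed-rank machinery, adding per-condition tests against the silent
baseline.

# MVPA

`loro_crossval_svm()` is a linear SVM (cost 1, one-vs-one multiclass —
the defaults of the toolbox family this analysis style comes from) with
one sample per condition and run; each fold trains on all runs but one
and tests on the held-out run, and features are standardized with
training-fold statistics only, so no test information reaches the model.
Fold count equals the number of runs supplied — nothing is hard-coded.
The test against chance treats the per-fold accuracies as a one-sample
problem (signed-rank of accuracy − chance, one-tailed); a literal
rank-sum mode against a constant vector at chance is available for
fidelity with the original description. When every fold sits exactly at
chance the statistic is undefined and the function returns p = 1 with a
warning. Cross-classifier comparison is a Kruskal–Wallis omnibus over
fold accuracies with paired signed-rank follow-ups for matched designs.

# RSA

The neural DSM averages β patterns across the selected runs, subtracts
the cross-condition mean pattern (removing any shared activation profile
— the DSM is provably invariant to adding a constant pattern to all
conditions), and takes pairwise Euclidean distances. The two target
models over the five categories are fixed matrices: the *dissociation*
model (0 within vocalizations and within non-vocalizations, 2 between
groups) and the *distinction* model (2 among vocalizations, 0 among
non-vocalizations, 1 between groups). Their lower-triangle vectors have
correlation −1/√6, a constant of the design.

Regression z-scores the 10-entry strictly-lower triangles of the neural
and model DSMs (vector-wise, not matrix-wise — matrix z-scoring would
double-count symmetric entries) and solves ordinary least squares with no
intercept (the z-scored response has zero mean). Models are not
orthogonalized; their modest correlation is reported by the design
constant above.

Repeated hold-out draws a random subset of runs per iteration — default
`subset_size = 3`, the literal reading of "hold out NRuns − 3 runs";
because the intended reading may be the complement, the size is a
parameter — computes the DSM and regression per iteration, and reports
the mean β, a percentile interval, and a signed-rank p against zero over
iterations. This significance test is anticonservative by construction:
iterations resample overlapping run subsets, so they re-test the same
realized noise alignment many times, and under a pure-noise pattern the
rejection rate at α = 0.05 is far above nominal (≈ 0.45 in the packaged
null simulations at 8 runs, 100 iterations). The tests therefore assert
unbiasedness of β across datasets, and the p-values should be read as
descriptive of the hold-out distribution, not as calibrated error rates.

Non-metric 2D embedding minimizes Kruskal stress-1 (via `MASS::isoMDS`)
from a classical-scaling start plus seeded random restarts (best of 8),
returning stress as a fraction.

# Numerical choices and problem sizes

Tolerances: dissimilarity and GLM operations are tested against
brute-force oracles at 1e-10–1e-12; the noiseless GLM recovers injected
β exactly to solver precision. Degenerate inputs are defined, not
accidental: constant condition tables give Friedman χ² = 0 with p = 1 and
a warning; all-chance folds give p = 1 with a warning; all-zero DSMs
embed as coincident points with stress 0 and a warning; an empty noise
pool gives k = 0 with a warning; an empty ROI result is an empty list,
not an error.

The packaged analyses and tests run at deliberately small problem sizes
chosen so the full suite completes in about a minute on one CPU while
every statistical check retains its power: 8×8×8 voxel grids, 4–24 runs,
40–60 voxels per β pattern, 100–1000 hold-out iterations, 200-dataset
chance calibrations, 10–50 seeded replicates for the power and
calibration suites. The same code paths scale to realistic sizes; only
the driver scripts choose the numbers.

# Known limitations

* Synthetic stimuli are category caricatures; they validate code, not
  bioacoustics. Real-data features (motion, physiological noise structure,
  spatial autocorrelation, inter-subject variability) are not simulated
  beyond low-rank shared noise and polynomial drift.
* The familywise voxel threshold is Bonferroni, deliberately conservative;
  the cluster-mass null is an exponential-excess approximation, not
  random-field theory.
* The noise-PC denoiser is the simplified cross-validated variant, not
  the full published denoising algorithm it summarizes.
* The repeated hold-out significance test is anticonservative (see
  above); the published original shares this construction.
* PSSD/PSCV estimator choices follow the verbal definitions; the printed
  units of the original table cannot be reconciled exactly (documented
  above), so re-derivation of the packaged table's values from audio is
  explicitly out of scope.
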