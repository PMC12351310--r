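Package: vocfmri
Title: Stimulus Acoustics and Representational Analyses for Macaque
    Vocalization fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing vocalization stimuli and analysing
    block-design auditory fMRI of macaques with an iron-oxide (MION)
    contrast agent. Provides gammatone auditory spectrograms, modulation
    power spectra, acoustic feature extraction (F0, harmonic-to-noise
    ratio, spectral centroid and spread), acoustic dissimilarity matrices
    with hierarchical clustering and cophenetic validation, multiband
    time-domain sound scrambling, a block-design GLM with a MION
    hemodynamic response function and cross-validated noise-PC denoising,
    split-half ROI selection, percent signal change and FIR time courses,
    leave-one-run-out SVM pattern classification, and model-based
    representational similarity analysis with repeated hold-out. A
    synthetic-data module generates stimuli, run designs, voxel time
    series and beta patterns with known ground truth so every stage is
    testable without the original recordings or scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    e1071,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
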