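Package: sterrp
Title: Single-Trial Error-Potential Estimation and Compact CNN Classification for EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-stage detection of error-related potentials (ErrP) in
    multichannel EEG. A domain-specific single-trial estimation stage
    (subspace-regularized Bayesian filtering, ARX single-sweep modeling, or
    dyadic-wavelet denoising) is inserted between standard EEG preprocessing
    (common average reference, zero-phase FIR band-pass, downsampling,
    epoching) and compact convolutional classifiers (an EEGNet-style network,
    a light CNN, and a Siamese network). Includes a synthetic-EEG session
    generator with stereotyped ErrP waveforms over autoregressive background
    activity, an imbalance-aware evaluation protocol (stratified five-fold
    cross-validation with majority voting, ARX surrogate balancing, balanced
    accuracy, F1, utility gain), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
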