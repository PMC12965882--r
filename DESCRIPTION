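Package: neurovox
Title: Differentiable Formant-Vocoder Speech Synthesis and ECoG Speech Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A speech-decoding framework for electrocorticographic (ECoG)
    recordings built around a differentiable source-filter speech synthesizer.
    The synthesizer maps 18 interpretable per-frame speech parameters (pitch,
    six formant frequency/amplitude pairs, a broadband unvoiced filter, voice
    weight and loudness) to a magnitude spectrogram through a harmonic and a
    noise pathway mixed by a soft voicing weight. A speech encoder trained in
    a speech-to-speech auto-encoding task supplies reference parameter
    trajectories, and interchangeable causal or non-causal neural ECoG
    decoders (temporal-convolutional ResNet, shifted-window 3D attention,
    LSTM) map high-gamma envelope tensors to the same parameter space.
    Includes the associated training objectives (multi-scale spectral loss,
    STOI+ intelligibility objective, parameter supervision and reference
    losses), ECoG preprocessing (common average reference, high-gamma
    envelope, baseline z-scoring), occlusion-based electrode contribution
    maps with a shuffled-model noise floor, and a seeded synthetic-data
    generator with a known electrode-to-parameter mapping so the full
    pipeline can be exercised end to end without patient data. All neural
    components run on a compact reverse-mode automatic-differentiation
    engine written in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
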