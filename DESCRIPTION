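Package: flysleeplfp
Title: Sleep Staging from Long-Term Multichannel Fly LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for identifying sleep stages in long-term
    multichannel local field potential (LFP) recordings from Drosophila.
    Includes a ground-truth-labeled synthetic session generator (LFP, video
    movement, pose traces), movement-based sleep segmentation and staging,
    LFP preprocessing with polarity-reversal re-referencing, channel-by-
    frequency spectral features with cluster-based permutation statistics,
    SVM probability probing and random-forest staging classifiers with
    permutation feature importance, proboscis-extension and antennal
    periodicity detection, and a random-intercept mixed-model comparison
    harness with likelihood-ratio tests and Tukey post hocs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    ranger,
    lme4,
    lmerTest,
    emmeans,
    EBImage,
    pracma
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
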