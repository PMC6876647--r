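Package: ehgtree
Title: Decision-Tree Classification of Uterine Contractions from
    Multichannel Electrohysterograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising uterine contractions in multichannel
    surface electrohysterogram (EHG) recordings. Provides a seeded
    synthetic-recording generator (8 EHG channels plus a TOCO-like
    reference with annotated contractions and common artifacts),
    low-pass/median preprocessing with per-channel amplitude
    normalisation, extraction of labelled contraction and
    non-contraction segments, computation of 24 time-domain, spectral
    and nonlinear waveform characteristics (including sample entropy,
    time reversibility and the largest Lyapunov exponent), per-channel
    CART classification under stratified 10-fold cross-validation with
    best-level cost-complexity pruning, Gini importance ranking, and
    AUC/sensitivity/specificity/PPV/NPV/accuracy evaluation with a
    Kruskal-Wallis fold-repeatability test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    rpart,
    pROC,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
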