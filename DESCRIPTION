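Package: microdyn
Title: EEG Microstate Brain-Network Dynamics, Controllability and Pinning Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline linking EEG microstates to brain-network
    dynamics. Implements global-field-power based microstate segmentation
    (polarity-invariant modified k-means on GFP-peak topographies, canonical
    A-D labelling, backfitting, temporal parameters), per-microstate
    phase-locking-value (PLV) networks from theta-band analytic-signal phases,
    weighted graph topology (clustering coefficient, characteristic path
    length, global and local efficiency, small-worldness), Laplacian
    synchronizability (eigenratio), average and modal network controllability,
    and pinning-control node ranking via spectral feedback-gain optimization.
    A synthetic-data module generates Markov-switching multichannel EEG
    cohorts with known ground truth (planted topographies, state sequences,
    phase coupling, and group effects) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
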