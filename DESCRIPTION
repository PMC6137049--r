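Package: speechtrf
Title: Cortical Tracking of the Speech Envelope in EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of cortical tracking of continuous
    speech in multichannel EEG. Provides a synthetic-data generator for
    two-register (infant- vs adult-directed speech) listening studies,
    artifact subspace reconstruction and standard EEG conditioning,
    Hanning-window theta-band power with repeated-measures ANOVA,
    ridge-regression temporal response functions (TRFs) with
    cross-validated EEG prediction, and spatiotemporal cluster-mass
    permutation statistics, composed into a reproducible end-to-end
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    data.table,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
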