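Package: mccalign
Title: Multiset Canonical Correlation Alignment Analysis for Multi-Subject MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial filtering of multi-subject sensor-space time series by
    multiset canonical correlation analysis (MCCA) with the MAXVAR criterion,
    cross-validated intersubject correlation (ISC) of the top canonical
    component with a circular-shift bootstrap null, forward-model activation
    patterns, and the pre/post-intervention contrast layer (paired and Welch
    t-tests, Cohen's d, sensitivity power analysis, FDR correction). Includes
    a synthetic-data generator that emulates a group x session x condition
    MEG study design with known ground-truth shared structure, plus the
    deterministic preprocessing chain (zero-phase band-pass filtering,
    resampling, zero-padding of rejected segments, PCA reduction).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    data.table,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
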