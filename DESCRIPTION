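Package: flowLicense
Title: Simultaneous Scoring of MCM Loading and RB1 Anchoring in G1 by Flow Cytometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the single-cell flow-cytometric analysis of replication
    licensing (chromatin-bound MCM2-7) together with restriction-point state
    (anchored, hypo-phosphorylated RB1) in G1 cells. Implements automated
    singlet gating from DNA pulse area/width, DNA-content peak detection and a
    left-side G1 gate, data-driven MCM and RB1 positivity thresholds anchored
    at the S/G2 border and the S-phase negative reference, Q1-Q4 quadrant
    classification with Wilson intervals, fluorescent-cell-barcoding
    demultiplexing by a one-dimensional Gaussian mixture, and time-course onset
    estimation for restriction-point passage, MCM loading and S entry. A
    ground-truthed synthetic cytometry generator emulates asynchronous growth,
    G0 release, irradiation arrest and nocodazole release so that every stage
    of the pipeline is verifiable. Reads and writes FCS 3.0/3.1 and CSV
    list-mode files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    data.table,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
biocViews: FlowCytometry, CellCycle, SingleCell, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'utils.R'
    'barcoding.R'
    'flowLicense-package.R'
    'gating.R'
    'io.R'
    'kinetics.R'
    'methods.R'
    'synthetic.R'
    'pipeline.R'
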