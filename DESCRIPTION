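Package: offmito
Title: Mitochondrial Pharmacogenetic Genotyping from Off-Target Capture Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Recovers MT-RNR1 pharmacogenetic genotypes (m.1555A>G,
    m.1494C>T and related aminoglycoside-ototoxicity variants) from the
    off-target reads of hybridization-capture sequencing experiments.
    Implements NUMT-aware mitochondrial read extraction by two-step
    competitive realignment, coordinate-based duplicate removal,
    quality-filtered pileups with off-target and coverage metrics, a
    VAF-based variant retention filter, and homoplasmy/heteroplasmy
    classification with clinical and low-coverage research modes. Ships a
    synthetic capture-read simulator with ground truth so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
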