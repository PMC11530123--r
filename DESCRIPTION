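Package: porepanel
Title: Targeted Nanopore Adaptive-Sampling Panel Design, Targeting QC and
    Run Metrics
Version: 0.1.0
Authors@R:
    person("porepanel", "maintainers", email = "porepanel@example.org",
           role = c("aut", "cre"))
Description: Toolkit for targeted long-read sequencing with nanopore adaptive
    sampling. Designs flanked target panels from gene intervals, assesses
    targeting fidelity against a reference by regressing observed on expected
    base fractions in log space, diagnoses loci degraded by reference
    duplication artifacts from supplementary-alignment evidence, emits a
    hard-masked reference, and computes run-level statistics from
    channel-labeled, haplotagged alignments: on-target enrichment over
    non-selective background coverage, phase breadth over strict gene bodies,
    post hoc time-to-phase, cis/trans allelic architecture from phased VCFs,
    and focal hypomethylation clusters from per-site 5mC calls. A deterministic
    simulator generates toy references, adaptive-sampling runs, phased variants
    and methylomes with known ground truth so the whole toolkit is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
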