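Package: somacohort
Title: Desk-Scale Somatic Mutation Cohort Analysis with a Synthetic
    Tumor-Normal Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cohort-level analysis of somatic small variants from
    whole-genome sequencing of tumor-normal pairs: consensus filtering of
    multi-caller call sets with a panel of normals and threshold rules,
    coding-effect annotation against a gene model, 6-class and
    96-trinucleotide-context mutational spectra, non-negative refitting of
    reference mutational signatures by iterative forward selection, rainfall
    and kataegis detection, chromosome-terminal enrichment testing, tumor
    mutational burden and driver mutual-exclusivity statistics. A fully
    synthetic cohort generator (reference genome, gene model, planted truth
    mutations, emulated per-caller VCFs and normal panels) makes every stage
    runnable and testable at desk scale without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
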