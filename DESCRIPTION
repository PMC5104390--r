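Package: cancertope
Title: Genome-Based Discovery and Prioritization of Cancer Neoepitopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for identifying candidate neoepitopes from somatic
    mutation profiles of cancer genomes. Somatic mutation records
    (missense, frameshift, in-frame insertion/deletion) are applied to
    reference coding sequences, translated into mutant proteins, and
    decomposed into overlapping 9-mer neopeptides that contain at least
    one altered residue. Candidate peptides are screened against "self"
    peptide space (reference protein, reference proteome and
    population-variant proteomes) by exact k-mer membership, vaccine
    candidate genes are prioritized by the ratio of deleterious to
    neutral variant counts and by cohort mutation frequency, and a
    pluggable immune-arm layer classifies surviving peptides as HLA
    class I/II binders, CTL epitopes and B-cell epitopes, including
    promiscuous epitopes positive for every configured arm. Cohort,
    partially personalized (tumor versus reference proteome) and fully
    personalized (tumor versus matched normal proteome) screening modes
    are provided, together with a synthetic-data generator that produces
    every input type with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml,
    withr,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
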