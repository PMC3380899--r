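Package: aggregome
Title: SILAC Quantification of Detergent-Insoluble Aggregome Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative mass-spectrometry analysis of detergent-insoluble
    ("aggregome") proteomes with stable-isotope-labeled (SILAC) internal
    standards. Provides in-silico tryptic digestion with modification-aware
    cleavage, monoisotopic peptide and b/y fragment masses, reversed-decoy
    database construction and targeted inclusion-list planning; grouped
    target-decoy filtering of peptide-spectrum matches to a protein-level
    false discovery rate with the 2*nd/nt estimator; protein-level light/heavy
    ratio rollup, population recentering, 1.64*SD significance calling and
    triple-SILAC difference mapping; stoichiometry normalization of
    post-translationally modified peptides (ubiquitin GG remnants, methylated
    RGG motifs) against the parent protein level; targeted MS/MS quantification
    with automatic-gain-control inject-time correction and reference-peptide
    normalization; and a seeded synthetic-data generator with ground-truth
    manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
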