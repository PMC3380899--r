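#' Bundled reference tables
#'
#' Small plain-text tables shipped with the package: the significant-protein
#' table (per-comparison log2 ratio differences and peptide counts for the 42
#' table rows), the arginine-methylation stoichiometry table (XIC intensities
#' and derived ratio/percent columns for 8 modified peptides), the dialkylated
#' (pseudo-GG) reference-peptide table (14 peptides with printed [M+H]+ and
#' targeted-method segments), and the targeted-method peptide list (six
#' peptides with printed isolation centers and quantifier fragments).
#'
#' @return A data.frame (see the corresponding TSV under `inst/extdata` for
#'   column meanings).
#' @name reference_tables
NULL

extdata <- function(file) {
  system.file("extdata", file, package = "aggregome", mustWork = TRUE)
}

#' @rdname reference_tables
#' @export
significant_protein_table <- function() {
  utils::read.delim(extdata("significant_proteins.tsv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
methylation_site_table <- function() {
  utils::read.delim(extdata("methylation_sites.tsv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
gg_reference_table <- function() {
  utils::read.delim(extdata("gg_reference_peptides.tsv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
targeted_method_peptides <- function() {
  utils::read.delim(extdata("targeted_peptides.tsv"), stringsAsFactors = FALSE)
}

#' Bundled TDP-43 sequence
#'
#' The 414-residue TDP-43 protein sequence shipped with the package; its
#' peptide coordinates (ubiquitination sites K84-K224, the RRM1 peptide at
#' F152, the C-terminal glycine-rich peptide at F276) are checked against the
#' bundled reference-peptide tables by the test suite.
#'
#' @return Single character string (the sequence), with the FASTA header as
#'   attribute `header`.
#' @export
tdp43_sequence <- function() {
  fa <- Biostrings::readAAStringSet(extdata("tdp43.fasta"))
  structure(as.character(fa[[1L]]), header = names(fa)[1L])
}
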