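#' Build a concatenated target-decoy protein database
#'
#' Every protein sequence in the input FASTA is reversed and appended to the
#' database under a decoy-prefixed identifier, doubling the entry count.
#' Per-entry length and residue composition are preserved, so decoy matches
#' estimate the false-match rate of the target search.
#'
#' @param fasta_in Path to the input FASTA.
#' @param fasta_out Path for the concatenated target+decoy FASTA. When NULL
#'   the database is returned without being written.
#' @param prefix Identifier prefix marking decoy entries.
#' @return Invisibly, a `Biostrings::AAStringSet` with targets followed by
#'   decoys.
#' @export
reverse_decoy_database <- function(fasta_in, fasta_out = NULL, prefix = "REV_") {
  db <- Biostrings::readAAStringSet(fasta_in)
  ids <- sub("\\s.*$", "", names(db))
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in FASTA: ", ids[duplicated(ids)][1L])
  }
  decoys <- Biostrings::reverse(db)
  names(decoys) <- paste0(prefix, ids)
  names(db) <- ids
  out <- c(db, decoys)
  if (!is.null(fasta_out)) {
    Biostrings::writeXStringSet(out, fasta_out, width = 60L)
  }
  invisible(out)
}

#' Is an identifier a decoy accession?
#'
#' @param id Character vector of protein identifiers.
#' @param prefix Decoy prefix used when the database was built.
#' @return Logical vector.
#' @export
is_decoy_id <- function(id, prefix = "REV_") {
  startsWith(id, prefix)
}
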