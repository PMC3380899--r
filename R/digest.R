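#' Tryptic digestion rules
#'
#' Trypsin cleaves C-terminal to K or R but not when the next residue is
#' proline. `trypticity = "full"` requires both peptide termini at cleavage
#' sites (or protein termini); `"partial"` (semi-tryptic) requires only one.
#'
#' @param max_missed_cleavages Maximum number of internal (unblocked) K/R
#'   cleavage sites allowed inside a peptide.
#' @param trypticity `"full"` or `"partial"`.
#' @param min_length Minimum peptide length to report.
#' @return A list of class `digest_rules`.
#' @export
digest_rules <- function(max_missed_cleavages = 2L,
                         trypticity = c("full", "partial"),
                         min_length = 1L) {
  stopifnot(max_missed_cleavages >= 0L, min_length >= 1L)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 trypticity = match.arg(trypticity),
                 min_length = as.integer(min_length)),
            class = "digest_rules")
}

#' In-silico tryptic digestion of a protein
#'
#' Enumerates tryptic (or semi-tryptic) peptides of a protein under a missed
#' cleavage budget. Site-localized modifications are given in protein
#' coordinates and copied onto the peptides that contain them. A lysine
#' carrying a cleavage-blocking modification (GG remnant, dimethyl-K) never
#' terminates a peptide and does not count toward the missed-cleavage budget:
#' trypsin does not cut at such residues, which is what makes GG-remnant
#' peptides observable with their diagnostic internal lysine.
#'
#' @param protein Uppercase amino-acid string.
#' @param rules A [digest_rules()].
#' @param mods Data.frame with columns `pos` (1-based position in the protein)
#'   and `name` (registry modification name), or NULL.
#' @param protein_id Accession carried onto the peptides.
#' @return List of [peptide()] objects with protein coordinates and flanking
#'   residues.
#' @examples
#' digest("MAAAG", digest_rules(0))           # single peptide, no K/R
#' @export
digest <- function(protein, rules = digest_rules(), mods = NULL,
                   protein_id = NA_character_) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  letters <- strsplit(protein, "")[[1L]]
  unknown <- setdiff(letters, names(AA_MONO))
  if (length(unknown) > 0L) {
    stop("unknown residue letter '", unknown[1L], "' in protein sequence")
  }
  n <- length(letters)
  if (is.null(mods)) {
    mods <- data.frame(pos = integer(0), name = character(0),
                       stringsAsFactors = FALSE)
  }
  mods <- as.data.frame(mods)
  if (nrow(mods) > 0L) {
    mods$pos <- as.integer(mods$pos)
    if (any(mods$pos < 1L | mods$pos > n)) {
      stop("modification position outside protein")
    }
    reg <- mod_registry()
    for (i in seq_len(nrow(mods))) {
      spec <- reg[reg$name == mods$name[i], , drop = FALSE]
      if (nrow(spec) == 0L) stop("unregistered modification: '", mods$name[i], "'")
      if (!grepl(letters[mods$pos[i]], spec$targets, fixed = TRUE)) {
        stop("modification '", mods$name[i], "' does not match residue '",
             letters[mods$pos[i]], "' at protein position ", mods$pos[i])
      }
    }
  }
  blocked <- rep(FALSE, n)
  if (nrow(mods) > 0L) {
    reg <- mod_registry()
    blocks <- reg$name[reg$blocks_cleavage]
    blocked[mods$pos[mods$name %in% blocks]] <- TRUE
  }
  # cleavable[i]: trypsin cuts after position i
  cleavable <- letters %in% c("K", "R") &
    c(letters[-1L], "") != "P" & !blocked
  cleavable[n] <- FALSE  # the protein C-terminus is a boundary, not a cut
  boundaries <- c(0L, which(cleavable), n)  # peptide end positions

  mods_for <- function(from, to) {
    sel <- mods[mods$pos >= from & mods$pos <= to, , drop = FALSE]
    if (nrow(sel) == 0L) return(NULL)
    data.frame(pos = sel$pos - from + 1L, name = sel$name,
               stringsAsFactors = FALSE)
  }
  flank <- function(i) if (i < 1L || i > n) "-" else letters[i]

  make_pep <- function(from, to) {
    peptide(paste(letters[from:to], collapse = ""), mods = mods_for(from, to),
            preceding = flank(from - 1L), following = flank(to + 1L),
            protein_id = protein_id, start = from)
  }
  missed_inside <- function(from, to) {
    if (to <= from) return(0L)
    sum(cleavable[from:(to - 1L)])
  }

  out <- list()
  if (rules$trypticity == "full") {
    nb <- length(boundaries)
    for (i in seq_len(nb - 1L)) {
      for (j in (i + 1L):nb) {
        from <- boundaries[i] + 1L; to <- boundaries[j]
        if (to - from + 1L < rules$min_length) next
        if (missed_inside(from, to) > rules$max_missed_cleavages) break
        out[[length(out) + 1L]] <- make_pep(from, to)
      }
    }
  } else {
    # semi-tryptic: at least one terminus at a boundary
    starts_ok <- c(0L, which(cleavable)) + 1L
    ends_ok <- c(which(cleavable), n)
    for (from in seq_len(n)) {
      for (to in from:n) {
        if (to - from + 1L < rules$min_length) next
        if (!((from %in% starts_ok) || (to %in% ends_ok))) next
        if (missed_inside(from, to) > rules$max_missed_cleavages) next
        out[[length(out) + 1L]] <- make_pep(from, to)
      }
    }
  }
  out
}
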