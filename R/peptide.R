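#' Construct a peptide with site-localized modifications
#'
#' A peptide is an uppercase amino-acid string plus a (possibly empty) list of
#' site-localized modifications, the flanking residues in the parent protein,
#' and protein coordinates. Modification positions are 1-based within the
#' peptide and must sit on a residue that the modification targets.
#'
#' @param sequence Uppercase amino-acid string (standard 20 letters).
#' @param mods Data.frame with columns `pos` (1-based position in peptide) and
#'   `name` (registry name, see [mod_registry()]), or NULL for none.
#' @param preceding,following Flanking residue letters, or `"-"` at a protein
#'   terminus.
#' @param protein_id Accession of the parent protein (may be NA).
#' @param start 1-based start position within the parent protein (may be NA).
#' @return An object of class `peptide`.
#' @examples
#' p <- peptide("TGHSKGFGFVR", mods = data.frame(pos = 5, name = "gg"))
#' peptide_mass(p)$mh
#' @export
peptide <- function(sequence, mods = NULL, preceding = "-", following = "-",
                    protein_id = NA_character_, start = NA_integer_) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  letters <- strsplit(sequence, "")[[1L]]
  unknown <- setdiff(letters, names(AA_MONO))
  if (length(unknown) > 0L) {
    stop("unknown residue letter '", unknown[1L], "' in sequence")
  }
  if (is.null(mods)) {
    mods <- data.frame(pos = integer(0), name = character(0),
                       stringsAsFactors = FALSE)
  }
  mods <- as.data.frame(mods)
  if (nrow(mods) > 0L) {
    mods$pos <- as.integer(mods$pos)
    if (any(mods$pos < 1L | mods$pos > length(letters))) {
      stop("modification position outside peptide")
    }
    reg <- mod_registry()
    for (i in seq_len(nrow(mods))) {
      spec <- reg[reg$name == mods$name[i], , drop = FALSE]
      if (nrow(spec) == 0L) stop("unregistered modification: '", mods$name[i], "'")
      res <- letters[mods$pos[i]]
      if (!grepl(res, spec$targets, fixed = TRUE)) {
        stop("modification '", mods$name[i], "' cannot sit on residue '",
             res, "' at position ", mods$pos[i])
      }
    }
  }
  structure(
    list(sequence = sequence, mods = mods, preceding = preceding,
         following = following, protein_id = protein_id,
         start = as.integer(start)),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(format_peptide_notation(x), "\n")
  invisible(x)
}

#' Render a peptide in flanked dot notation
#'
#' Produces the field-standard `X.PEPTIDE.Z` presentation with bracketed mass
#' offsets after modified residues, e.g. `K.TGHSK[+114.0429]GFGFVR.F`.
#'
#' @param pep A [peptide()].
#' @return A single string.
#' @export
format_peptide_notation <- function(pep) {
  letters <- strsplit(pep$sequence, "")[[1L]]
  if (nrow(pep$mods) > 0L) {
    deltas <- mod_delta(pep$mods$name)
    for (i in seq_len(nrow(pep$mods))) {
      p <- pep$mods$pos[i]
      letters[p] <- sprintf("%s[%+0.4f]", letters[p], deltas[i])
    }
  }
  paste0(pep$preceding, ".", paste(letters, collapse = ""), ".", pep$following)
}

#' Parse flanked peptide notation
#'
#' Accepts `X.PEPTIDE.Z` (flanks optional) with modifications written either
#' as bracketed mass offsets (`K[+114.0429]`, matched to the registry within
#' 0.01 Da) or bracketed registry names (`K[gg]`).
#'
#' @param x A single notation string.
#' @return A [peptide()].
#' @export
parse_peptide_notation <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  preceding <- "-"; following <- "-"
  core <- x
  m <- regmatches(x, regexec("^([A-Z-])\\.(.+)\\.([A-Z-])$", x))[[1L]]
  if (length(m) == 4L) {
    preceding <- m[2L]; core <- m[3L]; following <- m[4L]
  }
  seq_chars <- character(0)
  mods <- data.frame(pos = integer(0), name = character(0),
                     stringsAsFactors = FALSE)
  reg <- mod_registry()
  i <- 1L
  chars <- strsplit(core, "")[[1L]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1L]
      if (is.na(j)) stop("unbalanced '[' in peptide notation")
      tag <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (grepl("^[+-]?[0-9.]+$", tag)) {
        delta <- as.numeric(tag)
        k <- which(abs(reg$delta_mass - delta) < 0.01)
        if (length(k) == 0L) stop("no registered modification near ", tag, " Da")
        name <- reg$name[k[1L]]
      } else {
        name <- tag
      }
      mods <- rbind(mods, data.frame(pos = length(seq_chars), name = name,
                                     stringsAsFactors = FALSE))
      i <- j + 1L
    } else {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  peptide(paste(seq_chars, collapse = ""), mods = mods,
          preceding = preceding, following = following)
}

#' Monoisotopic mass of a modified peptide
#'
#' Neutral mass is the sum of monoisotopic residue masses plus water plus all
#' modification deltas; `mh` is the singly protonated mass [M+H]+ and
#' `mz_by_charge` gives (neutral + z*proton)/z for the requested charges.
#'
#' @param pep A [peptide()] or a plain sequence string.
#' @param charges Integer charges for which m/z is reported.
#' @return An object of class `mass_result`: a list with `neutral_mass`, `mh`,
#'   and `mz_by_charge`.
#' @examples
#' peptide_mass("G")$mh           # 76.0393
#' @export
peptide_mass <- function(pep, charges = 1:3) {
  if (is.character(pep)) pep <- peptide(pep)
  stopifnot(inherits(pep, "peptide"))
  letters <- strsplit(pep$sequence, "")[[1L]]
  neutral <- sum(AA_MONO[letters]) + WATER_MASS + sum(mod_delta(pep$mods$name))
  mz <- (neutral + charges * PROTON_MASS) / charges
  names(mz) <- as.character(charges)
  structure(
    list(neutral_mass = neutral, mh = neutral + PROTON_MASS, mz_by_charge = mz),
    class = "mass_result"
  )
}

#' @export
print.mass_result <- function(x, ...) {
  cat(sprintf("neutral %.4f Da, [M+H]+ %.4f\n", x$neutral_mass, x$mh))
  invisible(x)
}

#' Heavy SILAC partner mass of a peptide
#'
#' Adds the Lys8 delta (+8.014199 Da) per lysine and the Arg10 delta
#' (+10.008269 Da) per arginine to the light mass; used to pair light and
#' heavy extracted-ion features. A peptide without K or R is its own heavy
#' partner.
#'
#' @inheritParams peptide_mass
#' @return A `mass_result` for the fully heavy-labeled peptide.
#' @export
heavy_partner_mass <- function(pep, charges = 1:3) {
  if (is.character(pep)) pep <- peptide(pep)
  letters <- strsplit(pep$sequence, "")[[1L]]
  extra <- sum(letters == "K") * mod_registry("silac_k8")$delta_mass +
    sum(letters == "R") * mod_registry("silac_r10")$delta_mass
  light <- peptide_mass(pep, charges)
  mz <- light$mz_by_charge + extra / charges
  structure(
    list(neutral_mass = light$neutral_mass + extra,
         mh = light$mh + extra, mz_by_charge = mz),
    class = "mass_result"
  )
}

#' b/y fragment-ion ladder of a peptide
#'
#' b ions are the first i residues (plus their modifications) plus a proton;
#' y ions are the last j residues plus water plus a proton. Multiply charged
#' variants follow the usual (m + z*proton)/z rule. Only b and y ions are
#' produced.
#'
#' @inheritParams peptide_mass
#' @param ion_types Subset of `c("b", "y")`.
#' @param max_charge Highest fragment charge to emit.
#' @return Data.frame with columns `ion` (e.g. `"y6"`), `charge`, `mz`, and
#'   `mz_2dp` (presentation rounding for method planning).
#' @examples
#' fl <- fragment_ladder(peptide("FGVHLISNVYGR"))
#' fl[fl$ion == "y6", "mz_2dp"]   # 695.35
#' @export
fragment_ladder <- function(pep, ion_types = c("b", "y"), max_charge = 1L) {
  if (is.character(pep)) pep <- peptide(pep)
  letters <- strsplit(pep$sequence, "")[[1L]]
  n <- length(letters)
  if (n < 2L) stop("fragment ladder requires peptide length >= 2")
  ion_types <- match.arg(ion_types, c("b", "y"), several.ok = TRUE)
  res <- AA_MONO[letters]
  if (nrow(pep$mods) > 0L) {
    deltas <- mod_delta(pep$mods$name)
    for (i in seq_len(nrow(pep$mods))) {
      res[pep$mods$pos[i]] <- res[pep$mods$pos[i]] + deltas[i]
    }
  }
  rows <- list()
  for (z in seq_len(max_charge)) {
    if ("b" %in% ion_types) {
      bm <- cumsum(res)[seq_len(n - 1L)]  # neutral b fragment = residue sum
      rows[[length(rows) + 1L]] <- data.frame(
        ion = paste0("b", seq_len(n - 1L)), charge = z,
        mz = (bm + z * PROTON_MASS) / z, stringsAsFactors = FALSE)
    }
    if ("y" %in% ion_types) {
      ym <- cumsum(rev(res))[seq_len(n - 1L)] + WATER_MASS
      rows[[length(rows) + 1L]] <- data.frame(
        ion = paste0("y", seq_len(n - 1L)), charge = z,
        mz = (ym + z * PROTON_MASS) / z, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$mz_2dp <- round(out$mz, 2L)
  rownames(out) <- NULL
  out
}
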