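#' Monoisotopic residue masses and physical constants
#'
#' Standard monoisotopic masses of the 20 amino-acid residues (Da), plus the
#' proton and water masses used throughout mass computation. All values are
#' monoisotopic; average masses are deliberately not supported.
#'
#' @format Named numeric vector, one element per residue letter.
#' @export
AA_MONO <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' @rdname AA_MONO
#' @export
PROTON_MASS <- 1.00727646

#' @rdname AA_MONO
#' @export
WATER_MASS <- 18.0105646

#' Built-in modification registry
#'
#' The set of modifications used for aggregome analysis: the ubiquitin GG
#' remnant left on lysine after tryptic digestion (and its mass-identical
#' dialkyl mimic produced by hot iodoacetamide treatment), arginine/lysine
#' mono- and dimethylation, methionine oxidation, and the heavy SILAC labels
#' Lys8 (13C6 15N2) and Arg10 (13C6 15N4). A GG remnant or a dimethyl group on
#' lysine blocks tryptic cleavage at that residue.
#'
#' @param name Optional modification name; when given, the single matching
#'   registry row is returned (error if unknown).
#' @return A data.frame with columns `name`, `delta_mass` (monoisotopic Da),
#'   `targets` (residue letters the modification may sit on), and
#'   `blocks_cleavage`.
#' @examples
#' mod_registry()
#' mod_registry("gg")$delta_mass
#' @export
mod_registry <- function(name = NULL) {
  reg <- data.frame(
    name = c("gg", "dialkyl", "methyl", "dimethyl", "ox", "silac_k8", "silac_r10"),
    delta_mass = c(114.042927, 114.042927, 14.015650, 28.031300,
                   15.994915, 8.014199, 10.008269),
    targets = c("K", "K", "KR", "KR", "M", "K", "R"),
    blocks_cleavage = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(reg)
  hit <- reg[reg$name == name, , drop = FALSE]
  if (nrow(hit) == 0L) stop("unregistered modification: '", name, "'")
  hit
}

#' Look up modification deltas by name
#'
#' @param names Character vector of registry names.
#' @return Numeric vector of monoisotopic mass deltas (Da).
#' @keywords internal
mod_delta <- function(names) {
  if (length(names) == 0L) return(numeric(0))
  reg <- mod_registry()
  idx <- match(names, reg$name)
  if (anyNA(idx)) {
    stop("unregistered modification: '", names[which(is.na(idx))[1L]], "'")
  }
  reg$delta_mass[idx]
}
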