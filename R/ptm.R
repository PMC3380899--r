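#' Light/heavy ratio of a modified peptide
#'
#' @param light,heavy Extracted-ion intensities (signal-to-noise) of the
#'   unlabeled and SILAC internal-standard forms.
#' @return The light/heavy ratio, or NA (with a warning-free "not
#'   quantifiable" marker) when either channel is non-positive. Full precision
#'   is retained; use [signif()] with 3 digits for reporting.
#' @examples
#' modified_peptide_ratio(780, 926)   # 0.842...
#' @export
modified_peptide_ratio <- function(light, heavy) {
  ifelse(light > 0 & heavy > 0, light / heavy, NA_real_)
}

#' Modification stoichiometry table with parent-protein normalization
#'
#' For each modified peptide, per-condition light/heavy ratios are converted
#' to an unnormalized percent-of-control (`100 * ratio_cond / ratio_mock`) and
#' then normalized by the parent protein's unmodified-peptide percent-of-
#' control for the same condition (`100 * unnorm / unmodified`). The
#' normalization separates a change in modification stoichiometry from a
#' change in the protein's own abundance in the fraction: a modified peptide
#' that merely tracks its protein normalizes to 100 percent.
#'
#' @param sites Data.frame with one row per modified peptide: `protein`,
#'   `site` (e.g. `"R291-me2"`), `peptide`, plus per-condition intensity
#'   columns `light_<cond>` and `heavy_<cond>` for `mock` and each
#'   experimental condition.
#' @param unmodified_percent Data.frame `protein`, `condition`,
#'   `percent_of_mock` giving the protein-level unmodified-peptide
#'   percent-of-control (from [quantify_proteins()] on unmodified features:
#'   `100 * 2^(difference vs mock)`).
#' @param conditions Experimental (non-mock) condition labels.
#' @return Data.frame with per-condition `ratio_`, `unnorm_pct_` and
#'   `norm_pct_` columns (full precision; `signif(x, 3)` reproduces the
#'   printed presentation).
#' @export
stoichiometry_table <- function(sites, unmodified_percent,
                                conditions = c("tdp43", "tdps6")) {
  out <- sites
  rm <- modified_peptide_ratio(sites$light_mock, sites$heavy_mock)
  out$ratio_mock <- rm
  for (cn in conditions) {
    rc <- modified_peptide_ratio(sites[[paste0("light_", cn)]],
                                 sites[[paste0("heavy_", cn)]])
    out[[paste0("ratio_", cn)]] <- rc
    unnorm <- 100 * rc / rm
    out[[paste0("unnorm_pct_", cn)]] <- unnorm
    up <- unmodified_percent[unmodified_percent$condition == cn, , drop = FALSE]
    prot_pct <- up$percent_of_mock[match(sites$protein, up$protein)]
    out[[paste0("norm_pct_", cn)]] <- ifelse(
      is.na(prot_pct), NA_real_, 100 * unnorm / prot_pct)
  }
  out
}

#' Detect and annotate modification-site candidates among accepted PSMs
#'
#' Groups accepted modified PSMs by (protein, site, modification). Site labels
#' are 1-based protein coordinates, e.g. `"K145-gg"`; a peptide carrying two
#' modifications yields two site records sharing the same PSMs. PSMs must
#' carry `peptide`, `mods` (semicolon `pos:name`, peptide coordinates),
#' `protein_ids` and `peptide_start` (1-based start of the peptide in the
#' protein) columns.
#'
#' @param accepted Data.frame of accepted PSMs.
#' @param mod_names Which registry modifications to report (default: the PTMs
#'   of interest -- GG remnants and methylation).
#' @return Data.frame `protein`, `site`, `mod`, `peptide`, `mods_string`
#'   (the site-localized modification string of the supporting PSMs),
#'   `n_psms`, `spectrum_ids` (semicolon list); zero rows when nothing is
#'   modified.
#' @export
detect_ptm_candidates <- function(accepted,
                                  mod_names = c("gg", "methyl", "dimethyl")) {
  empty <- data.frame(protein = character(0), site = character(0),
                      mod = character(0), peptide = character(0),
                      mods_string = character(0),
                      n_psms = integer(0), spectrum_ids = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(accepted) || nrow(accepted) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(accepted))) {
    mods <- parse_mod_string(accepted$mods[i])
    if (nrow(mods) == 0L) next
    mods <- mods[mods$name %in% mod_names, , drop = FALSE]
    if (nrow(mods) == 0L) next
    start <- accepted$peptide_start[i]
    if (is.null(start) || is.na(start)) {
      stop("peptide_start required to place sites on the protein")
    }
    letters <- strsplit(accepted$peptide[i], "")[[1L]]
    for (j in seq_len(nrow(mods))) {
      res <- letters[mods$pos[j]]
      spec <- mod_registry(mods$name[j])
      if (!grepl(res, spec$targets, fixed = TRUE)) {
        stop("site/residue mismatch: '", mods$name[j], "' on '", res,
             "' in ", accepted$peptide[i])
      }
      prot_pos <- start + mods$pos[j] - 1L
      for (prot in strsplit(accepted$protein_ids[i], ";", fixed = TRUE)[[1L]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein = prot,
          site = paste0(res, prot_pos, "-", mods$name[j]),
          mod = mods$name[j],
          peptide = accepted$peptide[i],
          mods_string = accepted$mods[i],
          spectrum_id = accepted$spectrum_id[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  flat <- do.call(rbind, rows)
  key <- paste(flat$protein, flat$site, flat$mod, flat$peptide, sep = "\r")
  agg <- lapply(split(flat, key), function(d) {
    data.frame(protein = d$protein[1L], site = d$site[1L], mod = d$mod[1L],
               peptide = d$peptide[1L], mods_string = d$mods_string[1L],
               n_psms = nrow(d),
               spectrum_ids = paste(sort(unique(d$spectrum_id)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$protein, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# "5:gg;7:me2" -> data.frame(pos, name); "" -> zero rows
parse_mod_string <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(pos = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  data.frame(pos = as.integer(vapply(kv, `[`, "", 1L)),
             name = vapply(kv, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# data.frame(pos, name) -> "5:gg;7:me2"
format_mod_string <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  paste(paste0(mods$pos, ":", mods$name), collapse = ";")
}
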