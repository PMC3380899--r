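#' Read a SILAC feature table
#'
#' Columns: `peptide`, `mods` (empty for unmodified), `protein_group`,
#' `condition` (`mock`, `tdp43`, `tdps6`), `replicate`, `gel_region`,
#' `light_intensity`, `heavy_intensity`. Intensities are extracted-ion
#' signal-to-noise values; a record is quantifiable only when both channels
#' are positive.
#'
#' @param path File path.
#' @return Data.frame of features.
#' @export
read_feature_table <- function(path) {
  fx <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("peptide", "protein_group", "condition", "replicate",
              "gel_region", "light_intensity", "heavy_intensity")
  missing <- setdiff(needed, names(fx))
  if (length(missing) > 0L) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!"mods" %in% names(fx)) fx$mods <- ""
  fx$mods[is.na(fx$mods)] <- ""
  fx
}

#' Protein-level light/heavy rollup for one record set
#'
#' The protein-level log2(light/heavy) ratio is the median of peptide-level
#' log2 ratios across peptides and gel regions; the median is robust to
#' occasional outlier peptides (mis-assigned or interference-affected
#' features). Records with a non-positive channel are rejected and counted.
#'
#' @param records Data.frame of features for one protein in one
#'   condition/replicate.
#' @return List with `log2_ratio` (median), `sd` (dispersion across peptide
#'   ratios), `n` (quantifiable records) and `n_rejected`.
#' @export
protein_log2_ratio <- function(records) {
  ok <- records$light_intensity > 0 & records$heavy_intensity > 0
  r <- records[ok, , drop = FALSE]
  if (nrow(r) == 0L) {
    return(list(log2_ratio = NA_real_, sd = NA_real_, n = 0L,
                n_rejected = sum(!ok)))
  }
  lr <- log2(r$light_intensity / r$heavy_intensity)
  list(log2_ratio = stats::median(lr),
       sd = if (length(lr) > 1L) stats::sd(lr) else NA_real_,
       n = length(lr), n_rejected = sum(!ok))
}

#' Roll features up to per-protein condition ratios and differences
#'
#' For each protein and condition the peptide-level log2(light/heavy) ratios
#' are rolled up per replicate ([protein_log2_ratio()]), replicates are then
#' averaged, and the three pairwise differences are formed:
#' `d43 = log2(TDP-43) - log2(mock)`, `dS6 = log2(TDP-S6) - log2(mock)` and
#' `dS6_43 = log2(TDP-S6) - log2(TDP-43)`, so that `dS6_43 == dS6 - d43`
#' identically. Modified peptides (non-empty `mods`) are excluded from the
#' rollup: protein abundance is measured on unmodified peptides.
#'
#' @param features Data.frame from [read_feature_table()].
#' @param conditions Condition labels: mock first, then the two overexpression
#'   conditions.
#' @return A `protein_quant` data.frame with per-condition ratios, peptide
#'   counts, replicate coverage and the three differences.
#' @export
quantify_proteins <- function(features,
                              conditions = c("mock", "tdp43", "tdps6")) {
  if (!"mods" %in% names(features)) features$mods <- ""
  features$mods[is.na(features$mods)] <- ""
  fx <- features[features$mods == "", , drop = FALSE]
  proteins <- sort(unique(fx$protein_group))
  rows <- lapply(proteins, function(p) {
    sub <- fx[fx$protein_group == p, , drop = FALSE]
    cond_mean <- setNames(rep(NA_real_, 3L), conditions)
    cond_n <- setNames(rep(0L, 3L), conditions)
    cond_reps <- setNames(rep(0L, 3L), conditions)
    for (cn in conditions) {
      cs <- sub[sub$condition == cn, , drop = FALSE]
      if (nrow(cs) == 0L) next
      reps <- sort(unique(cs$replicate))
      per_rep <- vapply(reps, function(r) {
        protein_log2_ratio(cs[cs$replicate == r, , drop = FALSE])$log2_ratio
      }, numeric(1L))
      per_rep <- per_rep[!is.na(per_rep)]
      if (length(per_rep) == 0L) next
      cond_mean[cn] <- mean(per_rep)
      cond_n[cn] <- sum(cs$light_intensity > 0 & cs$heavy_intensity > 0)
      cond_reps[cn] <- length(per_rep)
    }
    data.frame(
      protein_group = p,
      log2_mock = cond_mean[1L], log2_tdp43 = cond_mean[2L],
      log2_tdps6 = cond_mean[3L],
      n_mock = cond_n[1L], n_tdp43 = cond_n[2L], n_tdps6 = cond_n[3L],
      reps_mock = cond_reps[1L], reps_tdp43 = cond_reps[2L],
      reps_tdps6 = cond_reps[3L],
      d43 = cond_mean[2L] - cond_mean[1L],
      dS6 = cond_mean[3L] - cond_mean[1L],
      dS6_43 = cond_mean[3L] - cond_mean[2L],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("protein_quant", "data.frame")
  out
}

#' Recenter a population of log2 ratio differences
#'
#' Subtracts the population mean so the null bulk of the distribution sits at
#' zero; the subtracted mean is reported as an attribute for the audit trail.
#'
#' @param x Numeric vector of differences (NAs tolerated and preserved).
#' @return Numeric vector with attribute `mean_subtracted`.
#' @export
recenter <- function(x) {
  m <- mean(x, na.rm = TRUE)
  structure(x - m, mean_subtracted = m)
}

#' Significance cutoffs from recentered difference populations
#'
#' The cutoff for each comparison is `multiplier` times the sample standard
#' deviation of the recentered differences for that comparison; the default
#' 1.64 corresponds to the one-tailed 95 percent point of the normal
#' distribution (p < 0.05 one-tailed).
#'
#' @param differences Data.frame (or named list) with numeric columns `d43`,
#'   `dS6`, `dS6_43` of recentered differences.
#' @param multiplier Cutoff multiplier (default 1.64).
#' @return Named numeric vector of cutoffs, one per comparison.
#' @export
significance_cutoffs <- function(differences, multiplier = 1.64) {
  comps <- c("d43", "dS6", "dS6_43")
  out <- vapply(comps, function(cc) {
    v <- differences[[cc]]
    v <- v[!is.na(v)]
    if (length(v) < 3L) return(NA_real_)
    multiplier * stats::sd(v)
  }, numeric(1L))
  names(out) <- comps
  out
}

#' Classify proteins into significance groups
#'
#' Group 1: changed beyond the cutoff versus mock in both overexpression
#' models, with the same sign. Group 2: changed only in the TDP-S6 model.
#' Group 3: changed only in the TDP-43 model. Group 4 ("lost in TDP-S6"):
#' `dS6_43` falls below minus its cutoff (one-tailed, signed) -- this label
#' can attach in addition to groups 1-3, mirroring the dual marking of such
#' proteins. Everything else is unchanged. The direction comes from the sign
#' of the triggering difference. Comparisons with missing values produce
#' partial calls (`not_evaluable` lists them).
#'
#' @param quant A `protein_quant` data.frame with recentered `d43`, `dS6`,
#'   `dS6_43` columns.
#' @param cutoffs Named cutoffs from [significance_cutoffs()].
#' @return `quant` with `group` (`group1_both`, `group2_s6`, `group3_43`,
#'   `group4_lost_in_s6`, `unchanged`), `lost_in_s6` flag, `direction`
#'   (`up`/`down`/NA) and `not_evaluable` columns.
#' @export
classify_proteins <- function(quant, cutoffs) {
  n <- nrow(quant)
  group <- rep("unchanged", n)
  direction <- rep(NA_character_, n)
  lost <- rep(FALSE, n)
  not_eval <- character(n)
  for (i in seq_len(n)) {
    d43 <- quant$d43[i]; dS6 <- quant$dS6[i]; dd <- quant$dS6_43[i]
    miss <- c("d43", "dS6", "dS6_43")[c(is.na(d43), is.na(dS6), is.na(dd))]
    not_eval[i] <- paste(miss, collapse = ";")
    hit43 <- !is.na(d43) && abs(d43) > cutoffs["d43"]
    hitS6 <- !is.na(dS6) && abs(dS6) > cutoffs["dS6"]
    if (hit43 && hitS6 && sign(d43) == sign(dS6)) {
      group[i] <- "group1_both"
      direction[i] <- if (d43 > 0) "up" else "down"
    } else if (hitS6 && !hit43) {
      group[i] <- "group2_s6"
      direction[i] <- if (dS6 > 0) "up" else "down"
    } else if (hit43 && !hitS6) {
      group[i] <- "group3_43"
      direction[i] <- if (d43 > 0) "up" else "down"
    }
    if (!is.na(dd) && dd < -cutoffs["dS6_43"]) {
      lost[i] <- TRUE
      if (group[i] == "unchanged") {
        group[i] <- "group4_lost_in_s6"
        direction[i] <- "down"
      }
    }
  }
  quant$group <- group
  quant$lost_in_s6 <- lost
  quant$direction <- direction
  quant$not_evaluable <- not_eval
  quant
}

#' Convert a log2 difference to a linear fold change
#'
#' @param log2_difference Numeric vector.
#' @param presentation Round to the nearest integer when the fold is at least
#'   2 (the convention used when reporting "11-fold", "80-fold").
#' @return Numeric vector of linear folds.
#' @examples
#' fold_change(3.51)   # 11
#' fold_change(6.32)   # 80
#' @export
fold_change <- function(log2_difference, presentation = TRUE) {
  f <- 2^log2_difference
  if (presentation) ifelse(f >= 2, round(f), f) else f
}

#' Triple-SILAC map coordinates
#'
#' Produces per-protein coordinates for the scatter of recentered log2 ratio
#' differences: x is the recentered TDP-43 minus mock difference and y is,
#' by default, the recentered TDP-S6 minus TDP-43 difference (`dS6_43`); the
#' simpler TDP-S6 minus mock difference is available as an alternative y
#' axis. The axis assignment is recorded in the returned attributes.
#'
#' @param quant A classified `protein_quant` (recentered differences).
#' @param y_axis `"dS6_43"` (default) or `"dS6"`.
#' @return Data.frame `protein_group`, `x`, `y`, `group`, `lost_in_s6` with
#'   attributes `x_axis`, `y_axis`.
#' @export
triple_map <- function(quant, y_axis = c("dS6_43", "dS6")) {
  y_axis <- match.arg(y_axis)
  out <- data.frame(protein_group = quant$protein_group,
                    x = quant$d43, y = quant[[y_axis]],
                    group = if ("group" %in% names(quant)) quant$group else NA,
                    lost_in_s6 = if ("lost_in_s6" %in% names(quant))
                      quant$lost_in_s6 else NA,
                    stringsAsFactors = FALSE)
  attr(out, "x_axis") <- "d43"
  attr(out, "y_axis") <- y_axis
  out
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant: %d proteins, %d quantified in all conditions\n",
              nrow(x), sum(stats::complete.cases(x[, c("d43", "dS6")]))))
  NextMethod()
}
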