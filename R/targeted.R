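#' Sum required fragment intensities in a targeted MS/MS scan
#'
#' Every required fragment must be present (a peak within `tolerance` m/z)
#' for a positive identification; when all are found, the matched peak
#' intensities are summed (per fragment, the closest peak in m/z is taken).
#' When any required fragment is missing the scan yields no quantity (NA),
#' absence being a value rather than an error.
#'
#' @param scan Data.frame with `mz` and `intensity` columns (fragment peaks).
#' @param required Numeric vector (length >= 2) of required fragment m/z.
#' @param tolerance Match tolerance in m/z (default 0.5, ion-trap MS/MS).
#' @return Summed intensity, or NA when a required fragment is absent.
#' @export
sum_required_fragments <- function(scan, required, tolerance = 0.5) {
  stopifnot(length(required) >= 2L)
  if (nrow(scan) == 0L) return(NA_real_)
  total <- 0
  for (f in required) {
    d <- abs(scan$mz - f)
    i <- which.min(d)
    if (d[i] > tolerance) return(NA_real_)
    total <- total + scan$intensity[i]
  }
  total
}

#' Correct a summed MS/MS intensity for automatic gain control
#'
#' The ion trap fills to a fixed ion count (AGC target), so raw fragment
#' intensity reflects fill time, not analyte flux. Multiplying by
#' `max_inject / inject_time` (150 ms maximum fill) cancels the AGC effect,
#' putting weak and multiplexed spectra on a common flux scale.
#'
#' @param intensity Raw summed fragment intensity.
#' @param inject_time Ion inject time in ms; must be positive.
#' @param max_inject Maximum inject time in ms (default 150).
#' @return Corrected intensity = intensity * max_inject / inject_time.
#' @examples
#' agc_correct(1000, 75)   # 2000
#' @export
agc_correct <- function(intensity, inject_time, max_inject = 150) {
  if (any(inject_time <= 0)) stop("inject_time must be positive")
  intensity * max_inject / inject_time
}

#' Peak intensity from an extracted-ion chromatogram
#'
#' Summarizes a precursor XIC trace by its apex intensity within the elution
#' window (`summary = "apex"`); a trapezoidal area is available as an
#' alternative. The window is recorded on the result.
#'
#' @param trace Data.frame with `time` and `intensity` columns.
#' @param window Numeric length-2 elution window (same units as `time`).
#' @param summary `"apex"` (default) or `"area"`.
#' @return Peak intensity (or area), NA for an empty window; attribute
#'   `window`.
#' @export
xic_quantify <- function(trace, window = range(trace$time),
                         summary = c("apex", "area")) {
  summary <- match.arg(summary)
  if (nrow(trace) == 0L) return(structure(NA_real_, window = window))
  sel <- trace$time >= window[1L] & trace$time <= window[2L]
  if (!any(sel)) return(structure(NA_real_, window = window))
  tr <- trace[sel, , drop = FALSE]
  v <- if (summary == "apex") {
    max(tr$intensity)
  } else {
    if (nrow(tr) < 2L) 0 else {
      ord <- order(tr$time)
      sum(diff(tr$time[ord]) *
            (tr$intensity[ord][-1L] + tr$intensity[ord][-nrow(tr)]) / 2)
    }
  }
  structure(v, window = window)
}

#' Normalize targeted intensities to reference peptides and summarize
#'
#' Each target intensity is divided by each reference-peptide intensity in
#' the same sample, the experimental/control ratio is formed per reference
#' and replicate, and the per-peptide summary is the mean log2 ratio over the
#' k = references x replicates values, with a t-based 95 percent confidence
#' interval (`qt(0.975, k - 1) * sd / sqrt(k)`); a normal-approximation CI
#' over replicates only is available via `ci`.
#'
#' @param intensities Data.frame `peptide_id`, `sample`, `replicate`,
#'   `intensity` of AGC-corrected (or XIC) target intensities.
#' @param references Data.frame of the same shape for the (two) reference
#'   peptides; every reference must be quantified in every sample/replicate
#'   used, samples lacking one are excluded and reported.
#' @param control Label of the control sample.
#' @param ci `"t_refs_reps"` (default: t over references x replicates) or
#'   `"t_reps"` (t over replicate means).
#' @return An object of class `targeted_result`: data.frame with one row per
#'   peptide and experimental sample: `mean_log2`, `ci95`, `percent_change`
#'   (= 100 * (2^mean_log2 - 1)), `k`; attribute `excluded` lists dropped
#'   sample/replicates.
#' @export
normalize_and_summarize <- function(intensities, references, control,
                                    ci = c("t_refs_reps", "t_reps")) {
  ci <- match.arg(ci)
  ref_ids <- sort(unique(references$peptide_id))
  samples <- unique(intensities$sample)
  stopifnot(control %in% samples)
  ref_val <- function(rid, smp, rep) {
    v <- references$intensity[references$peptide_id == rid &
                                references$sample == smp &
                                references$replicate == rep]
    if (length(v) == 1L && is.finite(v) && v > 0) v else NA_real_
  }
  excluded <- character(0)
  rows <- list()
  for (pid in sort(unique(intensities$peptide_id))) {
    tgt <- intensities[intensities$peptide_id == pid, , drop = FALSE]
    for (smp in setdiff(samples, control)) {
      vals <- list(t_all = numeric(0), rep = integer(0))
      for (rep in sort(unique(tgt$replicate))) {
        t_exp <- tgt$intensity[tgt$sample == smp & tgt$replicate == rep]
        t_ctl <- tgt$intensity[tgt$sample == control & tgt$replicate == rep]
        if (length(t_exp) != 1L || length(t_ctl) != 1L ||
            !is.finite(t_exp) || !is.finite(t_ctl)) next
        for (rid in ref_ids) {
          r_exp <- ref_val(rid, smp, rep)
          r_ctl <- ref_val(rid, control, rep)
          if (is.na(r_exp) || is.na(r_ctl)) {
            excluded <- c(excluded, paste0(smp, "/rep", rep, "/", rid))
            next
          }
          ratio <- (t_exp / r_exp) / (t_ctl / r_ctl)
          vals$t_all <- c(vals$t_all, log2(ratio))
          vals$rep <- c(vals$rep, rep)
        }
      }
      k <- length(vals$t_all)
      if (k == 0L) next
      m <- mean(vals$t_all)
      half <- if (ci == "t_refs_reps") {
        if (k > 1L) stats::qt(0.975, k - 1L) * stats::sd(vals$t_all) / sqrt(k)
        else NA_real_
      } else {
        rep_means <- tapply(vals$t_all, vals$rep, mean)
        kr <- length(rep_means)
        if (kr > 1L) stats::qt(0.975, kr - 1L) * stats::sd(rep_means) / sqrt(kr)
        else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = pid, sample = smp, mean_log2 = m, ci95 = half,
        percent_change = 100 * (2^m - 1), k = k, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, excluded = unique(excluded),
            class = c("targeted_result", "data.frame"))
}

#' @export
print.targeted_result <- function(x, ...) {
  df <- as.data.frame(x)
  df$mean_log2 <- round(df$mean_log2, 2L)
  df$ci95 <- round(df$ci95, 2L)
  df$percent_change <- round(df$percent_change)
  print(df)
  ex <- attr(x, "excluded")
  if (length(ex) > 0L) cat("excluded:", paste(ex, collapse = ", "), "\n")
  invisible(x)
}

#' Read targeted scan and XIC trace tables
#'
#' Scan TSV columns: `sample`, `replicate`, `peptide_id`, `inject_time_ms`,
#' `fragments` (semicolon-separated `mz:intensity` pairs). Trace TSV columns:
#' `sample`, `replicate`, `peptide_id`, `time`, `intensity`.
#'
#' @param path File path.
#' @return For scans: data.frame with a `peaks` list-column of per-scan
#'   data.frames. For traces: plain data.frame.
#' @export
read_targeted_scans <- function(path) {
  sc <- utils::read.delim(path, stringsAsFactors = FALSE)
  sc$peaks <- lapply(sc$fragments, function(f) {
    if (is.na(f) || !nzchar(f)) {
      return(data.frame(mz = numeric(0), intensity = numeric(0)))
    }
    kv <- strsplit(strsplit(f, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    data.frame(mz = as.numeric(vapply(kv, `[`, "", 1L)),
               intensity = as.numeric(vapply(kv, `[`, "", 2L)))
  })
  sc
}

#' @rdname read_targeted_scans
#' @export
read_xic_traces <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
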