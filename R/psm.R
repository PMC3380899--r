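#' Read and write PSM tables
#'
#' The PSM (peptide-spectrum match) TSV dialect has columns `spectrum_id`,
#' `peptide`, `mods` (semicolon-separated `pos:name` pairs, empty for none),
#' `charge`, `xcorr`, `delta_cn`, `observed_mh`, `theoretical_mh`,
#' `trypticity` (`full`/`partial`), `is_decoy` (0/1) and `protein_ids`
#' (semicolon-separated accessions). The signed precursor mass error in ppm is
#' recomputed as (observed - theoretical)/theoretical * 1e6.
#'
#' @param path File path.
#' @return Data.frame of PSMs with a `ppm_error` column.
#' @export
read_psm_table <- function(path) {
  psm <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("spectrum_id", "peptide", "charge", "xcorr", "delta_cn",
              "observed_mh", "theoretical_mh", "trypticity", "is_decoy",
              "protein_ids")
  missing <- setdiff(needed, names(psm))
  if (length(missing) > 0L) {
    stop("PSM table lacks columns: ", paste(missing, collapse = ", "))
  }
  psm$is_decoy <- as.logical(psm$is_decoy)
  psm$ppm_error <- (psm$observed_mh - psm$theoretical_mh) /
    psm$theoretical_mh * 1e6
  psm
}

#' @rdname read_psm_table
#' @param psm Data.frame of PSMs.
#' @export
write_psm_table <- function(psm, path) {
  utils::write.table(psm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Target-decoy FDR estimate
#'
#' FDR = 2 * nd / nt, where nd is the number of decoy matches among the
#' accepted set and nt the total number of accepted matches; the factor 2
#' assumes false matches hit target and decoy sequences equally often. Returns
#' 0 for an empty set.
#'
#' @param accepted Data.frame with a logical (or 0/1) `is_decoy` column.
#' @return FDR estimate as a fraction.
#' @examples
#' estimate_fdr(data.frame(is_decoy = c(rep(FALSE, 995), rep(TRUE, 5))))
#' @export
estimate_fdr <- function(accepted) {
  nt <- nrow(accepted)
  if (is.null(nt) || nt == 0L) return(0)
  nd <- sum(as.logical(accepted$is_decoy))
  2 * nd / nt
}

#' Partition PSMs by trypticity and precursor charge
#'
#' PSMs are grouped by the combination of trypticity (full, partial) and
#' precursor charge (2+, 3+, 4+), giving up to six groups that are filtered
#' independently; score distributions differ systematically across these axes.
#' PSMs with a charge outside 2-4 are routed to a `rejected` bin.
#'
#' @param psm Data.frame of PSMs.
#' @return List with `groups` (named list of data.frames, names like
#'   `"full/2"`) and `rejected`.
#' @export
group_psms <- function(psm) {
  ok <- psm$charge %in% 2:4 & psm$trypticity %in% c("full", "partial")
  rejected <- psm[!ok, , drop = FALSE]
  kept <- psm[ok, , drop = FALSE]
  key <- paste(kept$trypticity, kept$charge, sep = "/")
  lev <- paste(rep(c("full", "partial"), each = 3L), 2:4, sep = "/")
  groups <- split(kept, factor(key, levels = lev))
  groups <- groups[vapply(groups, nrow, 1L) > 0L]
  list(groups = groups, rejected = rejected)
}

# Protein-level 2*nd/nt after family grouping of an accepted PSM set.
protein_level_fdr <- function(accepted) {
  fam <- group_protein_families(accepted)
  if (nrow(fam) == 0L) return(list(fdr = 0, nd = 0L, nt = 0L))
  nd <- sum(fam$is_decoy)
  list(fdr = 2 * nd / nrow(fam), nd = nd, nt = nrow(fam))
}

# Fast protein-level 2*nd/nt over an acceptance mask: union-find connected
# components of the peptide-protein graph restricted to accepted rows.
# pep_id: integer peptide node per row; prots: list of integer protein ids
# per row; prot_decoy: logical per protein.
protein_fdr_mask <- function(pep_id, prots, prot_decoy, accept) {
  rows <- which(accept)
  if (length(rows) == 0L) return(list(fdr = 0, nd = 0L, nt = 0L))
  n_pep <- max(pep_id)
  parent <- seq_len(n_pep + length(prot_decoy))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in rows) {
    a <- find(pep_id[r])
    for (p in prots[[r]]) {
      b <- find(n_pep + p)
      if (a != b) parent[b] <- a
    }
  }
  present <- unique(unlist(prots[rows]))
  roots <- vapply(n_pep + present, find, 1L)
  all_decoy <- tapply(prot_decoy[present], roots, all)
  nt <- length(all_decoy)
  nd <- sum(all_decoy)
  list(fdr = 2 * nd / nt, nd = nd, nt = nt)
}

#' Grouped dynamic threshold filtering of PSMs
#'
#' Reproduces the grouped target-decoy filtering strategy: PSMs are split by
#' trypticity and charge, gated at a precursor mass accuracy limit, and then
#' per-group minimum Xcorr and deltaCn thresholds are raised from their floors
#' (Xcorr 1.0 in steps of 0.1, deltaCn 0.05 in steps of 0.01) until the
#' protein-level FDR (2 * decoy protein groups / all protein groups, after
#' family grouping) is at or below `target_fdr`. Each greedy step tightens the
#' one group/axis whose increment removes the most decoy PSMs per target PSM
#' lost; ties resolve toward the lower Xcorr threshold, then the lower deltaCn
#' threshold, then the canonical group order. The search therefore keeps as
#' many target PSMs as it can while meeting the constraint, and is fully
#' deterministic.
#'
#' @param psm Data.frame of PSMs (see [read_psm_table()] for columns).
#' @param target_fdr Protein-level FDR constraint (default 0.01).
#' @param ppm_limit Precursor mass-error gate in ppm (default 15).
#' @param xcorr_floor,xcorr_step,dcn_floor,dcn_step Threshold grid.
#' @return An object of class `filter_result`: accepted PSMs, per-group
#'   thresholds, PSM- and protein-level nd/nt and FDR estimates, protein
#'   groups, and a diagnostic message when the constraint is infeasible.
#' @export
dynamic_filter <- function(psm, target_fdr = 0.01, ppm_limit = 15,
                           xcorr_floor = 1.0, xcorr_step = 0.1,
                           dcn_floor = 0.05, dcn_step = 0.01) {
  if (!"ppm_error" %in% names(psm)) {
    psm$ppm_error <- (psm$observed_mh - psm$theoretical_mh) /
      psm$theoretical_mh * 1e6
  }
  psm$is_decoy <- as.logical(psm$is_decoy)
  grouped <- group_psms(psm[abs(psm$ppm_error) <= ppm_limit, , drop = FALSE])
  groups <- grouped$groups
  gnames <- names(groups)
  kept <- do.call(rbind, groups)
  if (is.null(kept)) kept <- psm[0L, , drop = FALSE]
  rownames(kept) <- NULL
  gidx <- rep(seq_along(gnames), vapply(groups, nrow, 1L))

  # integer peptide/protein encodings for the fast protein-FDR path
  mods_col <- if ("mods" %in% names(kept)) kept$mods else ""
  pep_id <- as.integer(factor(paste0(kept$peptide, "|", mods_col)))
  prot_lists <- strsplit(kept$protein_ids, ";", fixed = TRUE)
  prot_levels <- unique(unlist(prot_lists))
  prots <- lapply(prot_lists, function(p) match(p, prot_levels))
  prot_decoy <- startsWith(prot_levels, "REV_")

  thr <- data.frame(group = gnames, xcorr = xcorr_floor, delta_cn = dcn_floor,
                    stringsAsFactors = FALSE)
  accept_mask <- function(th) {
    kept$xcorr >= th$xcorr[gidx] & kept$delta_cn >= th$delta_cn[gidx]
  }
  acc_mask <- accept_mask(thr)
  state <- protein_fdr_mask(pep_id, prots, prot_decoy, acc_mask)
  diagnostic <- NULL
  while (state$fdr > target_fdr) {
    # candidate single-step tightenings, canonical order
    best <- NULL
    for (i in seq_along(gnames)) {
      in_g <- gidx == i
      cur <- acc_mask & in_g
      n_cur <- sum(cur)
      if (n_cur == 0L) next
      for (axis in c("xcorr", "delta_cn")) {
        xc <- thr$xcorr[i] + if (axis == "xcorr") xcorr_step else 0
        dc <- thr$delta_cn[i] + if (axis == "delta_cn") dcn_step else 0
        nxt <- in_g & kept$xcorr >= xc & kept$delta_cn >= dc
        lost <- n_cur - sum(nxt)
        decoy_lost <- sum(kept$is_decoy[cur]) - sum(kept$is_decoy[nxt])
        target_lost <- lost - decoy_lost
        # prefer moves removing the most decoys per target lost; a move that
        # loses nothing still advances the grid across empty score gaps
        cand <- list(i = i, axis = axis,
                     score = decoy_lost / (target_lost + 1),
                     target_lost = target_lost)
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score && cand$target_lost < best$target_lost)) {
          best <- cand
        }
      }
    }
    if (is.null(best)) {
      # every group exhausted without meeting the target
      diagnostic <- sprintf(
        "infeasible: protein FDR %.4f above target %.4f at maximal thresholds",
        state$fdr, target_fdr)
      acc_mask <- rep(FALSE, nrow(kept))
      state <- list(fdr = 0, nd = 0L, nt = 0L)
      break
    }
    if (best$axis == "xcorr") {
      thr$xcorr[best$i] <- thr$xcorr[best$i] + xcorr_step
    } else {
      thr$delta_cn[best$i] <- thr$delta_cn[best$i] + dcn_step
    }
    acc_mask <- accept_mask(thr)
    state <- protein_fdr_mask(pep_id, prots, prot_decoy, acc_mask)
  }

  acc <- kept[acc_mask, , drop = FALSE]
  rownames(acc) <- NULL
  fam <- group_protein_families(acc)
  structure(list(
    thresholds = cbind(thr, ppm_limit = ppm_limit),
    accepted = acc,
    nd = if (nrow(acc)) sum(acc$is_decoy) else 0L,
    nt = nrow(acc),
    fdr_estimate = estimate_fdr(acc),
    protein_groups = fam,
    nd_protein = state$nd, nt_protein = state$nt,
    fdr_protein = state$fdr,
    rejected = grouped$rejected,
    target_fdr = target_fdr,
    diagnostic = diagnostic
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result: %d accepted PSMs (%d decoy), PSM FDR %.4f\n",
              x$nt, x$nd, x$fdr_estimate))
  cat(sprintf("  protein groups: %d (%d decoy), protein FDR %.4f (target %.3f)\n",
              x$nt_protein, x$nd_protein, x$fdr_protein, x$target_fdr))
  if (!is.null(x$diagnostic)) cat("  ", x$diagnostic, "\n")
  invisible(x)
}

#' Cluster proteins sharing accepted peptides into families
#'
#' Proteins matched by a common accepted peptide are merged into a single
#' group, with merging applied transitively (connected components of the
#' peptide-protein graph). A group is a decoy group only when every member is
#' a decoy. Proteins supported by a single distinct peptide are flagged for
#' manual inspection.
#'
#' @param accepted Data.frame of accepted PSMs with `peptide`, `mods` and
#'   `protein_ids` (semicolon list) columns.
#' @param decoy_prefix Prefix identifying decoy accessions.
#' @return Data.frame with one row per protein group: `group_id`, `proteins`
#'   (semicolon list, sorted), `n_proteins`, `n_peptides`, `is_decoy`,
#'   `single_peptide` flag.
#' @export
group_protein_families <- function(accepted, decoy_prefix = "REV_") {
  if (is.null(accepted) || nrow(accepted) == 0L) {
    return(data.frame(group_id = integer(0), proteins = character(0),
                      n_proteins = integer(0), n_peptides = integer(0),
                      is_decoy = logical(0), single_peptide = logical(0),
                      stringsAsFactors = FALSE))
  }
  mods <- if ("mods" %in% names(accepted)) accepted$mods else ""
  pep_key <- paste0("pep::", accepted$peptide, "|", mods)
  edges <- do.call(rbind, lapply(seq_len(nrow(accepted)), function(i) {
    prots <- strsplit(accepted$protein_ids[i], ";", fixed = TRUE)[[1L]]
    prots <- prots[nzchar(prots)]
    if (length(prots) == 0L) return(NULL)
    data.frame(from = pep_key[i], to = paste0("prot::", prots),
               stringsAsFactors = FALSE)
  }))
  g <- igraph::graph_from_data_frame(unique(edges), directed = FALSE)
  comp <- igraph::components(g)
  vn <- igraph::V(g)$name
  rows <- lapply(seq_len(comp$no), function(k) {
    members <- vn[comp$membership == k]
    prots <- sort(sub("^prot::", "", members[startsWith(members, "prot::")]))
    peps <- members[startsWith(members, "pep::")]
    data.frame(
      proteins = paste(prots, collapse = ";"),
      n_proteins = length(prots),
      n_peptides = length(peps),
      is_decoy = all(startsWith(prots, decoy_prefix)),
      single_peptide = length(peps) == 1L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$proteins), , drop = FALSE]
  out <- cbind(group_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
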