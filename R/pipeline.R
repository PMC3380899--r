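#' Pipeline configuration
#'
#' Collects every stage parameter and file path for [run_pipeline()]. All
#' rounding happens at report time; intermediate computation keeps full
#' precision. The configuration round-trips through [jsonlite] unchanged.
#'
#' @param out_dir Directory for all outputs (created if needed).
#' @param seed Seed for the simulate stage (and recorded in the log).
#' @param stages Which stages to run, a subset of
#'   `c("simulate", "filter", "quantify", "ptm", "targeted", "report")`.
#' @param psm,features,targeted,traces Input file paths; defaults point at
#'   the simulate stage's outputs under `out_dir`.
#' @param target_fdr,ppm_limit Filtering parameters (see [dynamic_filter()]).
#' @param cutoff_multiplier Significance cutoff multiplier (default 1.64).
#' @param ci_mode Confidence-interval mode for the targeted stage (see
#'   [normalize_and_summarize()]).
#' @param sim A [simulation_config()]; defaults to `simulation_config(seed)`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "filter", "quantify",
                                       "ptm", "targeted", "report"),
                            psm = file.path(out_dir, "psm.tsv"),
                            features = file.path(out_dir, "features.tsv"),
                            targeted = file.path(out_dir, "targeted.tsv"),
                            traces = file.path(out_dir, "traces.tsv"),
                            target_fdr = 0.01, ppm_limit = 15,
                            cutoff_multiplier = 1.64,
                            ci_mode = "t_refs_reps",
                            sim = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(sim)) sim <- simulation_config(seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the aggregome analysis pipeline
#'
#' Executes the toggled stages in order: simulate (synthetic inputs with a
#' truth manifest), filter (grouped target-decoy PSM filtering), quantify
#' (protein rollup, recentering, cutoffs, classification, triple-map
#' coordinates), ptm (modification stoichiometry table), targeted (AGC-
#' corrected reference-normalized targeted quantification) and report (run
#' log with seed, parameters, recentering means and cutoffs). Identical
#' configuration and inputs yield identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of all written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(files = character(0))
  out <- function(f) file.path(config$out_dir, f)
  emit <- function(d, f) {
    utils::write.table(d, out(f), sep = "\t", quote = FALSE, row.names = FALSE)
    res$files <<- c(res$files, out(f))
  }
  log_lines <- c(sprintf("aggregome pipeline, seed %d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = ", ")),
                 sprintf("target_fdr %.4g, ppm_limit %.4g, cutoff_multiplier %.4g",
                         config$target_fdr, config$ppm_limit,
                         config$cutoff_multiplier))

  if ("simulate" %in% config$stages) {
    proteome <- generate_proteome(config$sim, out("proteome.fasta"))
    res$truth <- simulate_experiment(config$sim, proteome, config$out_dir)
    res$files <- c(res$files, out("proteome.fasta"),
                   file.path(config$out_dir,
                             c("psm.tsv", "features.tsv", "targeted.tsv",
                               "traces.tsv", "truth.json")))
  }

  if ("filter" %in% config$stages) {
    if (!file.exists(config$psm)) stop("PSM input missing: ", config$psm)
    psm <- read_psm_table(config$psm)
    fr <- dynamic_filter(psm, target_fdr = config$target_fdr,
                         ppm_limit = config$ppm_limit)
    res$filter <- fr
    emit(fr$accepted, "accepted_psms.tsv")
    thr <- utils::capture.output({
      print(fr$thresholds); cat(sprintf(
        "PSM nd %d nt %d FDR %.5f | protein nd %d nt %d FDR %.5f (target %.3g)\n",
        fr$nd, fr$nt, fr$fdr_estimate, fr$nd_protein, fr$nt_protein,
        fr$fdr_protein, fr$target_fdr))
      if (!is.null(fr$diagnostic)) cat(fr$diagnostic, "\n")
    })
    writeLines(thr, out("thresholds.txt"))
    res$files <- c(res$files, out("thresholds.txt"))
  }

  if (any(c("quantify", "ptm") %in% config$stages)) {
    if (!file.exists(config$features)) {
      stop("feature input missing: ", config$features)
    }
    features <- read_feature_table(config$features)
    quant <- quantify_proteins(features)
    raw_d43 <- quant$d43; raw_dS6 <- quant$dS6  # kept for the PTM stage
    r43 <- recenter(quant$d43); rS6 <- recenter(quant$dS6)
    rdd <- recenter(quant$dS6_43)
    quant$d43 <- as.numeric(r43); quant$dS6 <- as.numeric(rS6)
    quant$dS6_43 <- as.numeric(rdd)
    cuts <- significance_cutoffs(quant, multiplier = config$cutoff_multiplier)
    quant <- classify_proteins(quant, cuts)
    res$quant <- quant; res$cutoffs <- cuts
    res$recentering_means <- c(d43 = attr(r43, "mean_subtracted"),
                               dS6 = attr(rS6, "mean_subtracted"),
                               dS6_43 = attr(rdd, "mean_subtracted"))
    if ("quantify" %in% config$stages) {
      tab <- quant
      tab$fold_43 <- fold_change(tab$d43)
      tab$fold_s6 <- fold_change(tab$dS6)
      emit(format_numeric(tab, 4L), "protein_table.tsv")
      emit(format_numeric(triple_map(quant), 4L), "map_coordinates.tsv")
      log_lines <- c(log_lines,
                     sprintf("recentering means: d43 %+0.5f dS6 %+0.5f dS6_43 %+0.5f",
                             res$recentering_means[1], res$recentering_means[2],
                             res$recentering_means[3]),
                     sprintf("cutoffs (%0.2f*SD): d43 %.4f dS6 %.4f dS6_43 %.4f",
                             config$cutoff_multiplier, cuts[1], cuts[2], cuts[3]))
    }
    if ("ptm" %in% config$stages) {
      if (is.null(res$filter)) {
        if (!file.exists(config$psm)) stop("PSM input missing for ptm stage")
        res$filter <- dynamic_filter(read_psm_table(config$psm),
                                     target_fdr = config$target_fdr,
                                     ppm_limit = config$ppm_limit)
      }
      ptm_tab <- build_ptm_table(res$filter$accepted, features,
                                 raw_d43, raw_dS6, quant$protein_group)
      res$ptm <- ptm_tab
      emit(format_numeric(ptm_tab, 4L), "ptm_table.tsv")
    }
  }

  if ("targeted" %in% config$stages) {
    if (!file.exists(config$targeted) || !file.exists(config$traces)) {
      stop("targeted inputs missing")
    }
    res$targeted <- run_targeted_stage(config$targeted, config$traces,
                                       ci = config$ci_mode)
    emit(format_numeric(as.data.frame(res$targeted), 4L), "targeted_summary.tsv")
  }

  if ("report" %in% config$stages) {
    log_lines <- c(log_lines,
                   sprintf("R %s, aggregome %s", getRversion(),
                           as.character(utils::packageVersion("aggregome"))))
    writeLines(log_lines, out("pipeline_log.txt"))
    res$files <- c(res$files, out("pipeline_log.txt"))
  }
  invisible(res)
}

# round numeric columns for stable on-disk presentation
format_numeric <- function(d, digits) {
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]])) d[[j]] <- round(d[[j]], digits)
  }
  d
}

# methylation-table-style stoichiometry summary from accepted PSMs + features
build_ptm_table <- function(accepted, features, raw_d43, raw_dS6, proteins) {
  cand <- detect_ptm_candidates(accepted)
  if (nrow(cand) == 0L) {
    return(data.frame(protein = character(0), site = character(0)))
  }
  unmod_pct <- rbind(
    data.frame(protein = proteins, condition = "tdp43",
               percent_of_mock = 100 * 2^raw_d43, stringsAsFactors = FALSE),
    data.frame(protein = proteins, condition = "tdps6",
               percent_of_mock = 100 * 2^raw_dS6, stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    fx <- features[features$peptide == cand$peptide[i] &
                     features$mods == cand$mods_string[i] &
                     features$protein_group == cand$protein[i], , drop = FALSE]
    if (nrow(fx) == 0L) return(NULL)
    cond_int <- function(cn, ch) {
      v <- fx[[ch]][fx$condition == cn]
      if (length(v) == 0L) NA_real_ else mean(v)
    }
    data.frame(protein = cand$protein[i], site = cand$site[i],
               peptide = cand$peptide[i], mods = cand$mods_string[i],
               light_mock = cond_int("mock", "light_intensity"),
               heavy_mock = cond_int("mock", "heavy_intensity"),
               light_tdp43 = cond_int("tdp43", "light_intensity"),
               heavy_tdp43 = cond_int("tdp43", "heavy_intensity"),
               light_tdps6 = cond_int("tdps6", "light_intensity"),
               heavy_tdps6 = cond_int("tdps6", "heavy_intensity"),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, rows)
  if (is.null(sites)) return(data.frame(protein = character(0)))
  stoichiometry_table(sites, unmod_pct, conditions = c("tdp43", "tdps6"))
}

# targeted stage: MS2 scans summed+AGC-corrected, XIC peptides from traces,
# references normalized out, log2 summaries with 95% CI
run_targeted_stage <- function(targeted_path, traces_path, ci = "t_refs_reps",
                               control = "control", tolerance = 0.5) {
  method <- targeted_method_peptides()
  scans <- read_targeted_scans(targeted_path)
  traces <- read_xic_traces(traces_path)
  ints <- list()
  for (i in seq_len(nrow(scans))) {
    row <- method[method$id == scans$peptide_id[i], ]
    if (nrow(row) != 1L || row$quant_mode != "ms2") next
    frg <- strsplit(row$fragments, ";", fixed = TRUE)[[1L]]  # "label:mz" pairs
    req <- as.numeric(vapply(strsplit(frg, ":", fixed = TRUE), `[`, "", 2L))
    s <- sum_required_fragments(scans$peaks[[i]], req, tolerance)
    ints[[length(ints) + 1L]] <- data.frame(
      peptide_id = scans$peptide_id[i], sample = scans$sample[i],
      replicate = scans$replicate[i],
      intensity = if (is.na(s)) NA_real_ else
        agc_correct(s, scans$inject_time_ms[i]),
      stringsAsFactors = FALSE)
  }
  key <- unique(traces[, c("sample", "replicate", "peptide_id")])
  for (i in seq_len(nrow(key))) {
    tr <- traces[traces$sample == key$sample[i] &
                   traces$replicate == key$replicate[i] &
                   traces$peptide_id == key$peptide_id[i], , drop = FALSE]
    ints[[length(ints) + 1L]] <- data.frame(
      peptide_id = key$peptide_id[i], sample = key$sample[i],
      replicate = key$replicate[i],
      intensity = as.numeric(xic_quantify(tr)), stringsAsFactors = FALSE)
  }
  all_int <- do.call(rbind, ints)
  ref_ids <- method$id[method$role == "reference"]
  refs <- all_int[all_int$peptide_id %in% ref_ids, , drop = FALSE]
  targets <- all_int[!all_int$peptide_id %in% ref_ids, , drop = FALSE]
  normalize_and_summarize(targets, refs, control = control, ci = ci)
}

#' Recompute and check every derivable printed value in the bundled tables
#'
#' Recomputes the reference-peptide [M+H]+ masses (dialkyl/GG table and
#' methylation table) from sequence plus modification deltas, the
#' methylation table's derived columns (light/heavy ratios, unnormalized and
#' normalized percent-of-control) from its printed XIC intensities, the
#' significant-protein table's difference arithmetic (S6-43 = S6-mock minus
#' 43-mock) and headline fold changes, and the targeted-method isolation
#' centers, and reports a per-cell pass/fail table.
#'
#' Mass cells pass at two units in the last printed digit (2e-4 Da): the
#' printed tables were rounded from a slightly different residue-mass table
#' and a small systematic offset remains. Cells derived from printed XIC
#' intensities carry the roundings of their inputs (each printed to 3
#' significant figures), so they pass at the larger of one unit in the last
#' printed digit and a propagated relative tolerance (1.2% for ratios of two
#' rounded inputs, 2.2% for percent-of-control, 3.2% for normalized percent,
#' which additionally divides by a rounded intermediate).
#'
#' @param perturb Internal testing hook: a list `(table, row, column, value)`
#'   overwriting one fixture cell before validation.
#' @return Data.frame `table`, `row`, `cell`, `computed`, `printed`, `pass`.
#' @export
validate_fixtures <- function(perturb = NULL) {
  t1 <- significant_protein_table(); t4 <- methylation_site_table(); t5 <- gg_reference_table()
  tm <- targeted_method_peptides()
  if (!is.null(perturb)) {
    tab <- switch(perturb$table, significant = "t1", methylation = "t4",
                  gg_reference = "t5", targeted = "tm")
    tmp <- get(tab); tmp[perturb$row, perturb$column] <- perturb$value
    assign(tab, tmp)
  }
  rows <- list()
  add <- function(table, row, cell, computed, printed, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      table = table, row = row, cell = cell, computed = computed,
      printed = printed, pass = is.finite(computed) &&
        abs(computed - printed) <= tol, stringsAsFactors = FALSE)
  }
  ulp <- function(x) 10^(ceiling(log10(abs(x))) - 3L)  # 3 significant digits

  for (i in seq_len(nrow(t5))) {
    mh <- peptide_mass(parse_peptide_notation(t5$notation[i]))$mh
    add("gg_reference", t5$site[i], "mh", mh, t5$mh_printed[i], 2.05e-4)
  }
  for (i in seq_len(nrow(t4))) {
    pep <- parse_peptide_notation(t4$notation[i])
    add("methylation", t4$site[i], "expected_mh", peptide_mass(pep)$mh,
        t4$expected_mh[i], 2.05e-4)
    rm <- modified_peptide_ratio(t4$light_mock[i], t4$heavy_mock[i])
    add("methylation", t4$site[i], "ratio_mock", rm, t4$ratio_mock[i],
        max(1.05 * ulp(t4$ratio_mock[i]), 0.012 * t4$ratio_mock[i]))
    for (cn in c("wt", "s6")) {
      pr <- t4[[paste0("ratio_", cn)]][i]
      rc <- modified_peptide_ratio(t4[[paste0("light_", cn)]][i],
                                   t4[[paste0("heavy_", cn)]][i])
      add("methylation", t4$site[i], paste0("ratio_", cn), rc, pr,
          max(1.05 * ulp(pr), 0.012 * pr))
      pu <- t4[[paste0("unnorm_", cn)]][i]
      un <- 100 * rc / rm
      add("methylation", t4$site[i], paste0("unnorm_", cn), un, pu,
          max(1.05 * ulp(pu), 0.022 * pu))
      pn <- t4[[paste0("norm_", cn)]][i]
      nm <- 100 * un / t4[[paste0("unmod_", cn)]][i]
      add("methylation", t4$site[i], paste0("norm_", cn), nm, pn,
          max(2.05 * ulp(pn), 0.032 * pn))
    }
  }
  for (i in seq_len(nrow(t1))) {
    add("significant", t1$gene[i], "dS6_43", t1$dS6[i] - t1$d43[i], t1$dS6_43[i],
        0.015)
  }
  tardbp <- t1[t1$gene == "TARDBP", ]
  add("significant", "TARDBP", "fold_43", fold_change(tardbp$d43), 11, 0.5)
  add("significant", "TARDBP", "fold_s6", fold_change(tardbp$dS6), 80, 0.5)
  centers <- sort(vapply(tm$peptide, function(p)
    plan_inclusion_list(list(p), charge = 2L)$center, numeric(1)))
  printed <- sort(tm$printed_center)
  for (i in seq_along(centers)) {
    add("targeted", paste0("center", i), "center", centers[i], printed[i], 0.03)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
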