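#' Configuration for the synthetic aggregome experiment
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the structure of the triple-transfection SILAC study: 585 proteins
#' quantified in all three conditions (mock, TDP-43, TDP-S6) in two
#' replicates against a heavy internal standard; 35 up- and 6 down-spiked
#' changers on a correlated Gaussian null whose per-comparison standard
#' deviations (0.55 / 0.54 / 0.40 log2 units for 43-mock, S6-mock, S6-43) put
#' the 1.64*SD cutoffs near +/-0.9 / 0.9 / 0.65; decoy and false-target PSMs
#' with separated score distributions; condition-dependent modification
#' stoichiometries; and targeted MS/MS scans whose inject times follow the
#' AGC law (inject = min(150 ms, AGC target / ion flux)).
#'
#' @param seed Integer seed; all generation is deterministic per seed
#'   (mandatory -- there is no unseeded mode).
#' @param n_proteins,n_spiked_up,n_spiked_down Population structure.
#' @param null_sd Named numeric: SDs of the true null log2 differences for
#'   `d43`, `dS6`, `dS6_43` (the third fixes the correlation).
#' @param mock_sd SD of the mock log2(light/heavy) population itself.
#' @param spike_mean,spike_sd,spike_min Spiked |log2 effect| distribution
#'   (normal, truncated below at `spike_min`).
#' @param peptides_min,peptides_lambda Peptides per protein:
#'   `peptides_min + rpois(peptides_lambda)`.
#' @param peptide_noise_sd Peptide-level log2 measurement noise.
#' @param base_intensity,intensity_log_sd Heavy-channel signal-to-noise scale
#'   (log-normal).
#' @param replicates Number of replicates per condition.
#' @param protein_length_mean,protein_length_sd Simulated protein lengths.
#' @param decoy_rate,false_target_rate Decoy PSMs and false target PSMs as a
#'   fraction of target PSM count.
#' @param target_xcorr,decoy_xcorr,target_dcn,decoy_dcn `c(mean, sd)` score
#'   distributions for correct vs incorrect matches.
#' @param target_ppm_sd Precursor error SD (ppm) for correct matches;
#'   incorrect matches draw uniformly from +/-40 ppm.
#' @param ptm_sites Data.frame of simulated modification sites:
#'   `protein_index`, `mod`, `stoich_mock`, `stoich_tdp43`, `stoich_tdps6`,
#'   `stoich_heavy`.
#' @param targeted_log2 Named list per experimental sample of named log2
#'   fold-changes versus control for the six targeted-method peptides.
#' @param targeted_noise_sd Log2 noise on targeted quantities.
#' @param agc_target,base_flux AGC ion target and per-peptide base ion flux
#'   (ions/ms): inject time = min(150, agc_target / flux).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_proteins = 585L,
                              n_spiked_up = 35L,
                              n_spiked_down = 6L,
                              null_sd = c(d43 = 0.55, dS6 = 0.54, dS6_43 = 0.40),
                              mock_sd = 0.30,
                              spike_mean = 1.5, spike_sd = 0.3, spike_min = 1.0,
                              peptides_min = 2L, peptides_lambda = 4,
                              peptide_noise_sd = 0.25,
                              base_intensity = 100, intensity_log_sd = 1.0,
                              replicates = 2L,
                              protein_length_mean = 360, protein_length_sd = 90,
                              decoy_rate = 0.05, false_target_rate = 0.01,
                              target_xcorr = c(3.0, 0.7),
                              decoy_xcorr = c(1.4, 0.35),
                              target_dcn = c(0.30, 0.10),
                              decoy_dcn = c(0.06, 0.04),
                              target_ppm_sd = 3,
                              ptm_sites = default_ptm_sites(),
                              targeted_log2 = default_targeted_log2(),
                              targeted_noise_sd = 0.05,
                              agc_target = 5000, base_flux = 50) {
  if (missing(seed)) stop("a seed is mandatory; there is no unseeded mode")
  stopifnot(n_proteins > 0L, all(null_sd > 0),
            n_spiked_up + n_spiked_down < n_proteins)
  # the three SDs must admit a correlation: var(dS6_43) = v43 + vS6 - 2*cov
  cv <- (null_sd[["d43"]]^2 + null_sd[["dS6"]]^2 - null_sd[["dS6_43"]]^2) / 2
  rho <- cv / (null_sd[["d43"]] * null_sd[["dS6"]])
  if (abs(rho) >= 1) stop("null_sd triple implies |correlation| >= 1")
  structure(as.list(environment()), class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_ptm_sites <- function() {
  data.frame(
    protein_index = c(1L, 2L, 3L),
    mod = c("gg", "dimethyl", "dimethyl"),
    stoich_mock = c(0.05, 0.05, 0.08),
    stoich_tdp43 = c(0.05, 0.10, 0.08),
    stoich_tdps6 = c(0.15, 0.05, 0.16),
    stoich_heavy = c(0.05, 0.05, 0.08),
    stringsAsFactors = FALSE)
}

#' @rdname simulation_config
#' @export
default_targeted_log2 <- function() {
  list(
    arsenite = c(a = 2.3, b = 2.3, c = 0.70, d = 1.0, e = 0, f = 0),
    s6 = c(a = 2.72, b = 2.3, c = 5.91, d = 1.0, e = 0, f = 0))
}

# human-like residue frequencies for random proteins
aa_frequencies <- function() {
  f <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, E = 7.1, Q = 4.8,
         G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.8, M = 2.1, F = 3.7,
         P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0)
  f / sum(f)
}

#' Generate a random proteome FASTA
#'
#' Random protein sequences with human-like residue frequencies; each
#' sequence is redrawn until it yields at least three fully tryptic peptides
#' of length >= 6, so every protein is quantifiable. Deterministic per seed.
#'
#' @param config A [simulation_config()].
#' @param fasta_out Optional output path.
#' @return Invisibly, a `Biostrings::AAStringSet` named `SIM0001`...
#' @export
generate_proteome <- function(config, fasta_out = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  freq <- aa_frequencies()
  lens <- pmax(80L, pmin(1200L, round(stats::rnorm(
    config$n_proteins, config$protein_length_mean, config$protein_length_sd))))
  seqs <- character(config$n_proteins)
  enough_peptides <- function(chars) {
    cut <- which(chars %in% c("K", "R") & c(chars[-1L], "") != "P")
    cut <- cut[cut < length(chars)]
    sum(diff(c(0L, cut, length(chars))) >= 6L) >= 3L
  }
  for (i in seq_len(config$n_proteins)) {
    repeat {
      chars <- sample(names(freq), lens[i], replace = TRUE, prob = freq)
      if (enough_peptides(chars)) break
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  db <- Biostrings::AAStringSet(seqs)
  names(db) <- sprintf("SIM%04d", seq_len(config$n_proteins))
  if (!is.null(fasta_out)) Biostrings::writeXStringSet(db, fasta_out, width = 60L)
  invisible(db)
}

rnorm_trunc <- function(n, mean, sd, lower) pmax(lower, stats::rnorm(n, mean, sd))

# correlated null (d43, dS6) draws honoring the three configured SDs
draw_null_differences <- function(n, null_sd) {
  v43 <- null_sd[["d43"]]^2
  vS6 <- null_sd[["dS6"]]^2
  cv <- (v43 + vS6 - null_sd[["dS6_43"]]^2) / 2
  a <- cv / v43
  sd_res <- sqrt(vS6 - a^2 * v43)
  d43 <- stats::rnorm(n, 0, sqrt(v43))
  dS6 <- a * d43 + stats::rnorm(n, 0, sd_res)
  data.frame(d43 = d43, dS6 = dS6)
}

#' Simulate a full aggregome experiment with known ground truth
#'
#' Writes the five pipeline input files to `out_dir`: `psm.tsv` (target,
#' decoy and planted false-target PSMs), `features.tsv` (light/heavy SILAC
#' features per peptide, condition and replicate, including modified
#' peptides), `targeted.tsv` (targeted MS/MS scans with AGC-governed inject
#' times), `traces.tsv` (precursor XIC traces for the XIC-quantified and
#' reference peptides) and `truth.json` (every spiked protein and effect,
#' modification stoichiometry, targeted fold change and false-PSM label).
#'
#' @param config A [simulation_config()].
#' @param proteome `AAStringSet` from [generate_proteome()] (or a FASTA path).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the truth list.
#' @export
simulate_experiment <- function(config, proteome, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.character(proteome)) proteome <- Biostrings::readAAStringSet(proteome)
  if (max(config$ptm_sites$protein_index) > length(proteome)) {
    stop("ptm_sites references a protein index beyond the proteome")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  n <- length(proteome)
  ids <- names(proteome)
  conditions <- c("mock", "tdp43", "tdps6")

  ## --- true per-protein differences -------------------------------------
  truth_d <- draw_null_differences(n, config$null_sd)
  n_spiked <- config$n_spiked_up + config$n_spiked_down
  spiked_idx <- sample(n, n_spiked)
  spike_sign <- rep(c(1, -1), c(config$n_spiked_up, config$n_spiked_down))
  spike_pattern <- sample(c("both", "43", "s6"), n_spiked, replace = TRUE,
                          prob = c(0.4, 0.3, 0.3))
  spike_mag <- rnorm_trunc(n_spiked, config$spike_mean, config$spike_sd,
                           config$spike_min)
  for (j in seq_len(n_spiked)) {
    i <- spiked_idx[j]; eff <- spike_sign[j] * spike_mag[j]
    if (spike_pattern[j] %in% c("both", "43")) truth_d$d43[i] <- eff
    if (spike_pattern[j] %in% c("both", "s6")) {
      truth_d$dS6[i] <- eff + if (spike_pattern[j] == "both")
        stats::rnorm(1, 0, 0.2) else 0
    }
  }
  mock_base <- stats::rnorm(n, 0, config$mock_sd)
  cond_value <- cbind(mock = mock_base,
                      tdp43 = mock_base + truth_d$d43,
                      tdps6 = mock_base + truth_d$dS6)

  ## --- peptides ----------------------------------------------------------
  rules <- digest_rules(0L, "full", min_length = 6L)
  pep_per_prot <- config$peptides_min +
    stats::rpois(n, config$peptides_lambda)
  pep_list <- vector("list", n)
  for (i in seq_len(n)) {
    peps <- digest(as.character(proteome[[i]]), rules, protein_id = ids[i])
    peps <- peps[vapply(peps, function(p) nchar(p$sequence) <= 30L, TRUE)]
    k <- min(length(peps), pep_per_prot[i])
    pep_list[[i]] <- peps[sample(length(peps), k)]
  }

  ## --- SILAC features ----------------------------------------------------
  gel <- c("low", "mid", "high")
  pep_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(pep_list[[i]]) == 0L) return(NULL)
    data.frame(idx = i,
               peptide = vapply(pep_list[[i]], function(p) p$sequence, ""),
               start = vapply(pep_list[[i]], function(p) p$start, 1L),
               stringsAsFactors = FALSE)
  }))
  m <- nrow(pep_df)
  reps <- config$replicates
  M <- m * 3L * reps
  row_pep <- rep(seq_len(m), each = 3L * reps)
  row_cond <- rep(rep(conditions, each = reps), times = m)
  row_rep <- rep(rep(seq_len(reps), times = 3L), times = m)
  heavy <- stats::rlnorm(M, log(config$base_intensity), config$intensity_log_sd)
  l2 <- cond_value[cbind(pep_df$idx[row_pep], match(row_cond, conditions))] +
    stats::rnorm(M, 0, config$peptide_noise_sd)
  feat <- list(data.frame(
    peptide = pep_df$peptide[row_pep], mods = "",
    protein_group = ids[pep_df$idx[row_pep]],
    condition = row_cond, replicate = row_rep,
    gel_region = gel[1L + (pep_df$start[row_pep] %% 3L)],
    light_intensity = heavy * 2^l2, heavy_intensity = heavy,
    stringsAsFactors = FALSE))

  ## --- modified-peptide features and truth -------------------------------
  ptm_truth <- list()
  ptm_psm <- list()
  for (s in seq_len(nrow(config$ptm_sites))) {
    site <- config$ptm_sites[s, ]
    i <- site$protein_index
    chars <- strsplit(as.character(proteome[[i]]), "")[[1L]]
    targets <- strsplit(mod_registry(site$mod)$targets, "")[[1L]]
    # place the modification on a cleavable K/R: blocking that site creates
    # the diagnostic missed-cleavage peptide with an internal modified residue
    cut <- which(chars %in% targets & c(chars[-1L], "") != "P")
    cut <- cut[cut >= 6L & cut < length(chars) - 6L]
    if (length(cut) == 0L) next
    site_pos <- cut[1L]
    site_mods <- data.frame(pos = site_pos, name = site$mod,
                            stringsAsFactors = FALSE)
    peps_mod <- digest(as.character(proteome[[i]]), rules, mods = site_mods,
                       protein_id = ids[i])
    hit <- vapply(peps_mod, function(p) nrow(p$mods) > 0L, TRUE)
    if (!any(hit)) next
    pp <- peps_mod[hit][[1L]]
    pos <- site_pos - pp$start + 1L
    mods_str <- paste0(pos, ":", site$mod)
    stoich <- c(mock = site$stoich_mock, tdp43 = site$stoich_tdp43,
                tdps6 = site$stoich_tdps6)
    for (cn in conditions) for (r in seq_len(config$replicates)) {
      base <- stats::rlnorm(1, log(config$base_intensity),
                            config$intensity_log_sd)
      heavy <- base * site$stoich_heavy
      light <- base * stoich[[cn]] * 2^cond_value[i, cn]
      feat[[length(feat) + 1L]] <- data.frame(
        peptide = pp$sequence, mods = mods_str, protein_group = ids[i],
        condition = cn, replicate = r, gel_region = "low",
        light_intensity = light, heavy_intensity = heavy,
        stringsAsFactors = FALSE)
    }
    ptm_psm[[length(ptm_psm) + 1L]] <- list(pep = pp, mods = mods_str)
    prot_pos <- pp$start + pos - 1L
    ptm_truth[[length(ptm_truth) + 1L]] <- list(
      protein = ids[i],
      site = paste0(chars[site_pos], prot_pos, "-", site$mod),
      peptide = pp$sequence, mods = mods_str,
      stoich = as.list(stoich),
      true_norm_pct = as.list(100 * stoich / stoich[["mock"]]))
  }
  features <- do.call(rbind, feat)

  ## --- PSMs ---------------------------------------------------------------
  flat_peps <- unlist(pep_list, recursive = FALSE)
  n_t <- length(flat_peps)
  draw_scores <- function(k, class) {
    if (class == "target") {
      data.frame(
        xcorr = rnorm_trunc(k, config$target_xcorr[1], config$target_xcorr[2], 0.3),
        delta_cn = pmin(1, rnorm_trunc(k, config$target_dcn[1],
                                       config$target_dcn[2], 0)),
        ppm = stats::rnorm(k, 0, config$target_ppm_sd))
    } else {
      data.frame(
        xcorr = rnorm_trunc(k, config$decoy_xcorr[1], config$decoy_xcorr[2], 0.3),
        delta_cn = pmin(1, rnorm_trunc(k, config$decoy_dcn[1],
                                       config$decoy_dcn[2], 0)),
        ppm = stats::runif(k, -40, 40))
    }
  }
  is_false <- stats::runif(n_t) < config$false_target_rate
  sc_true <- draw_scores(n_t, "target")
  sc_false <- draw_scores(n_t, "decoy")
  sc <- sc_true; sc[is_false, ] <- sc_false[is_false, ]
  charge <- sample(2:4, n_t, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  tryp <- sample(c("full", "partial"), n_t, replace = TRUE, prob = c(0.9, 0.1))
  theo <- vapply(flat_peps, function(p) peptide_mass(p)$mh, numeric(1))
  psm <- data.frame(
    spectrum_id = sprintf("scan%05d", seq_len(n_t)),
    peptide = vapply(flat_peps, function(p) p$sequence, ""),
    mods = "",
    charge = charge, xcorr = round(sc$xcorr, 2), delta_cn = round(sc$delta_cn, 3),
    observed_mh = theo * (1 + sc$ppm / 1e6), theoretical_mh = theo,
    trypticity = tryp, is_decoy = 0L,
    protein_ids = vapply(flat_peps, function(p) p$protein_id, ""),
    peptide_start = vapply(flat_peps, function(p) p$start, 1L),
    stringsAsFactors = FALSE)
  # decoys: reversed peptides attributed to reversed-protein accessions
  n_d <- stats::rbinom(1, n_t, config$decoy_rate)
  di <- sample(n_t, n_d)
  if (n_d > 0L) {
    dsc <- draw_scores(n_d, "decoy")
    rev_seq <- vapply(strsplit(psm$peptide[di], ""), function(x)
      paste(rev(x), collapse = ""), "")
    dtheo <- psm$theoretical_mh[di]  # reversal preserves composition
    decoys <- data.frame(
      spectrum_id = sprintf("scan%05d", n_t + seq_len(n_d)),
      peptide = rev_seq, mods = "",
      charge = sample(2:4, n_d, replace = TRUE),
      xcorr = round(dsc$xcorr, 2), delta_cn = round(dsc$delta_cn, 3),
      observed_mh = dtheo * (1 + dsc$ppm / 1e6), theoretical_mh = dtheo,
      trypticity = sample(c("full", "partial"), n_d, TRUE),
      is_decoy = 1L,
      protein_ids = paste0("REV_", psm$protein_ids[di]),
      peptide_start = 1L, stringsAsFactors = FALSE)
    psm <- rbind(psm, decoys)
  }
  # PSMs for the modified peptides: solidly high-scoring (these emulate
  # manually validated modified-peptide spectra)
  if (length(ptm_psm) > 0L) {
    msc <- data.frame(
      xcorr = rnorm_trunc(length(ptm_psm), 4.0, 0.3, 2.5),
      delta_cn = pmin(1, rnorm_trunc(length(ptm_psm), 0.45, 0.05, 0.3)))
    mp <- do.call(rbind, lapply(seq_along(ptm_psm), function(j) {
      pp <- ptm_psm[[j]]$pep
      mz <- peptide_mass(pp)$mh +
        sum(mod_delta(parse_mod_string(ptm_psm[[j]]$mods)$name))
      data.frame(
        spectrum_id = sprintf("ptmscan%03d", j),
        peptide = pp$sequence, mods = ptm_psm[[j]]$mods,
        charge = 2L, xcorr = round(msc$xcorr[j], 2),
        delta_cn = round(msc$delta_cn[j], 3),
        observed_mh = mz * (1 + stats::rnorm(1, 0, config$target_ppm_sd) / 1e6),
        theoretical_mh = mz, trypticity = "full", is_decoy = 0L,
        protein_ids = pp$protein_id, peptide_start = pp$start,
        stringsAsFactors = FALSE)
    }))
    psm <- rbind(psm, mp)
  }

  ## --- targeted scans and traces ------------------------------------------
  method <- targeted_method_peptides()
  samples <- c("control", names(config$targeted_log2))
  tech_reps <- 2L
  scans <- list(); traces <- list()
  for (smp in samples) for (r in seq_len(tech_reps)) {
    scale <- stats::rlnorm(1, 0, 0.15)  # per-run loading factor
    for (k in seq_len(nrow(method))) {
      row <- method[k, ]
      l2 <- if (smp == "control") 0 else config$targeted_log2[[smp]][[row$id]]
      flux <- config$base_flux * scale * 2^(l2 +
        stats::rnorm(1, 0, config$targeted_noise_sd))
      if (row$quant_mode == "ms2") {
        inject <- min(150, config$agc_target / flux)
        ions <- flux * inject
        frg <- strsplit(row$fragments, ";", fixed = TRUE)[[1L]]
        mzs <- as.numeric(sub("^.*:", "", frg))
        share <- rep(1 / length(mzs), length(mzs))
        ints <- ions * share * stats::rlnorm(length(mzs), 0, 0.02)
        noise_mz <- stats::runif(3, 300, 1300)
        scans[[length(scans) + 1L]] <- data.frame(
          sample = smp, replicate = r, peptide_id = row$id,
          inject_time_ms = inject,
          fragments = paste(
            c(sprintf("%.2f:%.3f", mzs, ints),
              sprintf("%.2f:%.3f", noise_mz, ions * 0.01)), collapse = ";"),
          stringsAsFactors = FALSE)
      } else {
        tt <- seq(0, 10, by = 0.5)
        apex <- flux * 150
        prof <- apex * pmax(0, 1 - abs(tt - 5) / 3)
        traces[[length(traces) + 1L]] <- data.frame(
          sample = smp, replicate = r, peptide_id = row$id,
          time = tt, intensity = prof, stringsAsFactors = FALSE)
      }
    }
  }

  ## --- write ---------------------------------------------------------------
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(psm, "psm.tsv")
  wt(features, "features.tsv")
  wt(do.call(rbind, scans), "targeted.tsv")
  wt(do.call(rbind, traces), "traces.tsv")
  truth <- list(
    seed = config$seed,
    n_proteins = n,
    null_sd = as.list(config$null_sd),
    spiked = data.frame(protein = ids[spiked_idx], pattern = spike_pattern,
                        effect = spike_sign * spike_mag,
                        d43 = truth_d$d43[spiked_idx],
                        dS6 = truth_d$dS6[spiked_idx],
                        stringsAsFactors = FALSE),
    true_d43 = truth_d$d43, true_dS6 = truth_d$dS6,
    false_psms = psm$spectrum_id[c(is_false, rep(FALSE, nrow(psm) - n_t))],
    n_decoys = n_d,
    ptm = ptm_truth,
    targeted_log2 = config$targeted_log2)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(truth)
}
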