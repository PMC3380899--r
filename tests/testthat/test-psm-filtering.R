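make_psm <- function(n, xcorr, delta_cn, ppm = 0, charge = 2L,
                     trypticity = "full", is_decoy = FALSE,
                     protein = NULL, peptide = NULL, id_offset = 0L) {
  theo <- 1500
  data.frame(
    spectrum_id = sprintf("s%04d", id_offset + seq_len(n)),
    peptide = if (is.null(peptide)) sprintf("PEPTIDEK%d", id_offset + seq_len(n))
              else rep_len(peptide, n),
    mods = "",
    charge = rep_len(charge, n), xcorr = rep_len(xcorr, n),
    delta_cn = rep_len(delta_cn, n),
    observed_mh = theo * (1 + rep_len(ppm, n) / 1e6), theoretical_mh = theo,
    trypticity = rep_len(trypticity, n),
    is_decoy = rep_len(is_decoy, n),
    protein_ids = if (is.null(protein)) sprintf("P%04d", id_offset + seq_len(n))
                  else rep_len(protein, n),
    stringsAsFactors = FALSE)
}

test_that("the target-decoy estimator is 2*nd/nt and matches a recount", {
  expect_equal(estimate_fdr(data.frame(is_decoy = c(rep(FALSE, 995),
                                                    rep(TRUE, 5)))), 0.01)
  expect_equal(estimate_fdr(data.frame(is_decoy = rep(FALSE, 50))), 0)
  expect_equal(estimate_fdr(data.frame(is_decoy = logical(0))), 0)
  set.seed(3)
  for (i in 1:10) {
    d <- data.frame(is_decoy = stats::runif(200) < stats::runif(1, 0, 0.3))
    expect_equal(estimate_fdr(d), 2 * sum(d$is_decoy) / nrow(d))
  }
})

test_that("PSMs partition exhaustively by trypticity and charge", {
  psm <- rbind(make_psm(1, 3, .3, charge = 2, trypticity = "full"),
               make_psm(1, 3, .3, charge = 3, trypticity = "full", id_offset = 1),
               make_psm(1, 3, .3, charge = 4, trypticity = "full", id_offset = 2),
               make_psm(1, 3, .3, charge = 2, trypticity = "partial", id_offset = 3),
               make_psm(1, 3, .3, charge = 3, trypticity = "partial", id_offset = 4),
               make_psm(1, 3, .3, charge = 4, trypticity = "partial", id_offset = 5))
  g <- group_psms(psm)
  expect_length(g$groups, 6L)
  expect_true(all(vapply(g$groups, nrow, 1L) == 1L))
  one <- group_psms(make_psm(10, 3, .3))
  expect_length(one$groups, 1L)
  # out-of-range charge lands in the reject bin
  bad <- make_psm(2, 3, .3, charge = 5)
  expect_equal(nrow(group_psms(bad)$rejected), 2L)
  # conservation on random data
  set.seed(9)
  psm <- make_psm(100, 3, .3)
  psm$charge <- sample(2:5, 100, replace = TRUE)
  psm$trypticity <- sample(c("full", "partial"), 100, replace = TRUE)
  g <- group_psms(psm)
  expect_equal(sum(vapply(g$groups, nrow, 1L)) + nrow(g$rejected), 100L)
})

test_that("protein families are connected components over shared peptides", {
  shared <- make_psm(1, 3, .3, protein = "A;B", peptide = "SHAREDK")
  fam <- group_protein_families(shared)
  expect_equal(nrow(fam), 1L)
  expect_equal(fam$n_proteins, 2L)
  disjoint <- rbind(make_psm(1, 3, .3, protein = "A", peptide = "ONEK"),
                    make_psm(1, 3, .3, protein = "B", peptide = "TWOK",
                             id_offset = 1))
  expect_equal(nrow(group_protein_families(disjoint)), 2L)
  # random bipartite graphs against an independent union-find
  set.seed(17)
  for (i in 1:8) {
    n <- 30
    peps <- sprintf("PEP%02dK", seq_len(n))
    prot_lists <- lapply(seq_len(n), function(j)
      sample(sprintf("P%02d", 1:12), sample(1:3, 1)))
    psm <- make_psm(n, 3, .3)
    psm$peptide <- peps
    psm$protein_ids <- vapply(prot_lists, paste, "", collapse = ";")
    fam <- group_protein_families(psm)
    got <- lapply(strsplit(fam$proteins, ";"), sort)
    want <- uf_families(peps, prot_lists)
    expect_setequal(vapply(got, paste, "", collapse = ";"),
                    vapply(want, paste, "", collapse = ";"))
  }
  # decoy status and the single-peptide inspection flag
  d <- rbind(make_psm(1, 3, .3, protein = "REV_A", peptide = "AAAK",
                      is_decoy = TRUE),
             make_psm(2, 3, .3, protein = "B", peptide = "BBBK", id_offset = 1))
  fam <- group_protein_families(d)
  expect_equal(fam$is_decoy[fam$proteins == "REV_A"], TRUE)
  expect_equal(fam$single_peptide[fam$proteins == "REV_A"], TRUE)
  expect_equal(fam$single_peptide[fam$proteins == "B"], TRUE)  # one distinct peptide
})

test_that("dynamic filtering handles degenerate inputs", {
  # all-decoy input: no thresholds can reach the target, acceptance is empty
  alld <- make_psm(50, 2, .2, is_decoy = TRUE, protein = "REV_X")
  fr <- dynamic_filter(alld)
  expect_equal(fr$nt, 0L)
  # pure targets above the floors pass through untouched
  pure <- make_psm(80, 3, .3)
  fr2 <- dynamic_filter(pure)
  expect_equal(fr2$nt, 80L)
  expect_equal(fr2$fdr_estimate, 0)
  expect_equal(fr2$thresholds$xcorr, 1.0)
  expect_equal(fr2$thresholds$delta_cn, 0.05)
})

test_that("the mass-accuracy gate drops PSMs beyond the ppm limit", {
  psm <- rbind(make_psm(5, 3, .3, ppm = 0),
               make_psm(5, 3, .3, ppm = 20, id_offset = 5))
  fr <- dynamic_filter(psm, ppm_limit = 15)
  expect_equal(fr$nt, 5L)
  expect_true(all(abs(fr$accepted$ppm_error) <= 15))
})

test_that("raising thresholds is monotone in nd and nt", {
  set.seed(31)
  psm <- rbind(make_psm(200, 0, 0), make_psm(40, 0, 0, is_decoy = TRUE,
                                             id_offset = 200))
  psm$xcorr <- c(rnorm_hi <- pmax(0.3, stats::rnorm(200, 3, .7)),
                 pmax(0.3, stats::rnorm(40, 1.4, .35)))
  psm$delta_cn <- c(pmin(1, pmax(0, stats::rnorm(200, .3, .1))),
                    pmin(1, pmax(0, stats::rnorm(40, .06, .04))))
  psm$protein_ids[psm$is_decoy] <- paste0("REV_", psm$protein_ids[psm$is_decoy])
  prev_nd <- Inf; prev_nt <- Inf
  for (floor in c(1.0, 1.5, 2.0, 2.5)) {
    fr <- dynamic_filter(psm, target_fdr = 1, xcorr_floor = floor)
    expect_lte(fr$nd, prev_nd)
    expect_lte(fr$nt, prev_nt)
    prev_nd <- fr$nd; prev_nt <- fr$nt
  }
})

test_that("identical input gives identical filter results", {
  set.seed(41)
  psm <- rbind(make_psm(100, 0, 0), make_psm(20, 0, 0, is_decoy = TRUE,
                                             id_offset = 100))
  psm$xcorr <- pmax(0.3, stats::rnorm(120, c(rep(3, 100), rep(1.4, 20)), .5))
  psm$delta_cn <- pmin(1, pmax(0, stats::rnorm(120, c(rep(.3, 100),
                                                      rep(.06, 20)), .05)))
  psm$protein_ids[psm$is_decoy] <- paste0("REV_", psm$protein_ids[psm$is_decoy])
  a <- dynamic_filter(psm)
  b <- dynamic_filter(psm)
  expect_identical(a$thresholds, b$thresholds)
  expect_identical(a$accepted, b$accepted)
})

test_that("the estimator is calibrated against realized false-target fractions", {
  # symmetric false matches: equally many false targets and decoys, both from
  # the same low-score distribution; the mean estimate should track the
  # realized false-target fraction among accepted PSMs
  set.seed(53)
  est <- real <- numeric(10)
  for (i in 1:10) {
    n_true <- 300; n_false <- 15; n_decoy <- 15
    psm <- rbind(make_psm(n_true, 0, 0),
                 make_psm(n_false, 0, 0, id_offset = n_true),
                 make_psm(n_decoy, 0, 0, is_decoy = TRUE,
                          id_offset = n_true + n_false))
    psm$protein_ids[psm$is_decoy] <-
      paste0("REV_", psm$protein_ids[psm$is_decoy])
    lowscore <- function(k) pmax(0.3, stats::rnorm(k, 1.6, .4))
    psm$xcorr <- c(pmax(0.3, stats::rnorm(n_true, 3.2, .6)),
                   lowscore(n_false), lowscore(n_decoy))
    psm$delta_cn <- pmin(1, pmax(0.05, stats::rnorm(nrow(psm), .3, .1)))
    acc <- psm[psm$xcorr >= 1.8, ]  # a fixed acceptance rule
    est[i] <- estimate_fdr(acc)
    acc_t <- acc[!acc$is_decoy, ]
    real[i] <- mean(as.integer(sub("^s", "", acc_t$spectrum_id)) > n_true)
  }
  p <- mean(real)
  # the estimator carries decoy-count noise on top of the binomial noise of
  # the realized fraction; allow 1.5 percentage points
  expect_lt(abs(mean(est) - p), 0.015)
})
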