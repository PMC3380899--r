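make_features <- function(protein, ratios_by_cond, reps = 1:2, heavy = 100,
                          peptide_prefix = "PEP") {
  rows <- list()
  for (cn in names(ratios_by_cond)) {
    r <- ratios_by_cond[[cn]]
    for (rep in reps) for (i in seq_along(r)) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = paste0(peptide_prefix, i, "K"), mods = "",
        protein_group = protein, condition = cn, replicate = rep,
        gel_region = "mid", light_intensity = heavy * r[i],
        heavy_intensity = heavy, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("the protein rollup is the median of peptide log2 ratios", {
  eq <- protein_log2_ratio(data.frame(light_intensity = 100,
                                      heavy_intensity = 100))
  expect_equal(eq$log2_ratio, 0)
  med <- protein_log2_ratio(data.frame(light_intensity = c(200, 200, 800),
                                       heavy_intensity = 100))
  expect_equal(med$log2_ratio, 1)
  # brute-force oracle on random record sets; bad records rejected and counted
  set.seed(13)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    rec <- data.frame(light_intensity = stats::rlnorm(n, 4, 1),
                      heavy_intensity = stats::rlnorm(n, 4, 1))
    rec$light_intensity[1] <- -1
    out <- protein_log2_ratio(rec)
    expect_equal(out$n_rejected, 1L)
    expect_equal(out$log2_ratio,
                 stats::median(log2(rec$light_intensity[-1] /
                                      rec$heavy_intensity[-1])))
  }
})

test_that("recentering zeroes the population mean and reports the shift", {
  expect_equal(as.numeric(recenter(rep(2.5, 10))), rep(0, 10))
  expect_equal(as.numeric(recenter(c(-1, 1))), c(-1, 1))
  set.seed(19)
  for (i in 1:5) {
    x <- stats::rnorm(50, stats::runif(1, -2, 2))
    r <- recenter(x)
    expect_equal(mean(r), 0, tolerance = 1e-9)
    expect_equal(attr(r, "mean_subtracted"), mean(x))
  }
})

test_that("significance cutoffs are 1.64 times the population SD", {
  set.seed(23)
  x <- stats::rnorm(10000)
  cut <- significance_cutoffs(data.frame(d43 = x, dS6 = x, dS6_43 = x))
  expect_lt(abs(cut[["d43"]] - 1.64), 0.03)
  # a population with SD 0.5548 gives the 0.91 cutoff
  y <- as.numeric(recenter(x))
  y <- y / stats::sd(y) * 0.5548
  cut2 <- significance_cutoffs(data.frame(d43 = y, dS6 = y, dS6_43 = y))
  expect_equal(round(cut2[["d43"]], 2), 0.91)
  cut3 <- significance_cutoffs(data.frame(d43 = rep(1, 5), dS6 = rep(1, 5),
                                          dS6_43 = rep(0, 5)))
  expect_equal(unname(cut3), c(0, 0, 0))
})

test_that("classification reproduces the printed group calls", {
  cuts <- c(d43 = 0.91, dS6 = 0.89, dS6_43 = 0.65)
  q <- data.frame(
    protein_group = c("TARDBP", "G3BP1", "NOP58", "DYNC1H1", "null"),
    d43 = c(3.51, 0.0, 0.33, 0.94, 0.1),
    dS6 = c(6.32, 1.70, -0.73, 0.28, -0.2))
  q$dS6_43 <- q$dS6 - q$d43
  q$dS6_43[3] <- -1.06  # printed value for the lost-in-S6 exemplar
  out <- classify_proteins(q, cuts)
  expect_equal(out$group[1], "group1_both"); expect_equal(out$direction[1], "up")
  expect_equal(out$group[2], "group2_s6");  expect_equal(out$direction[2], "up")
  expect_equal(out$group[3], "group4_lost_in_s6")
  expect_true(out$lost_in_s6[3])
  # dual marking: significant in the 43 model AND lost in S6
  expect_equal(out$group[4], "group3_43")
  expect_true(out$lost_in_s6[4])
  expect_equal(out$group[5], "unchanged")
  # missing comparisons give partial calls
  q$dS6[5] <- NA; q$dS6_43[5] <- NA
  out2 <- classify_proteins(q, cuts)
  expect_match(out2$not_evaluable[5], "dS6")
})

test_that("fold changes convert log2 differences to the printed folds", {
  expect_equal(fold_change(3.51), 11)
  expect_equal(fold_change(6.32), 80)
  expect_equal(fold_change(0), 1)
  expect_equal(fold_change(0.5), 2^0.5)  # below 2: not rounded
})

test_that("triple-map coordinates satisfy the difference identity", {
  q <- data.frame(protein_group = "TARDBP", d43 = 3.51, dS6 = 6.32,
                  dS6_43 = 6.32 - 3.51)
  m <- triple_map(q)
  expect_equal(c(m$x, m$y), c(3.51, 2.81))
  expect_equal(attr(m, "x_axis"), "d43")
  set.seed(29)
  q2 <- data.frame(protein_group = letters[1:20],
                   d43 = stats::rnorm(20), dS6 = stats::rnorm(20))
  q2$dS6_43 <- q2$dS6 - q2$d43
  m2 <- triple_map(q2)
  expect_equal(m2$y, q2$dS6 - q2$d43)
  m3 <- triple_map(q2, y_axis = "dS6")
  expect_equal(attr(m3, "y_axis"), "dS6")
  # a protein sitting at the population means maps to the origin
  r <- data.frame(d43 = as.numeric(recenter(q2$d43)))
  expect_equal(mean(r$d43), 0, tolerance = 1e-9)
})

test_that("quantify_proteins preserves the dS6_43 identity and skips mods", {
  fx <- make_features("P1", list(mock = c(1, 1, 1), tdp43 = c(2, 2, 2),
                                 tdps6 = c(4, 4, 4)))
  modrow <- fx[1, ]; modrow$mods <- "3:gg"; modrow$light_intensity <- 1e6
  q <- quantify_proteins(rbind(fx, modrow))
  expect_equal(q$d43, 1); expect_equal(q$dS6, 2); expect_equal(q$dS6_43, 1)
  expect_equal(q$dS6_43, q$dS6 - q$d43, tolerance = 1e-9)
  set.seed(37)
  fx2 <- do.call(rbind, lapply(1:8, function(i) {
    make_features(paste0("Q", i),
                  list(mock = stats::rlnorm(4), tdp43 = stats::rlnorm(4),
                       tdps6 = stats::rlnorm(4)))
  }))
  q2 <- quantify_proteins(fx2)
  expect_equal(q2$dS6_43, q2$dS6 - q2$d43, tolerance = 1e-9)
})

test_that("the one-tailed 1.64*SD rule flags about five percent of nulls", {
  set.seed(43)
  n <- 5000
  d <- draw_frame <- data.frame(d43 = stats::rnorm(n, 0, 0.55),
                                dS6 = stats::rnorm(n, 0, 0.54))
  d$dS6_43 <- stats::rnorm(n, 0, 0.40)
  r <- data.frame(d43 = as.numeric(recenter(d$d43)),
                  dS6 = as.numeric(recenter(d$dS6)),
                  dS6_43 = as.numeric(recenter(d$dS6_43)))
  cuts <- significance_cutoffs(r)
  for (cc in c("d43", "dS6", "dS6_43")) {
    frac_up <- mean(r[[cc]] > cuts[[cc]])
    ci <- 3 * sqrt(0.05 * 0.95 / n)
    expect_lt(abs(frac_up - 0.05), ci + 0.002)
  }
})

test_that("a spiked +1.5 effect at 20 peptides is recovered within 0.15", {
  errs <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    ratios <- lapply(c(mock = 0, tdp43 = 1.5, tdps6 = 0), function(l2)
      2^(l2 + stats::rnorm(20, 0, 0.25)))
    q <- quantify_proteins(make_features("SPIKE", ratios))
    errs[s] <- q$d43 - 1.5
  }
  expect_lt(abs(stats::median(errs)), 0.15)
})
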