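test_that("all required fragments must match for a scan to quantify", {
  scan <- data.frame(mz = c(993.47, 1351.60, 500.0),
                     intensity = c(1000, 2000, 50))
  expect_equal(sum_required_fragments(scan, c(993.45, 1351.61), 0.3), 3000)
  expect_true(is.na(sum_required_fragments(scan, c(993.45, 700.0), 0.3)))
  # the closest peak wins when several fall inside the tolerance
  dup <- data.frame(mz = c(993.2, 993.5, 1351.7), intensity = c(10, 20, 30))
  expect_equal(sum_required_fragments(dup, c(993.45, 1351.61), 0.5), 50)
  set.seed(71)
  for (i in 1:10) {
    peaks <- data.frame(mz = sort(stats::runif(20, 400, 1400)),
                        intensity = stats::rlnorm(20, 5, 1))
    req <- sample(peaks$mz, 3) + stats::runif(3, -0.2, 0.2)
    brute <- sum(vapply(req, function(f)
      peaks$intensity[which.min(abs(peaks$mz - f))], 1.0))
    expect_equal(sum_required_fragments(peaks, req, 0.5), brute)
  }
})

test_that("AGC correction rescales by 150 ms over the inject time", {
  expect_equal(agc_correct(1000, 150), 1000)
  expect_equal(agc_correct(1000, 75), 2000)
  set.seed(73)
  it <- stats::runif(20, 1, 150); x <- stats::rlnorm(20, 6, 1)
  expect_equal(agc_correct(x, it), x * 150 / it)
  expect_error(agc_correct(10, 0), "positive")
})

test_that("AGC correction cancels flux-dependent fill times below the cap", {
  # halving the flux doubles the fill time (until the 150 ms cap), leaving
  # the corrected intensity unchanged
  agc_target <- 5000
  for (flux in c(400, 200, 100, 50)) {
    it <- min(150, agc_target / flux)
    raw <- flux * it
    expect_equal(agc_correct(raw, it), flux * 150)
  }
})

test_that("XIC quantification returns the apex within the window", {
  tri <- data.frame(time = 0:10, intensity = c(0:5, 4:0) * 10)
  expect_equal(as.numeric(xic_quantify(tri)), 50)
  two <- data.frame(time = 0:10,
                    intensity = c(0, 5, 0, 0, 0, 0, 0, 9, 3, 0, 0))
  expect_equal(as.numeric(xic_quantify(two, window = c(5, 10))), 9)
  expect_true(is.na(xic_quantify(two, window = c(20, 30))))
  set.seed(79)
  for (i in 1:10) {
    tr <- data.frame(time = 0:50, intensity = stats::rlnorm(51, 3, 1))
    w <- sort(stats::runif(2, 0, 50))
    brute <- max(tr$intensity[tr$time >= w[1] & tr$time <= w[2]])
    expect_equal(as.numeric(xic_quantify(tr, w)), brute)
  }
})

make_targeted <- function(target_log2, ref_scale = c(ctl = 1, exp = 1),
                          reps = 1:2, noise = 0) {
  tgt <- list(); ref <- list()
  for (r in reps) for (smp in c("ctl", "exp")) {
    l2 <- if (smp == "exp") target_log2 else 0
    tgt[[length(tgt) + 1L]] <- data.frame(
      peptide_id = "t", sample = smp, replicate = r,
      intensity = ref_scale[[smp]] * 1000 * 2^(l2 + stats::rnorm(1, 0, noise)))
    for (rid in c("r1", "r2")) {
      ref[[length(ref) + 1L]] <- data.frame(
        peptide_id = rid, sample = smp, replicate = r,
        intensity = ref_scale[[smp]] * 500 * 2^stats::rnorm(1, 0, noise))
    }
  }
  list(targets = do.call(rbind, tgt), refs = do.call(rbind, ref))
}

test_that("identical samples summarize to zero change", {
  d <- make_targeted(0)
  out <- normalize_and_summarize(d$targets, d$refs, control = "ctl")
  expect_equal(out$mean_log2, 0, tolerance = 1e-12)
  expect_equal(out$percent_change, 0, tolerance = 1e-9)
  expect_equal(out$k, 4L)  # 2 references x 2 replicates
})

test_that("a 0.70 log2 ratio is a 62 percent increase", {
  d <- make_targeted(0.70)
  out <- normalize_and_summarize(d$targets, d$refs, control = "ctl")
  expect_equal(out$mean_log2, 0.70, tolerance = 1e-12)
  expect_equal(round(out$percent_change), 62)
})

test_that("reference normalization cancels per-sample loading factors", {
  set.seed(83)
  a <- make_targeted(1.2, ref_scale = c(ctl = 1, exp = 1), noise = 0.03)
  set.seed(83)
  b <- make_targeted(1.2, ref_scale = c(ctl = 1, exp = 7.5), noise = 0.03)
  oa <- normalize_and_summarize(a$targets, a$refs, control = "ctl")
  ob <- normalize_and_summarize(b$targets, b$refs, control = "ctl")
  expect_equal(oa$mean_log2, ob$mean_log2, tolerance = 1e-9)
})

test_that("a four-fold spike is recovered across seeds", {
  est <- numeric(12)
  for (s in seq_along(est)) {
    set.seed(900 + s)
    d <- make_targeted(2.0, noise = 0.08)
    est[s] <- normalize_and_summarize(d$targets, d$refs,
                                      control = "ctl")$mean_log2
  }
  expect_lt(abs(mean(est) - 2.0), 0.1)
})

test_that("the t-based confidence interval follows its formula", {
  set.seed(89)
  d <- make_targeted(1.0, noise = 0.1)
  out <- normalize_and_summarize(d$targets, d$refs, control = "ctl")
  # recompute from the k normalized log2 values
  vals <- local({
    v <- numeric(0)
    for (r in 1:2) for (rid in c("r1", "r2")) {
      te <- d$targets$intensity[d$targets$sample == "exp" &
                                  d$targets$replicate == r]
      tc <- d$targets$intensity[d$targets$sample == "ctl" &
                                  d$targets$replicate == r]
      re <- d$refs$intensity[d$refs$sample == "exp" & d$refs$replicate == r &
                               d$refs$peptide_id == rid]
      rc <- d$refs$intensity[d$refs$sample == "ctl" & d$refs$replicate == r &
                               d$refs$peptide_id == rid]
      v <- c(v, log2((te / re) / (tc / rc)))
    }
    v
  })
  expect_equal(out$mean_log2, mean(vals))
  expect_equal(out$ci95, stats::qt(0.975, 3) * stats::sd(vals) / 2)
})

test_that("samples missing a reference are excluded and reported", {
  d <- make_targeted(1.0)
  d$refs <- d$refs[!(d$refs$sample == "exp" & d$refs$replicate == 2 &
                       d$refs$peptide_id == "r2"), ]
  out <- normalize_and_summarize(d$targets, d$refs, control = "ctl")
  expect_equal(out$k, 3L)
  expect_match(attr(out, "excluded"), "r2")
})
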