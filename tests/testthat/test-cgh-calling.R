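# Copy-number calling: centering, segmentation (with an exhaustive
# least-squares oracle), thresholds, state calls, two-pass recentering and
# sex-chromosome exclusion.

test_that("median_center zeroes the median and handles missing values", {
  expect_equal(median_center(c(0.3, 0.5, 0.7)), c(-0.2, 0, 0.2))
  centered <- c(-0.2, 0, 0.2)
  expect_equal(median_center(centered), centered)
  with_na <- c(0.1, NA, 0.3, 0.5, 0.7)
  out <- median_center(with_na)
  expect_equal(out, with_na - median(c(0.1, 0.3, 0.5, 0.7)))
  expect_true(is.na(out[2]))
  expect_error(median_center(c(NA_real_, NA_real_)), "no non-missing")
})

test_that("segmentation finds noiseless changepoints exactly", {
  panel <- toy_panel(100)
  x <- c(rep(0, 50), rep(0.8, 50))
  seg <- segment_profile(x, panel, min_seg_probes = 5)
  expect_equal(nrow(seg$segments), 2L)
  expect_equal(seg$segments$end_idx[1], 50L)
  expect_equal(seg$segments$mean, c(0, 0.8))
  expect_equal(seg$probe_mean, c(rep(0, 50), rep(0.8, 50)))

  # constant profile: one segment per chromosome
  panel2 <- probe_panel(sprintf("q%02d", 1:40), rep(c("1", "2"), each = 20),
                        rep(seq(1e6, 2e7, length.out = 20), 2))
  seg2 <- segment_profile(rep(0.1, 40), panel2)
  expect_equal(nrow(seg2$segments), 2L)
  expect_equal(seg2$segments$chrom, c("1", "2"))
})

test_that("segmentation equals exhaustive least squares on small profiles", {
  set.seed(42)
  for (case in 1:20) {
    n <- sample(10:20, 1)
    k <- sample(0:2, 1)
    min_len <- 3
    # plant k breakpoints with segments >= min_len, distinct levels
    bkps <- integer(0)
    if (k > 0) {
      ok <- FALSE
      while (!ok) {
        bkps <- sort(sample(seq(min_len, n - min_len), k))
        ok <- all(diff(c(0, bkps, n)) >= min_len)
      }
    }
    levels <- sample(seq(-1, 1, by = 0.25), k + 1)
    while (any(diff(levels) == 0))
      levels <- sample(seq(-1, 1, by = 0.25), k + 1)
    x <- rep(levels, diff(c(0, bkps, n)))
    seg <- segment_profile(x, toy_panel(n), min_seg_probes = min_len)
    got_bkps <- head(seg$segments$end_idx, -1)
    oracle <- oracle_segment(x, max_bkps = 2, min_len = min_len)
    expect_equal(as.integer(got_bkps), as.integer(oracle$bkps),
                 info = sprintf("case %d: n=%d k=%d", case, n, k))
  }
})

test_that("noisy planted breakpoints are recovered within 2 probes", {
  panel <- toy_panel(100)
  set.seed(7)
  x <- c(rep(0, 60), rep(0.8, 40)) + rnorm(100, 0, 0.15)
  seg <- segment_profile(x, panel, min_seg_probes = 5)
  expect_equal(nrow(seg$segments), 2L)
  expect_lte(abs(seg$segments$end_idx[1] - 60L), 2L)
})

test_that("derive_thresholds calibrates from X/Y spread or falls back", {
  default <- derive_thresholds()
  expect_equal(default$gain_cut, 0.05)
  expect_equal(default$loss_cut, -0.05)

  # vectors with SD ~0.02 at k = 2 give cuts ~ +/-0.04
  set.seed(1)
  ref <- list(rnorm(4000, 1, 0.02), rnorm(4000, -1, 0.02))
  thr <- derive_thresholds(ref, k = 2)
  expect_equal(thr$gain_cut, 0.04, tolerance = 0.05)
  expect_equal(thr$loss_cut, -thr$gain_cut)

  expect_error(derive_thresholds(ref, k = 0), "positive")
  expect_error(derive_thresholds(list(rep(0.3, 10))), "variance is zero")

  # works from a generated sex-mismatch reference object
  panel <- default_probe_panel(400, chroms = c("1", "2"), include_xy = TRUE)
  spec <- cgh_cohort_spec(panel, c(g = 2L), noise_sd = 0.1, seed = 5L)
  thr2 <- derive_thresholds(generate_sex_mismatch_reference(spec), k = 2)
  expect_equal(thr2$gain_cut, 0.2, tolerance = 0.15)
})

test_that("state calls follow strict threshold inequalities", {
  panel <- toy_panel(20)
  thr <- cgh_thresholds(0.05, -0.05, 1.0)
  means <- c(0.06, -0.06, 0.04, 0.05, -0.05, 1.2, 1.0, 0)
  x <- rep(means, length.out = 20)[1:20]
  # craft a segmented profile directly to test pure classification
  seg <- structure(list(
    segments = data.frame(chrom = "1", start_idx = 1:8, end_idx = 1:8,
                          start_bp = 1:8, end_bp = 1:8, n_probes = 1L,
                          mean = means),
    probe_mean = means), class = "segmented_profile")
  calls <- call_states(seg, thr)
  expect_equal(calls$segments$call,
               c("gain", "loss", "normal", "normal", "normal",
                 "high-amp", "high-amp", "normal"))
  # raising gain_cut never increases gain calls
  n_gain <- vapply(c(0.02, 0.05, 0.2, 0.7), function(cut)
    sum(call_states(seg, cgh_thresholds(cut, -0.05, 1.5)
        )$probe_call %in% c("gain", "high-amp")), numeric(1))
  expect_true(all(diff(n_gain) <= 0))
})

test_that("segment means conserve member-probe averages", {
  set.seed(3)
  panel <- default_probe_panel(300, chroms = c("1", "2", "3"))
  x <- rnorm(300, 0, 0.2) + rep(c(0, 0.5, 0), each = 100)
  seg <- segment_profile(x, panel)
  for (i in seq_len(nrow(seg$segments))) {
    idx <- seg$segments$start_idx[i]:seg$segments$end_idx[i]
    idx <- idx[!is.na(x[idx])]
    expect_equal(mean(seg$probe_mean[idx]), seg$segments$mean[i])
    expect_equal(mean(x[idx]), seg$segments$mean[i])
  }
})

test_that("recentering on normal segments restores a shifted baseline", {
  panel <- toy_panel(100)
  # 30% aberrant genome, baseline shifted by +0.03, noiseless; the shift
  # is below gain_cut so first-pass calls are still correct
  x <- c(rep(0, 70), rep(-0.8, 30)) + 0.03
  seg1 <- segment_profile(x, panel)
  first <- call_states(seg1, cgh_thresholds())
  second <- recenter_and_resegment(x, first, panel, cgh_thresholds())
  expect_true(second$recentered)
  normal_after <- which(second$calls$probe_call == "normal")
  expect_equal(unname(second$log2[normal_after[1]]), 0)
  expect_equal(median(second$log2[1:70]), 0)

  # an already-centered, majority-normal profile is unchanged by pass two
  x2 <- c(rep(0, 80), rep(0.8, 20))
  seg2 <- segment_profile(x2, panel)
  call2 <- call_states(seg2, cgh_thresholds())
  again <- recenter_and_resegment(x2, call2, panel, cgh_thresholds())
  expect_equal(again$log2, x2)
  expect_identical(again$calls$probe_call, call2$probe_call)

  # all-aberrant profile: recentering skipped with a warning
  x3 <- rep(0.8, 100)
  seg3 <- segment_profile(x3, panel)
  call3 <- call_states(seg3, cgh_thresholds())
  expect_warning(
    res3 <- recenter_and_resegment(x3, call3, panel, cgh_thresholds()),
    "skipped")
  expect_false(res3$recentered)
})

test_that("two-pass calling is at least as accurate as one pass", {
  # a quarter of the genome lost in every sample biases whole-genome
  # median centering; recentering on normal segments must repair it
  panel <- default_probe_panel(600, chroms = as.character(1:6))
  spec <- cgh_cohort_spec(
    panel, c(g = 10L),
    list(aberration_spec("1", 1e6, 2.4e8, -0.5, c(g = 1))),
    noise_sd = 0.15, baseline_shift_sd = 0.05, seed = 19L)
  coh <- generate_acgh_cohort(spec)
  acc <- function(calls) {
    simplified <- ifelse(calls == "high-amp", "gain", calls)
    mean(simplified == coh$truth_state, na.rm = TRUE)
  }
  two_pass <- call_cgh_cohort(coh$log2, coh$panel)
  one_pass <- call_cgh_cohort(coh$log2, coh$panel, recenter = FALSE)
  expect_gte(acc(two_pass$calls) + 1e-9, acc(one_pass$calls))
})

test_that("sex chromosomes are excluded with order preserved", {
  panel <- default_probe_panel(200, chroms = c("1", "2"), include_xy = TRUE)
  profiles <- matrix(0, nrow(panel), 3)
  out <- exclude_sex_chromosomes(panel, profiles)
  expect_false(any(out$panel$chrom %in% c("X", "Y")))
  n_xy <- sum(panel$chrom %in% c("X", "Y"))
  expect_equal(nrow(out$panel), nrow(panel) - n_xy)
  expect_equal(nrow(out$profiles), nrow(panel) - n_xy)
  expect_identical(out$panel$probe,
                   panel$probe[!panel$chrom %in% c("X", "Y")])
  # no-op without X/Y
  auto <- toy_panel(10)
  expect_equal(nrow(exclude_sex_chromosomes(auto)$panel), 10L)
})
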