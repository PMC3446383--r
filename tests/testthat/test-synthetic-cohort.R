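# Generators: seeded determinism, planted-parameter recovery within exact
# confidence intervals, and ground-truth alignment.

test_that("aCGH generator is reproducible and respects its spec", {
  spec <- cgh_cohort_spec(toy_panel(50), c(g1 = 4L, g2 = 3L),
                          noise_sd = 0.1, seed = 11L)
  a <- generate_acgh_cohort(spec)
  b <- generate_acgh_cohort(spec)
  expect_identical(a$log2, b$log2)
  expect_identical(a$truth_state, b$truth_state)
  expect_equal(dim(a$log2), c(50L, 7L))
  expect_identical(rownames(a$log2), a$panel$probe)

  # no aberrations, tiny noise: all truth normal, all |log2| small
  quiet <- generate_acgh_cohort(
    cgh_cohort_spec(toy_panel(50), c(g = 5L), noise_sd = 0.01,
                    baseline_shift_sd = 0.001, seed = 2L))
  expect_true(all(quiet$truth_state == "normal"))
  expect_lt(max(abs(quiet$log2)), 0.1)

  expect_error(generate_acgh_cohort(
    cgh_cohort_spec(toy_panel(10), c(g = 0L), seed = 1L)),
    "at least one sample")
  expect_error(probe_panel(character(0), character(0), numeric(0)),
               "at least one probe")
})

test_that("planted prevalences are recovered within exact binomial bounds", {
  ab <- aberration_spec("1", 1e6, 3e6, -0.5, c(met = 0.9, primary = 0.1))
  spec <- cgh_cohort_spec(toy_panel(40), c(met = 50L, primary = 50L),
                          list(ab), noise_sd = 0.1, seed = 31L)
  coh <- generate_acgh_cohort(spec)
  grp <- coh$samples$group
  n_met <- sum(coh$carriers[1, grp == "met"])
  n_pri <- sum(coh$carriers[1, grp == "primary"])
  expect_gte(n_met, qbinom(0.005, 50, 0.9))
  expect_lte(n_met, qbinom(0.995, 50, 0.9))
  expect_gte(n_pri, qbinom(0.005, 50, 0.1))
  expect_lte(n_pri, qbinom(0.995, 50, 0.1))
  # carried aberration visible in the planted truth over covered probes
  idx <- which(coh$panel$bp >= 1e6 & coh$panel$bp <= 3e6)
  carrier_cols <- which(coh$carriers[1, ])
  expect_true(all(coh$truth_state[idx, carrier_cols] == "loss"))
})

test_that("sex-mismatch reference carries the configured X/Y offsets", {
  panel <- default_probe_panel(300, chroms = as.character(1:4),
                               include_xy = TRUE)
  spec <- cgh_cohort_spec(panel, c(g = 3L), noise_sd = 1e-12, seed = 4L)
  ref <- generate_sex_mismatch_reference(spec, n_ref = 2,
                                         mismatch_shift = c(X = 1, Y = -1))
  x_rows <- panel$chrom == "X"; y_rows <- panel$chrom == "Y"
  expect_equal(unname(ref$log2[x_rows, 1]), rep(1, sum(x_rows)),
               tolerance = 1e-6)
  expect_equal(unname(ref$log2[y_rows, 2]), rep(-1, sum(y_rows)),
               tolerance = 1e-6)
  expect_equal(mean(ref$log2[!(x_rows | y_rows), 1]), 0, tolerance = 1e-6)

  # with real noise, the X/Y variance sits inside the chi-square interval
  spec2 <- cgh_cohort_spec(panel, c(g = 3L), noise_sd = 0.2, seed = 9L)
  ref2 <- generate_sex_mismatch_reference(spec2, n_ref = 1)
  v <- var(ref2$log2[x_rows, 1])
  n <- sum(x_rows)
  expect_gte(v, 0.2^2 * qchisq(0.005, n - 1) / (n - 1))
  expect_lte(v, 0.2^2 * qchisq(0.995, n - 1) / (n - 1))
  # reproducible
  expect_identical(ref2$log2,
                   generate_sex_mismatch_reference(spec2, n_ref = 1)$log2)

  no_xy <- cgh_cohort_spec(toy_panel(20), c(g = 2L), seed = 1L)
  expect_error(generate_sex_mismatch_reference(no_xy), "no X/Y probes")
})

test_that("microsatellite purity model yields the exact algebraic folds", {
  mk <- data.frame(marker = "M1", chrom = "10", bp = 9e7)
  base <- function(f, prev = 1) msat_cohort_spec(
    mk, c(g = 10L),
    list(ai_region_spec("10", 8e7, 1e8, f, c(g = prev))),
    heterozygosity = 1, peak_noise_cv = 0, seed = 3L)

  # loss fraction 0: tumor ratio equals normal ratio exactly
  coh0 <- generate_msat_cohort(base(0))
  with(coh0$peaks, expect_equal(t_allele1 / t_allele2,
                                n_allele1 / n_allele2))

  # loss fraction 0.5, no noise: normalized fold exactly 2.0
  coh5 <- generate_msat_cohort(base(0.5))
  cl <- classify_peak_table(coh5$peaks)
  expect_equal(cl$fold, rep(2, nrow(cl)))
  expect_true(all(cl$verdict == "AI"))

  # heterozygosity 0: everything noninformative
  spec_hom <- msat_cohort_spec(mk, c(g = 8L), heterozygosity = 0, seed = 2L)
  coh_hom <- generate_msat_cohort(spec_hom)
  expect_true(all(coh_hom$truth == "noninformative"))
  expect_true(all(is.na(coh_hom$peaks$n_allele2)))

  expect_error(
    msat_cohort_spec(data.frame(marker = "M1", chrom = "QQ", bp = 1),
                     c(g = 1L)),
    "unknown chromosome")
})

test_that("expression generator plants recoverable fold changes", {
  genes <- data.frame(gene = sprintf("g%03d", 1:200), chrom = "10",
                      bp = seq(1e6, 2e8, length.out = 200))
  de <- data.frame(gene = "g005", log2fc = -1)
  spec <- expr_cohort_spec(genes, c(a = 20L, b = 20L), de,
                           noise_sd = 0.4, seed = 21L)
  coh <- generate_expression_cohort(spec)
  expect_identical(coh$exprs, generate_expression_cohort(spec)$exprs)

  grp <- coh$samples$group
  d_obs <- mean(coh$exprs["g005", grp == "b"]) -
    mean(coh$exprs["g005", grp == "a"])
  se <- 0.4 * sqrt(1 / 20 + 1 / 20)
  expect_lt(abs(d_obs - (-1)), qt(0.995, 38) * se)

  # null genes differ only by sampling noise (99% z-bound each, checked
  # on the mean of per-gene differences)
  null_spec <- expr_cohort_spec(genes, c(a = 15L, b = 15L), seed = 8L)
  null <- generate_expression_cohort(null_spec)
  gm <- rowMeans(null$exprs[, null$samples$group == "b"]) -
    rowMeans(null$exprs[, null$samples$group == "a"])
  expect_lt(abs(mean(gm)), 3 * 0.5 * sqrt(2 / 15) / sqrt(200))

  expect_error(
    expr_cohort_spec(genes, c(a = 2L, b = 2L),
                     data.frame(gene = "nope", log2fc = 1)),
    "not present")
  expect_error(
    expr_cohort_spec(rbind(genes, genes[1, ]), c(a = 2L, b = 2L)),
    "duplicate")
})
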