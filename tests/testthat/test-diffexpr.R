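# Quantile normalization, the SAM d-statistic, permutation FDR and the
# positional candidate filter.

test_that("quantile normalization equalizes sample distributions", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- c("g1", "g2", "g3")
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  # idempotence and sample-order invariance
  set.seed(5)
  big <- matrix(rnorm(500), 100, 5,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  once <- quantile_normalize(big)
  expect_equal(quantile_normalize(once), once)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(quantile_normalize(big[, perm]), once[, perm])

  # post-condition: per-sample sorted vectors identical
  sorted <- apply(once, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  # identical samples unchanged
  same <- cbind(a = c(1, 5, 9), b = c(1, 5, 9))
  rownames(same) <- c("x", "y", "z")
  expect_equal(quantile_normalize(same), same)

  m2 <- m; rownames(m2) <- c("g1", "g2", "zz")
  expect_error(quantile_normalize(list(m, m2)), "identical gene set")
})

test_that("the d-statistic follows its defining arithmetic", {
  ex <- rbind(g1 = c(0, 0, 1, 1), g2 = c(2, 3, 2, 3))
  grp <- c("a", "a", "b", "b")
  st <- sam_statistic(ex, grp, s0 = 1)
  expect_equal(unname(st$d["g1"]), 1)        # pooled SE 0, d = 1/(0+1)
  expect_equal(unname(st$d["g2"]), 0)        # equal group means
  # doubling s0 never increases |d|
  st2 <- sam_statistic(ex, grp, s0 = 2)
  expect_true(all(abs(st2$d) <= abs(st$d) + 1e-12))
  expect_error(sam_statistic(ex, grp, s0 = 0), "undefined")
  expect_error(sam_statistic(ex, c("a", "a", "a", "b")), "at least 2")
})

test_that("SAM permutation stage is seeded, null-safe and recovers signal", {
  # null data: empty or near-empty significant set
  null <- generate_expression_cohort(
    default_expr_spec(seed = 31L, n_genes = 400, n_de = 0,
                      n_per_group = 6L))
  res_null <- sam_significant(null$exprs, null$samples$group,
                              target_fdr = 0.05, n_perm = 100, seed = 31L)
  expect_lte(length(res_null$significant), 2L)

  # planted effects recovered, deterministically under one seed
  coh <- generate_expression_cohort(
    default_expr_spec(seed = 17L, n_genes = 500, n_de = 25,
                      n_per_group = 8L))
  res <- sam_significant(coh$exprs, coh$samples$group, 0.05,
                         n_perm = 150, seed = 17L)
  res_again <- sam_significant(coh$exprs, coh$samples$group, 0.05,
                               n_perm = 150, seed = 17L)
  expect_identical(res$significant, res_again$significant)
  expect_gte(sum(coh$truth_de$gene %in% res$significant), 22L)

  # more permutations than distinct label splits: warn and use all
  tiny <- generate_expression_cohort(
    default_expr_spec(seed = 2L, n_genes = 50, n_de = 0, n_per_group = 3L))
  expect_warning(
    res_tiny <- sam_significant(tiny$exprs, tiny$samples$group,
                                n_perm = 1000, seed = 2L),
    "distinct permutations")
  expect_equal(res_tiny$n_perm_used, choose(6, 3))
})

test_that("candidate filtering applies abundance, position and FC rules", {
  # six genes with constructed means; survivors enumerable by hand
  grp <- rep(c("a", "b"), each = 4)
  mk_gene <- function(base, shift) c(rep(base, 4), rep(base + shift, 4))
  ex <- rbind(
    hi_chr10_fc4   = mk_gene(10, -2),   # keeps: abundant, chr10, FC 4
    hi_chr10_fc1   = mk_gene(10, -0.5), # drops: FC below 2
    hi_chr9_fc4    = mk_gene(10, -2),   # drops: wrong chromosome
    lo_chr10_fc4   = mk_gene(1, -2),    # drops: below 25th percentile
    hi_chr10_up4   = mk_gene(10, 2),    # keeps: FC cut is two-sided
    hi_chr10_fc4b  = mk_gene(10, -2)    # drops: not significant by SAM
  )
  genes <- data.frame(
    gene = rownames(ex),
    chrom = c("10", "10", "9", "10", "10", "10"),
    bp = c(1e6, 2e6, 3e6, 4e6, 5e6, 6e6))
  sam <- list(significant = setdiff(rownames(ex), "hi_chr10_fc4b"),
              d = setNames(rep(-5, 6), rownames(ex)),
              qvalue = setNames(rep(0, 6), rownames(ex)))
  out <- filter_candidates(sam, ex, genes, grp,
                           min_expression_percentile = 25,
                           chromosome = "10", min_fold_change = 2)
  expect_setequal(out$gene, c("hi_chr10_fc4", "hi_chr10_up4"))
  expect_equal(out$fold_change[out$gene == "hi_chr10_fc4"], -4)
  expect_equal(out$fold_change[out$gene == "hi_chr10_up4"], 4)

  # each filter alone never removes a gene the combined filter keeps
  loose <- filter_candidates(sam, ex, genes, grp, 0, NULL, NULL, 1.0001)
  expect_true(all(out$gene %in% loose$gene))
  expect_true(all(out$gene %in% sam$significant))

  # bp window restricts positionally, closed interval
  win <- filter_candidates(sam, ex, genes, grp, chromosome = "10",
                           bp_window = c(1e6, 5e6))
  expect_setequal(win$gene, c("hi_chr10_fc4", "hi_chr10_up4"))
})

test_that("genes_in_region uses a closed interval", {
  cand <- data.frame(gene = c("a", "b", "c"), bp = c(100, 200, 300))
  expect_equal(genes_in_region(cand, 100, 200)$gene, c("a", "b"))
  expect_equal(nrow(genes_in_region(cand[0, ], 1, 10)), 0L)
  expect_equal(genes_in_region(cand, 300, 301)$gene, "c")
})
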