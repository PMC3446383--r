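# SAM-style permutation differential expression between two groups, with a
# positional / fold-change / abundance candidate filter.

#' Quantile-normalize one or more expression matrices
#'
#' Matrices on identical gene sets are combined column-wise and quantile
#' normalized so that every sample shares the cross-sample rank-mean
#' distribution; ties receive the mean of the implicated rank means
#' (\code{limma::normalizeQuantiles}).
#'
#' @param ... one or more genes x samples matrices with identical row
#'   names.
#' @return the combined, normalized genes x samples matrix.
#' @export
quantile_normalize <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) && !is.matrix(mats[[1]]))
    mats <- mats[[1]]
  stopifnot(length(mats) >= 1L)
  ref <- rownames(mats[[1L]])
  for (m in mats) {
    stopifnot(is.matrix(m))
    if (!identical(rownames(m), ref))
      stopf("matrices must share an identical gene set (row names)")
  }
  combined <- do.call(cbind, mats)
  out <- limma::normalizeQuantiles(combined, ties = TRUE)
  dimnames(out) <- dimnames(combined)
  out
}

# Per-gene group means and pooled standard error of the difference,
# vectorized over genes. labels2 is a logical matrix (samples x perms) of
# group-2 membership, allowing many permutations in one pass.
group_stats <- function(exprs, in_g2) {
  n2 <- sum(in_g2); n1 <- ncol(exprs) - n2
  m2 <- rowMeans(exprs[, in_g2, drop = FALSE])
  m1 <- rowMeans(exprs[, !in_g2, drop = FALSE])
  ss2 <- rowSums((exprs[, in_g2, drop = FALSE] - m2)^2)
  ss1 <- rowSums((exprs[, !in_g2, drop = FALSE] - m1)^2)
  pooled <- (ss1 + ss2) / (n1 + n2 - 2)
  s <- sqrt((1 / n1 + 1 / n2) * pooled)
  list(diff = m2 - m1, s = s)
}

#' SAM d-statistic
#'
#' Moderated two-group statistic
#' \code{d = (mean2 - mean1) / (s + s0)} where \code{s} is the pooled
#' standard error of the mean difference and \code{s0} a fudge factor
#' stabilizing the denominator for low-variance genes.
#'
#' @param exprs genes x samples matrix (log2 scale).
#' @param groups group label per sample; exactly two levels, each with at
#'   least two samples.
#' @param s0 fudge factor; \code{NULL} (default) uses the 5th percentile
#'   of the per-gene \code{s} distribution.
#' @return list with \code{d} (per-gene statistic), \code{s}, \code{s0}
#'   and \code{diff} (mean2 - mean1 per gene).
#' @export
sam_statistic <- function(exprs, groups, s0 = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stopf("need exactly two groups")
  if (any(table(groups) < 2L)) stopf("need at least 2 samples per group")
  st <- group_stats(exprs, groups == lv[2L])
  if (is.null(s0)) s0 <- stats::quantile(st$s, 0.05, names = FALSE)
  if (s0 == 0 && any(st$s == 0))
    stopf("zero-variance gene with s0 = 0: d-statistic undefined")
  list(d = st$diff / (st$s + s0), s = st$s, s0 = s0, diff = st$diff)
}

#' SAM-style significant genes by permutation FDR
#'
#' Builds the null distribution of the d-statistic from seeded label
#' permutations. Candidate cutoffs are the observed |d| values; for each
#' cutoff the estimated FDR is the median permuted count of |d| at or
#' above the cutoff divided by the observed count. The returned set is
#' the largest whose estimated FDR does not exceed \code{target_fdr}.
#' Per-gene q-values are the monotonized FDR estimates at each gene's own
#' |d|.
#'
#' @param exprs genes x samples matrix (log2 scale).
#' @param groups group label per sample (two levels).
#' @param target_fdr FDR level (default 0.05).
#' @param n_perm number of label permutations (default 200). If fewer
#'   distinct permutations exist, all distinct ones are used with a
#'   warning.
#' @param s0 fudge factor, as in \code{\link{sam_statistic}}.
#' @param seed integer seed for the permutation draw.
#' @return list with \code{significant} (gene names), \code{d},
#'   \code{qvalue} (per gene), \code{s0}, \code{cutoff} (the |d| cutoff
#'   used, Inf when nothing is significant) and \code{n_perm_used}.
#' @export
sam_significant <- function(exprs, groups, target_fdr = 0.05,
                            n_perm = 200L, s0 = NULL, seed = 1L) {
  if (n_perm < 1L) stopf("n_perm must be at least 1")
  if (target_fdr <= 0 || target_fdr >= 1)
    stopf("target_fdr must lie strictly between 0 and 1")
  groups <- as.character(groups)
  lv <- unique(groups)
  obs <- sam_statistic(exprs, groups, s0)
  n <- ncol(exprs)
  n2 <- sum(groups == lv[2L])
  n_distinct <- choose(n, n2)
  n_use <- n_perm
  if (n_distinct < n_perm) {
    warning("only ", n_distinct, " distinct permutations exist; using all")
    n_use <- n_distinct
  }

  set.seed(seed)
  if (n_use == n_distinct) {
    combs <- utils::combn(n, n2)
    perm_idx <- lapply(seq_len(ncol(combs)), function(j) combs[, j])
  } else {
    perm_idx <- lapply(seq_len(n_use), function(j) sample(n, n2))
  }
  abs_d_perm <- vapply(perm_idx, function(idx) {
    in_g2 <- seq_len(n) %in% idx
    st <- group_stats(exprs, in_g2)
    abs(st$diff / (st$s + obs$s0))
  }, numeric(nrow(exprs)))

  abs_obs <- abs(obs$d)
  ord <- order(abs_obs, decreasing = TRUE)
  cutoffs <- abs_obs[ord]
  obs_counts <- seq_along(cutoffs)
  # per permutation, count |d_perm| >= each cutoff via a sorted lookup
  perm_counts <- vapply(seq_len(ncol(abs_d_perm)), function(j) {
    sv <- sort(abs_d_perm[, j])
    length(sv) - findInterval(cutoffs, sv, left.open = TRUE)
  }, numeric(length(cutoffs)))
  med_perm <- apply(perm_counts, 1L, stats::median)
  fdr_hat <- pmin(1, med_perm / obs_counts)
  # q-value: smallest estimated FDR over cutoffs at or below the gene's |d|
  qvals_sorted <- rev(cummin(rev(fdr_hat)))
  qvalue <- numeric(length(abs_obs))
  qvalue[ord] <- qvals_sorted

  pass <- which(qvals_sorted <= target_fdr)
  if (length(pass)) {
    k <- max(pass)
    cutoff <- cutoffs[k]
    significant <- rownames(exprs)[ord[seq_len(k)]]
  } else {
    cutoff <- Inf
    significant <- character(0)
  }
  names(qvalue) <- rownames(exprs)
  list(significant = significant, d = stats::setNames(obs$d, rownames(exprs)),
       qvalue = qvalue, s0 = obs$s0, cutoff = cutoff, n_perm_used = n_use)
}

#' Positional / abundance / fold-change candidate filter
#'
#' Narrows a significant gene set to candidates that are (a) expressed at
#' or above a percentile of the overall expression level (per-gene mean
#' across all samples), (b) located on the configured chromosome
#' (optionally within a bp window) and (c) changed more than
#' \code{min_fold_change}-fold between the groups, with the fold change
#' computed on anti-logged group means.
#'
#' @param sam a \code{\link{sam_significant}} result.
#' @param exprs the genes x samples matrix the result was computed on.
#' @param genes gene annotation (gene, chrom, bp) covering all rows.
#' @param groups group label per sample.
#' @param min_expression_percentile abundance filter (default 25).
#' @param chromosome chromosome filter (default "10"); \code{NULL}
#'   disables it.
#' @param bp_window optional numeric length-2 closed bp interval.
#' @param min_fold_change linear fold-change threshold, strict (default
#'   2).
#' @return data.frame of candidates (gene, chrom, bp, d, qvalue,
#'   fold_change signed by direction), sorted by position.
#' @export
filter_candidates <- function(sam, exprs, genes, groups,
                              min_expression_percentile = 25,
                              chromosome = "10", bp_window = NULL,
                              min_fold_change = 2) {
  if (min_expression_percentile < 0 || min_expression_percentile >= 100)
    stopf("min_expression_percentile must lie in [0, 100)")
  if (min_fold_change <= 1) stopf("min_fold_change must exceed 1")
  groups <- as.character(groups)
  lv <- unique(groups)
  gene_mean <- rowMeans(exprs)
  abund_cut <- stats::quantile(gene_mean, min_expression_percentile / 100,
                               names = FALSE)
  m1 <- rowMeans(exprs[, groups == lv[1L], drop = FALSE])
  m2 <- rowMeans(exprs[, groups == lv[2L], drop = FALSE])
  ratio <- 2^m2 / 2^m1                      # anti-logged group-mean ratio
  fold <- pmax(ratio, 1 / ratio)

  ann <- genes[match(rownames(exprs), genes$gene), , drop = FALSE]
  keep <- rownames(exprs) %in% sam$significant &
    gene_mean >= abund_cut &
    fold > min_fold_change
  if (!is.null(chromosome))
    keep <- keep & ann$chrom == as.character(chromosome)
  if (!is.null(bp_window))
    keep <- keep & ann$bp >= bp_window[1L] & ann$bp <= bp_window[2L]
  keep[is.na(keep)] <- FALSE

  out <- data.frame(gene = rownames(exprs)[keep],
                    chrom = ann$chrom[keep], bp = ann$bp[keep],
                    d = sam$d[keep], qvalue = sam$qvalue[keep],
                    fold_change = ifelse(ratio[keep] >= 1, fold[keep],
                                         -fold[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(chrom_rank(out$chrom), out$bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidates inside a genomic interval
#'
#' @param candidates a \code{\link{filter_candidates}} table (or any
#'   data.frame with a \code{bp} column).
#' @param start_bp,end_bp closed interval bounds.
#' @return the subset of rows whose position lies inside the interval.
#' @export
genes_in_region <- function(candidates, start_bp, end_bp) {
  keep <- candidates$bp >= start_bp & candidates$bp <= end_bp
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
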