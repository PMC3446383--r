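# Contingency-table association tests linking AI status to sample groups
# and clinical factors.

check_table <- function(tab) {
  if (!is.matrix(tab)) tab <- as.matrix(tab)
  if (any(is.na(tab)) || any(tab < 0) ||
      any(abs(tab - round(tab)) > 1e-8))
    stopf("contingency table must hold non-negative integer counts")
  storage.mode(tab) <- "double"
  tab
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, the p-value is the sum of hypergeometric
#' probabilities of every table whose point probability does not exceed
#' that of the observed table (within relative tolerance 1e-7, guarding
#' against floating-point ties). Degenerate margins give p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_table(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("table must be 2x2")
  stats::fisher.test(tab)$p.value
}

#' Pearson chi-squared test of independence
#'
#' Pearson statistic \code{sum((O - E)^2 / E)} with
#' \code{df = (R - 1)(C - 1)}; Yates continuity correction available for
#' 2x2 tables. All-zero rows or columns are dropped with a warning before
#' testing.
#'
#' @param tab R x C matrix of non-negative integer counts.
#' @param continuity_correction apply the Yates correction (2x2 only,
#'   default FALSE).
#' @return list with \code{statistic}, \code{df} and \code{p.value}.
#' @export
chi_square_independence <- function(tab, continuity_correction = FALSE) {
  tab <- check_table(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero row(s)/column(s) before the chi-squared test")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stopf("table degenerates to fewer than 2x2 after dropping zero margins")
  res <- suppressWarnings(
    stats::chisq.test(tab, correct = continuity_correction))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}

#' Build AI-by-group contingency tables
#'
#' For each requested two-group comparison, counts AI carriers versus
#' non-carriers; noninformative samples are excluded. An optional
#' stratifier (e.g. HER2 status) instead crosses AI status with the
#' stratifier levels within one group set.
#'
#' @param status per-sample AI status in
#'   \{"AI", "normal", "noninformative"\}.
#' @param groups group label per sample.
#' @param comparisons list of length-2 character vectors of group labels
#'   to compare; default every other group against the first.
#' @return named list of 2x2 matrices (rows AI/normal, columns the two
#'   groups); comparisons with an empty arm are skipped with a warning.
#' @export
build_tables <- function(status, groups,
                         comparisons = NULL) {
  stopifnot(length(status) == length(groups))
  groups <- as.character(groups)
  lv <- unique(groups)
  if (is.null(comparisons))
    comparisons <- lapply(lv[-1L], function(g) c(lv[1L], g))
  informative <- status != "noninformative"
  out <- list()
  for (cmp in comparisons) {
    stopifnot(length(cmp) == 2L)
    tabs <- lapply(cmp, function(g) {
      in_g <- informative & groups == g
      c(AI = sum(status[in_g] == "AI"),
        normal = sum(status[in_g] == "normal"))
    })
    tab <- cbind(tabs[[1L]], tabs[[2L]])
    colnames(tab) <- cmp
    if (any(colSums(tab) == 0)) {
      warning("comparison ", paste(cmp, collapse = " vs "),
              " has an empty arm; skipped")
      next
    }
    out[[paste(cmp, collapse = "_vs_")]] <- t(tab)
  }
  out
}
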