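# Cohort comparison: per-probe aberration frequencies per group, per-probe
# Wilcoxon rank-sum tests on segmented values, Benjamini-Hochberg FDR, and
# aggregation of significant probes into reportable genomic regions.

#' Per-probe gain/loss frequencies by group
#'
#' @param calls probes x samples character matrix of copy-number calls
#'   (\code{\link{call_cgh_cohort}}); gains and high-level amplifications
#'   both count as gained. Missing calls are excluded from the denominator.
#' @param groups group label per sample (length = ncol(calls)).
#' @return a \code{frequency_track}: list of per-group data.frames with
#'   columns \code{gain_pct}, \code{loss_pct} (0-100, one row per probe).
#' @export
aberration_frequencies <- function(calls, groups) {
  stopifnot(is.matrix(calls), ncol(calls) == length(groups))
  groups <- as.character(groups)
  out <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (!length(cols)) stopf("group '%s' has no samples", g)
    sub <- calls[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    if (any(n_obs == 0))
      warning("some probes have no non-missing calls in group ", g)
    gain <- rowSums(sub == "gain" | sub == "high-amp", na.rm = TRUE)
    loss <- rowSums(sub == "loss", na.rm = TRUE)
    out[[g]] <- data.frame(gain_pct = 100 * gain / pmax(n_obs, 1L),
                           loss_pct = 100 * loss / pmax(n_obs, 1L))
  }
  structure(out, class = "frequency_track")
}

#' Per-probe two-group Wilcoxon rank-sum tests
#'
#' Tests each probe's segmented log2 values between two sample groups with
#' the two-sided Wilcoxon rank-sum test: the exact distribution when the
#' combined sample size is at most \code{exact_max} and there are no ties,
#' the normal approximation with tie correction otherwise. A probe at
#' which both groups are constant and equal gets p = 1.
#'
#' @param values_a,values_b probes x samples matrices of segmented log2
#'   values for the two groups (same probes, aligned rows).
#' @param exact_max largest combined sample size for the exact
#'   distribution (default 20).
#' @return numeric vector of two-sided p-values, one per probe.
#' @export
per_probe_test <- function(values_a, values_b, exact_max = 20L) {
  stopifnot(is.matrix(values_a), is.matrix(values_b),
            nrow(values_a) == nrow(values_b))
  if (ncol(values_a) < 2L || ncol(values_b) < 2L)
    stopf("need at least 2 samples per group")
  vapply(seq_len(nrow(values_a)), function(i) {
    a <- values_a[i, ]; b <- values_b[i, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    if (length(unique(c(a, b))) == 1L) return(1)
    use_exact <- (length(a) + length(b)) <= exact_max &&
      !any(duplicated(c(a, b)))
    suppressWarnings(
      stats::wilcox.test(a, b, exact = use_exact,
                         correct = FALSE)$p.value)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: each p-value becomes
#' \code{min over j >= rank of p_(j) * m / j}, capped at 1.
#'
#' @param p p-values in [0, 1] (NA allowed, passed through).
#' @return adjusted values in the original order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Region size in Mbp
#'
#' \code{(end_bp - start_bp) / 1e6}, rounded half-up to one decimal, the
#' convention of printed region tables.
#'
#' @param start_bp,end_bp 1-based positions, start strictly smaller.
#' @return size in Mbp with one decimal.
#' @export
region_span <- function(start_bp, end_bp) {
  if (any(!(start_bp < end_bp))) stopf("start_bp must be < end_bp")
  round_half_up((end_bp - start_bp) / 1e6, 1)
}

# Merge a logical probe mask into maximal per-chromosome runs and summarize
# attached statistics over each run's probes.
mask_to_regions <- function(mask, panel, stats_df, groups_freq = NULL) {
  regions <- list()
  for (ch in unique(panel$chrom)) {
    rows <- which(panel$chrom == ch)
    runs <- true_runs(mask[rows])
    for (i in seq_len(nrow(runs))) {
      idx <- rows[runs$start[i]:runs$end[i]]
      start_bp <- panel$bp[idx[1L]]
      end_bp <- panel$bp[idx[length(idx)]]
      row <- data.frame(chrom = ch, start_idx = idx[1L],
                        end_idx = idx[length(idx)],
                        start_bp = start_bp, end_bp = end_bp,
                        n_probes = length(idx),
                        size_mbp = if (start_bp < end_bp)
                          region_span(start_bp, end_bp) else 0,
                        stringsAsFactors = FALSE)
      if (!is.null(groups_freq)) {
        for (g in names(groups_freq)) {
          fr <- groups_freq[[g]]
          row[[paste0(g, "_loss_min")]] <- round_half_up(min(fr$loss_pct[idx]), 1)
          row[[paste0(g, "_loss_max")]] <- round_half_up(max(fr$loss_pct[idx]), 1)
          row[[paste0(g, "_gain_min")]] <- round_half_up(min(fr$gain_pct[idx]), 1)
          row[[paste0(g, "_gain_max")]] <- round_half_up(max(fr$gain_pct[idx]), 1)
        }
      }
      if (!is.null(stats_df)) {
        for (s in names(stats_df)) {
          row[[paste0(s, "_min")]] <- min(stats_df[[s]][idx])
          row[[paste0(s, "_max")]] <- max(stats_df[[s]][idx])
        }
      }
      regions[[length(regions) + 1L]] <- row
    }
  }
  if (!length(regions)) return(NULL)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Aggregate significant probes into reportable regions
#'
#' Maximal runs of consecutive probes on one chromosome with
#' \code{p < p_max} and \code{fdr < fdr_max} become one region. Each
#' region reports its coordinates, size in Mbp, the min-max range of each
#' group's gain/loss frequencies over its probes, and the p/FDR ranges --
#' the layout of a printed "significantly different regions" table.
#'
#' @param track a \code{\link{aberration_frequencies}} result.
#' @param p,fdr per-probe p-values and adjusted values aligned to the
#'   panel.
#' @param panel the shared \code{\link{probe_panel}}.
#' @param p_max,fdr_max significance cutoffs (defaults 0.05 and 0.04).
#' @return data.frame of regions (possibly 0 rows).
#' @export
significant_regions <- function(track, p, fdr, panel, p_max = 0.05,
                                fdr_max = 0.04) {
  stopifnot(length(p) == nrow(panel), length(fdr) == nrow(panel))
  mask <- !is.na(p) & !is.na(fdr) & p < p_max & fdr < fdr_max
  out <- mask_to_regions(mask, panel, data.frame(p = p, fdr = fdr), track)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start_idx = integer(0),
                      end_idx = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_probes = integer(0),
                      size_mbp = numeric(0))
  }
  out
}

#' Loci with a large between-group frequency difference
#'
#' Finds, separately for gains and losses, maximal contiguous probe runs
#' where the two groups' aberration frequencies differ by more than
#' \code{min_diff_pct} percentage points.
#'
#' @param track_a,track_b single-group frequency data.frames (elements of
#'   a \code{\link{aberration_frequencies}} track).
#' @param panel the shared \code{\link{probe_panel}}.
#' @param min_diff_pct difference threshold in percentage points
#'   (default 30).
#' @return data.frame of loci with a \code{direction} column
#'   (\code{"gain"} or \code{"loss"}); 0 rows if none.
#' @export
high_freq_difference_loci <- function(track_a, track_b, panel,
                                      min_diff_pct = 30) {
  stopifnot(nrow(track_a) == nrow(panel), nrow(track_b) == nrow(panel))
  out <- list()
  for (dir in c("gain", "loss")) {
    col <- paste0(dir, "_pct")
    diff <- abs(track_a[[col]] - track_b[[col]])
    regions <- mask_to_regions(diff > min_diff_pct, panel,
                               data.frame(freq_diff = diff))
    if (!is.null(regions)) {
      regions$direction <- dir
      out[[dir]] <- regions
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), direction = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two cohorts probe by probe
#'
#' Convenience wrapper running the full comparison: group frequencies,
#' per-probe Wilcoxon tests on segment means, BH adjustment, and region
#' aggregation.
#'
#' @param segmean probes x samples matrix of assigned segment means.
#' @param calls probes x samples call matrix.
#' @param groups group label per sample; exactly two distinct labels.
#' @param panel the shared \code{\link{probe_panel}}.
#' @param p_max,fdr_max region significance cutoffs.
#' @return list with \code{track}, \code{p}, \code{fdr} and
#'   \code{regions}.
#' @export
compare_cohorts <- function(segmean, calls, groups, panel, p_max = 0.05,
                            fdr_max = 0.04) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stopf("need exactly two groups, got %d", length(lv))
  track <- aberration_frequencies(calls, groups)
  p <- per_probe_test(segmean[, groups == lv[1L], drop = FALSE],
                      segmean[, groups == lv[2L], drop = FALSE])
  fdr <- bh_fdr(p)
  regions <- significant_regions(track, p, fdr, panel, p_max, fdr_max)
  list(track = track, p = p, fdr = fdr, regions = regions)
}
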