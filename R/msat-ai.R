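# Allelic-imbalance calling from microsatellite peak heights, per-sample
# region status, core-region hotspot detection and group frequency tables.

#' Classify one marker from tumor/normal allele peak heights
#'
#' For a heterozygous normal (two constitutive alleles) the allelic ratio
#' of the tumor, normalized by the constitutive ratio, is folded to be at
#' least 1: \code{fold = max(r, 1/r)} with
#' \code{r = (t1/t2) / (n1/n2)}. A fold of \code{ai_cut} (default 2.0) or
#' higher is scored as allelic imbalance, below as retained. A homozygous
#' normal (single allele) is noninformative; absent tumor data is missing.
#' A heterozygous normal whose tumor retains only one allele is complete
#' loss: AI with infinite fold.
#'
#' Setting \code{normalized = FALSE} uses the raw tumor allele ratio
#' \code{t1/t2} without dividing by the constitutive ratio (sensitivity
#' analysis; constitutive peak-height skew then leaks into the call).
#'
#' @param n1,n2 normal allele peak heights (\code{n2 = NA} if homozygous).
#' @param t1,t2 tumor allele peak heights (NA if an allele is absent).
#' @param ai_cut fold threshold scored as AI, boundary inclusive.
#' @param normalized divide by the constitutive allele ratio (default).
#' @return list with \code{verdict} in
#'   \{"AI", "retained", "noninformative", "missing"\} and \code{fold}
#'   (>= 1, NA when undefined, Inf for complete loss).
#' @export
classify_marker <- function(n1, n2 = NA, t1 = NA, t2 = NA, ai_cut = 2.0,
                            normalized = TRUE) {
  present <- function(h) !is.na(h)
  for (h in c(n1, n2, t1, t2))
    if (present(h) && h <= 0) stopf("peak heights must be positive")
  if (!present(n1) && !present(n2)) stopf("no normal allele peaks present")
  if (!present(n1)) { n1 <- n2; n2 <- NA }   # single constitutive allele
  if (!present(n2))
    return(list(verdict = "noninformative", fold = NA_real_))
  if (!present(t1) && !present(t2))
    return(list(verdict = "missing", fold = NA_real_))
  if (xor(present(t1), present(t2)))
    return(list(verdict = "AI", fold = Inf))  # complete loss of one allele
  r <- if (normalized) (t1 / t2) / (n1 / n2) else t1 / t2
  fold <- max(r, 1 / r)
  list(verdict = if (fold >= ai_cut) "AI" else "retained", fold = fold)
}

#' Classify a whole peak table
#'
#' Vectorized \code{\link{classify_marker}} over a peak-height table as
#' emitted by \code{\link{generate_msat_cohort}} (columns sample, marker,
#' n_allele1, n_allele2, t_allele1, t_allele2). Records with a nonpositive
#' peak height are rejected with an informative error.
#'
#' @param peaks the peak table.
#' @param ai_cut,normalized as in \code{\link{classify_marker}}.
#' @return the peak table with added \code{verdict} and \code{fold}
#'   columns.
#' @export
classify_peak_table <- function(peaks, ai_cut = 2.0, normalized = TRUE) {
  need <- c("sample", "marker", "n_allele1", "n_allele2", "t_allele1",
            "t_allele2")
  missing_cols <- setdiff(need, names(peaks))
  if (length(missing_cols))
    stopf("peak table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  heights <- as.matrix(peaks[, need[3:6]])
  bad <- rowSums(!is.na(heights) & heights <= 0) > 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with nonpositive peak heights rejected")
    peaks <- peaks[!bad, , drop = FALSE]
  }
  res <- lapply(seq_len(nrow(peaks)), function(i)
    classify_marker(peaks$n_allele1[i], peaks$n_allele2[i],
                    peaks$t_allele1[i], peaks$t_allele2[i],
                    ai_cut = ai_cut, normalized = normalized))
  peaks$verdict <- vapply(res, `[[`, character(1), "verdict")
  peaks$fold <- vapply(res, `[[`, numeric(1), "fold")
  peaks
}

#' Turn a classified peak table into a sample x marker call matrix
#'
#' @param classified result of \code{\link{classify_peak_table}}.
#' @param markers optional marker annotation fixing the column order.
#' @return character matrix (samples x markers) of verdicts.
#' @export
call_matrix <- function(classified, markers = NULL) {
  marker_levels <- if (!is.null(markers)) markers$marker else
    unique(classified$marker)
  sample_levels <- unique(classified$sample)
  m <- matrix(NA_character_, length(sample_levels), length(marker_levels),
              dimnames = list(sample_levels, marker_levels))
  m[cbind(match(classified$sample, sample_levels),
          match(classified$marker, marker_levels))] <- classified$verdict
  m
}

#' Per-sample region status over a marker set
#'
#' A sample is an AI carrier if any informative marker shows AI; normal if
#' it has informative markers and none shows AI; noninformative if no
#' marker is informative.
#'
#' @param verdicts character vector of marker verdicts for one sample.
#' @return one of \code{"AI"}, \code{"normal"}, \code{"noninformative"}.
#' @export
sample_region_status <- function(verdicts) {
  if (!length(verdicts)) stopf("need at least one marker call")
  informative <- verdicts %in% c("AI", "retained")
  if (!any(informative)) return("noninformative")
  if (any(verdicts == "AI")) "AI" else "normal"
}

#' Per-marker AI frequency over informative samples
#'
#' @param calls sample x marker verdict matrix
#'   (\code{\link{call_matrix}}).
#' @return numeric vector: AI / (AI + retained) per marker; NA where no
#'   sample is informative.
#' @export
marker_ai_frequency <- function(calls) {
  ai <- colSums(calls == "AI", na.rm = TRUE)
  ret <- colSums(calls == "retained", na.rm = TRUE)
  ifelse(ai + ret > 0, ai / (ai + ret), NA_real_)
}

#' Detect AI core regions along a marker panel
#'
#' Computes the per-marker AI frequency over informative samples, then
#' reports maximal contiguous marker runs whose frequencies all reach
#' \code{min_freq} and that stand out as local maxima: every flanking
#' marker (the nearest marker outside the run on each existing side) must
#' lie at least \code{min_prominence} below the run's peak frequency. A
#' run covering the whole panel has no flank and is not a local hotspot.
#'
#' @param calls sample x marker verdict matrix, columns in panel order.
#' @param markers marker annotation (marker, chrom, bp) in column order.
#' @param min_freq minimum AI frequency inside a core region (default
#'   0.3).
#' @param min_prominence required drop to the flanking markers (default
#'   0.15).
#' @return data.frame of core regions (first_marker, last_marker,
#'   start_bp, end_bp, n_markers, peak_freq); 0 rows if none qualify.
#' @export
core_regions <- function(calls, markers, min_freq = 0.3,
                         min_prominence = 0.15) {
  if (nrow(markers) < 2L) stopf("need at least two markers")
  stopifnot(ncol(calls) == nrow(markers))
  freq <- marker_ai_frequency(calls)
  freq_cmp <- ifelse(is.na(freq), -Inf, freq)
  runs <- true_runs(freq_cmp >= min_freq)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    peak <- max(freq_cmp[a:b])
    flanks <- c(if (a > 1L) freq_cmp[a - 1L],
                if (b < nrow(markers)) freq_cmp[b + 1L])
    if (!length(flanks)) next  # spans the whole panel: not a local maximum
    if (all(peak - flanks >= min_prominence)) {
      out[[length(out) + 1L]] <- data.frame(
        first_marker = markers$marker[a], last_marker = markers$marker[b],
        start_bp = markers$bp[a], end_bp = markers$bp[b],
        n_markers = b - a + 1L, peak_freq = peak,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(first_marker = character(0),
                      last_marker = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_markers = integer(0),
                      peak_freq = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group frequency table for a region status
#'
#' Counts AI carriers per sample group and reports percentages rounded
#' half-up to one decimal (printed-table convention). The percentage
#' denominator is the full group size, matching clinical frequency
#' tables in which noninformative samples count as non-carriers of the
#' observation.
#'
#' @param status character vector of per-sample statuses
#'   (\code{\link{sample_region_status}}).
#' @param groups group label per sample.
#' @param region label for the summarized region.
#' @return data.frame with one row per group: region, group, n_ai, n,
#'   pct.
#' @export
group_frequency_table <- function(status, groups, region = "region") {
  stopifnot(length(status) == length(groups))
  groups <- as.character(groups)
  out <- lapply(unique(groups), function(g) {
    in_g <- groups == g
    n <- sum(in_g)
    if (n == 0L) stopf("group '%s' is empty", g)
    n_ai <- sum(status[in_g] == "AI")
    data.frame(region = region, group = g, n_ai = n_ai, n = n,
               pct = round_half_up(100 * n_ai / n, 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample status restricted to the markers of a core region
#'
#' @param calls sample x marker verdict matrix.
#' @param markers marker annotation in column order.
#' @param region one row of a \code{\link{core_regions}} result (or any
#'   list with \code{start_bp}, \code{end_bp}).
#' @return character vector of statuses, one per sample.
#' @export
region_status_per_sample <- function(calls, markers, region) {
  idx <- which(markers$bp >= region$start_bp & markers$bp <= region$end_bp)
  if (!length(idx)) stopf("no markers inside the region")
  apply(calls[, idx, drop = FALSE], 1L, sample_region_status)
}
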