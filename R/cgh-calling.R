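# Array-CGH copy-number calling: median centering, piecewise-constant
# segmentation, variance-calibrated thresholds, two-pass recentering on
# normal segments, and sex-chromosome exclusion.

#' Gain/loss/amplification thresholds
#'
#' @param gain_cut log2 value above which a segment mean is a gain
#'   (strictly greater).
#' @param loss_cut log2 value below which a segment mean is a loss
#'   (strictly smaller).
#' @param amp_cut log2 value at or above which a segment is a high-level
#'   amplification.
#' @return a \code{cgh_thresholds} list.
#' @export
cgh_thresholds <- function(gain_cut = 0.05, loss_cut = -gain_cut,
                           amp_cut = 1.0) {
  if (!(loss_cut < 0 && 0 < gain_cut && gain_cut < amp_cut))
    stopf("thresholds must satisfy loss_cut < 0 < gain_cut < amp_cut")
  structure(list(gain_cut = gain_cut, loss_cut = loss_cut,
                 amp_cut = amp_cut),
            class = "cgh_thresholds")
}

#' Derive calling thresholds from sex-mismatch reference profiles
#'
#' In a sex-mismatched hybridization the X and Y probes of a reference
#' profile sit at a known copy-number offset; their residual spread is pure
#' technical noise at a true single-copy difference and therefore
#' calibrates the gain/loss cutoffs. Each X/Y vector is centered at its
#' median (removing the mismatch offset) and the pooled residual SD is
#' multiplied by \code{k}.
#'
#' With no reference (\code{reference = NULL}) the conventional fixed
#' +/-0.05 log2 cutoffs are returned.
#'
#' @param reference either \code{NULL}, a list of numeric vectors (X/Y
#'   log2 ratios, one vector per chromosome per reference sample), or the
#'   result of \code{\link{generate_sex_mismatch_reference}}.
#' @param k multiplier mapping the residual SD to the cutoff.
#' @param amp_cut high-level amplification cutoff (log2).
#' @return a \code{\link{cgh_thresholds}}.
#' @export
derive_thresholds <- function(reference = NULL, k = 2, amp_cut = 1.0) {
  if (k <= 0) stopf("k must be positive")
  if (is.null(reference)) return(cgh_thresholds(0.05, -0.05, amp_cut))
  if (is.list(reference) && !is.null(reference$log2) &&
      !is.null(reference$panel)) {
    panel <- reference$panel
    vecs <- list()
    for (ch in c("X", "Y")) {
      rows <- panel$chrom == ch
      if (!any(rows)) next
      for (j in seq_len(ncol(reference$log2)))
        vecs[[length(vecs) + 1L]] <- reference$log2[rows, j]
    }
    reference <- vecs
  }
  if (!is.list(reference)) reference <- list(reference)
  if (!length(reference) || !sum(lengths(reference)))
    stopf("empty X/Y reference vectors")
  resid <- unlist(lapply(reference, function(v) {
    v <- v[!is.na(v)]
    v - stats::median(v)
  }))
  s <- stats::sd(resid)
  if (!is.finite(s) || s == 0)
    stopf("X/Y reference variance is zero; cannot calibrate thresholds")
  cgh_thresholds(k * s, -k * s, amp_cut)
}

#' Center a log2-ratio profile at median zero
#'
#' @param x numeric log2 ratios (NA = missing probe).
#' @return the centered vector (median of non-missing values exactly 0).
#' @export
median_center <- function(x) {
  if (all(is.na(x))) stopf("profile has no non-missing values")
  x - stats::median(x, na.rm = TRUE)
}

# ---------------------------------------------------------------------------
# Piecewise-constant segmentation by recursive binary splitting.
#
# Within one chromosome, the split maximizing the drop in within-segment sum
# of squares is applied recursively; a split is kept only if the drop
# exceeds a penalty (default 4 * sigma^2 * log(n), sigma estimated robustly
# from first differences), and no segment may be shorter than
# min_seg_probes. This meets the piecewise-means contract that downstream
# calling requires; the specific changepoint engine is interchangeable.

rss_fun <- function(cs, cs2) {
  # RSS of x[a..b] from prefix sums (cs, cs2 have a leading 0)
  function(a, b) {
    n <- b - a + 1
    s <- cs[b + 1] - cs[a]
    (cs2[b + 1] - cs2[a]) - s * s / n
  }
}

best_split <- function(a, b, cs, cs2, min_len) {
  # returns c(k, gain): best split with both parts >= min_len, or NULL
  lo <- a + min_len - 1L
  hi <- b - min_len
  if (hi < lo) return(NULL)
  ks <- lo:hi
  n1 <- ks - a + 1
  n2 <- b - ks
  s1 <- cs[ks + 1] - cs[a]
  stot <- cs[b + 1] - cs[a]
  s2 <- stot - s1
  fit <- s1 * s1 / n1 + s2 * s2 / n2
  k <- ks[which.max(fit)]
  whole <- stot * stot / (b - a + 1)
  c(k, max(fit) - whole)
}

segment_values <- function(x, min_len, penalty) {
  n <- length(x)
  if (n < 2L * min_len) return(data.frame(start = 1L, end = n))
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  bounds <- list()
  recurse <- function(a, b) {
    sp <- best_split(a, b, cs, cs2, min_len)
    if (is.null(sp) || sp[2] <= penalty) {
      bounds[[length(bounds) + 1L]] <<- c(a, b)
      return(invisible())
    }
    recurse(a, sp[1])
    recurse(sp[1] + 1L, b)
  }
  recurse(1L, n)
  m <- do.call(rbind, bounds)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

#' Segment a log2-ratio profile into piecewise-constant regions
#'
#' Fits, per chromosome, a piecewise-constant mean to the non-missing
#' probes by recursive binary splitting with a penalized stopping rule.
#' Every probe inside a segment is assigned the arithmetic mean of the
#' segment's member probes.
#'
#' @param x numeric log2 ratios aligned to \code{panel} (NA = missing).
#' @param panel a \code{\link{probe_panel}}.
#' @param min_seg_probes minimum probes per segment (default 5). A
#'   chromosome with fewer non-missing probes than twice this becomes a
#'   single segment.
#' @param penalty sum-of-squares drop required to accept a split;
#'   \code{NULL} (default) uses \code{4 * sigma^2 * log(n)} per chromosome
#'   with sigma estimated as \code{mad(diff(x))/sqrt(2)}.
#' @return a \code{segmented_profile}: list with \code{segments}
#'   (data.frame chrom, start_idx, end_idx, start_bp, end_bp, n_probes,
#'   mean) and \code{probe_mean} (per-probe assigned mean, NA where the
#'   probe is missing).
#' @export
segment_profile <- function(x, panel, min_seg_probes = 5L, penalty = NULL) {
  stopifnot(inherits(panel, "probe_panel"), length(x) == nrow(panel))
  probe_mean <- rep(NA_real_, length(x))
  seg_rows <- list()
  for (ch in unique(panel$chrom)) {
    rows <- which(panel$chrom == ch)
    obs <- rows[!is.na(x[rows])]
    if (!length(obs)) next
    v <- x[obs]
    pen <- penalty
    if (is.null(pen)) {
      sigma <- if (length(v) > 1L)
        stats::mad(diff(v)) / sqrt(2) else 0
      pen <- 4 * sigma^2 * log(length(v)) + 1e-10
    }
    segs <- segment_values(v, as.integer(min_seg_probes), pen)
    for (i in seq_len(nrow(segs))) {
      idx <- obs[segs$start[i]:segs$end[i]]
      m <- mean(x[idx])
      probe_mean[idx] <- m
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        chrom = ch, start_idx = idx[1L], end_idx = idx[length(idx)],
        start_bp = panel$bp[idx[1L]], end_bp = panel$bp[idx[length(idx)]],
        n_probes = length(idx), mean = m, stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(chrom = character(0), start_idx = integer(0),
               end_idx = integer(0), start_bp = numeric(0),
               end_bp = numeric(0), n_probes = integer(0),
               mean = numeric(0))
  rownames(segments) <- NULL
  structure(list(segments = segments, probe_mean = probe_mean),
            class = "segmented_profile")
}

#' Call copy-number states from a segmented profile
#'
#' Segment means strictly above \code{gain_cut} are gains (at or above
#' \code{amp_cut}, high-level amplifications), strictly below
#' \code{loss_cut} losses; everything else, including means exactly at a
#' cutoff, is normal. Missing probes stay missing.
#'
#' @param seg a \code{\link{segment_profile}} result.
#' @param thr a \code{\link{cgh_thresholds}}.
#' @return list with \code{probe_call} (character vector in
#'   \{loss, normal, gain, high-amp\}, NA = missing) and \code{segments}
#'   (the segment table with a \code{call} column).
#' @export
call_states <- function(seg, thr) {
  stopifnot(inherits(seg, "segmented_profile"),
            inherits(thr, "cgh_thresholds"))
  classify <- function(m) {
    out <- rep("normal", length(m))
    out[m > thr$gain_cut] <- "gain"
    out[m >= thr$amp_cut] <- "high-amp"
    out[m < thr$loss_cut] <- "loss"
    out[is.na(m)] <- NA_character_
    out
  }
  segments <- seg$segments
  segments$call <- classify(segments$mean)
  list(probe_call = classify(seg$probe_mean), segments = segments)
}

#' Recenter on normal segments and re-segment
#'
#' Second pass of the two-pass calling procedure: the median of the raw
#' log2 ratios of probes lying in first-pass normal segments is subtracted
#' from the whole profile (so the baseline is estimated from apparently
#' unaberrated genome only), then segmentation and calling are repeated.
#' If the first pass produced no normal segment the profile is returned
#' unchanged with a warning.
#'
#' @param x the (already median-centered) log2 profile.
#' @param first_pass result of \code{\link{call_states}} on the first-pass
#'   segmentation.
#' @param panel,thr,min_seg_probes,penalty as in
#'   \code{\link{segment_profile}} / \code{\link{call_states}}.
#' @return list with \code{log2} (recentered profile), \code{seg},
#'   \code{calls}, and \code{recentered} (logical).
#' @export
recenter_and_resegment <- function(x, first_pass, panel, thr,
                                   min_seg_probes = 5L, penalty = NULL) {
  normal_probes <- which(first_pass$probe_call == "normal")
  if (!length(normal_probes)) {
    warning("no normal segments in first pass; recentering skipped")
    seg <- segment_profile(x, panel, min_seg_probes, penalty)
    return(list(log2 = x, seg = seg, calls = first_pass,
                recentered = FALSE))
  }
  x2 <- x - stats::median(x[normal_probes], na.rm = TRUE)
  seg2 <- segment_profile(x2, panel, min_seg_probes, penalty)
  list(log2 = x2, seg = seg2, calls = call_states(seg2, thr),
       recentered = TRUE)
}

#' Full two-pass copy-number calling for one profile
#'
#' Median centering, segmentation, threshold calling, then recentering on
#' normal segments and a second segmentation/calling pass.
#'
#' @param x raw log2 ratios aligned to \code{panel}.
#' @param panel a \code{\link{probe_panel}}.
#' @param thr a \code{\link{cgh_thresholds}} (default the fixed +/-0.05
#'   cutoffs).
#' @param min_seg_probes,penalty segmentation controls.
#' @param recenter run the second pass (default TRUE).
#' @return list with \code{log2}, \code{seg}, \code{calls},
#'   \code{first_pass} (first-pass calls) and \code{recentered}.
#' @export
call_cgh_profile <- function(x, panel, thr = cgh_thresholds(),
                             min_seg_probes = 5L, penalty = NULL,
                             recenter = TRUE) {
  x0 <- median_center(x)
  seg1 <- segment_profile(x0, panel, min_seg_probes, penalty)
  calls1 <- call_states(seg1, thr)
  if (!recenter)
    return(list(log2 = x0, seg = seg1, calls = calls1,
                first_pass = calls1, recentered = FALSE))
  second <- recenter_and_resegment(x0, calls1, panel, thr,
                                   min_seg_probes, penalty)
  list(log2 = second$log2, seg = second$seg, calls = second$calls,
       first_pass = calls1, recentered = second$recentered)
}

#' Two-pass copy-number calling for a cohort
#'
#' @param log2 probes x samples matrix of raw log2 ratios.
#' @param panel a \code{\link{probe_panel}} matching the rows.
#' @param thr,min_seg_probes,penalty,recenter as in
#'   \code{\link{call_cgh_profile}}.
#' @return list with \code{calls} (probes x samples character matrix),
#'   \code{segmean} (probes x samples matrix of assigned segment means)
#'   and \code{profiles} (per-sample \code{\link{call_cgh_profile}}
#'   results).
#' @export
call_cgh_cohort <- function(log2, panel, thr = cgh_thresholds(),
                            min_seg_probes = 5L, penalty = NULL,
                            recenter = TRUE) {
  stopifnot(is.matrix(log2), nrow(log2) == nrow(panel))
  profiles <- lapply(seq_len(ncol(log2)), function(j)
    call_cgh_profile(log2[, j], panel, thr, min_seg_probes, penalty,
                     recenter))
  names(profiles) <- colnames(log2)
  calls <- vapply(profiles, function(p) p$calls$probe_call,
                  character(nrow(panel)))
  segmean <- vapply(profiles, function(p) p$seg$probe_mean,
                    numeric(nrow(panel)))
  dimnames(calls) <- dimnames(segmean) <- dimnames(log2)
  list(calls = calls, segmean = segmean, profiles = profiles)
}

#' Drop X and Y probes before downstream analysis
#'
#' Sex-mismatched hybridizations make the sex chromosomes uninterpretable
#' for tumor copy number, so they are excluded from all cohort statistics.
#'
#' @param panel a \code{\link{probe_panel}}.
#' @param profiles optional probes x samples matrix aligned to the panel.
#' @return list with the filtered \code{panel} and (if given)
#'   \code{profiles}; autosomal order is preserved.
#' @export
exclude_sex_chromosomes <- function(panel, profiles = NULL) {
  keep <- is_autosome(panel$chrom)
  out_panel <- panel[keep, , drop = FALSE]
  rownames(out_panel) <- NULL
  class(out_panel) <- c("probe_panel", "data.frame")
  out <- list(panel = out_panel)
  if (!is.null(profiles)) {
    stopifnot(nrow(profiles) == length(keep))
    out$profiles <- profiles[keep, , drop = FALSE]
  }
  out
}
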