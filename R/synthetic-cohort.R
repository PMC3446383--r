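# Synthetic cohort generators with planted ground truth.
#
# These emulate the statistical structure of a two-cohort tumor study
# profiled on genome-wide CGH arrays, a 10q microsatellite panel and
# two-group expression arrays: shared plus metastasis-enriched copy-number
# aberrations, allelic imbalance concentrated in core regions, and
# downregulated transcripts on 10q. Every generator returns the simulated
# data together with the planted truth, aligned index-for-index.

# ---------------------------------------------------------------------------
# Probe panels

# Approximate chromosome lengths in bp (GRCh37 scale), used to lay out
# synthetic probe grids.
CHROM_LENGTHS <- c(
  "1" = 249e6, "2" = 243e6, "3" = 198e6, "4" = 191e6, "5" = 181e6,
  "6" = 171e6, "7" = 159e6, "8" = 146e6, "9" = 141e6, "10" = 135e6,
  "11" = 135e6, "12" = 134e6, "13" = 115e6, "14" = 107e6, "15" = 103e6,
  "16" = 90e6, "17" = 81e6, "18" = 78e6, "19" = 59e6, "20" = 63e6,
  "21" = 48e6, "22" = 51e6, "X" = 155e6, "Y" = 59e6
)

#' Construct a probe panel
#'
#' An ordered probe annotation shared by all samples of an array-CGH cohort:
#' probe identifier, chromosome and 1-based bp position, sorted by
#' (chromosome, position).
#'
#' @param probe character vector of unique probe ids.
#' @param chrom chromosome labels in \code{1..22, X, Y} (a leading "chr"
#'   prefix is tolerated and stripped).
#' @param bp 1-based genomic positions.
#' @return a \code{probe_panel} data.frame with columns probe, chrom, bp.
#' @export
probe_panel <- function(probe, chrom, bp) {
  if (length(probe) == 0L) stopf("probe panel must contain at least one probe")
  if (anyDuplicated(probe)) stopf("probe ids must be unique")
  chrom <- sub("^chr", "", as.character(chrom))
  bad <- !chrom %in% names(CHROM_LENGTHS)
  if (any(bad)) stopf("unknown chromosome label(s): %s",
                      paste(unique(chrom[bad]), collapse = ", "))
  bp <- as.numeric(bp)
  if (any(!is.finite(bp)) || any(bp < 1)) stopf("bp positions must be >= 1")
  panel <- data.frame(probe = as.character(probe), chrom = chrom, bp = bp,
                      stringsAsFactors = FALSE)
  panel <- panel[order(chrom_rank(panel$chrom), panel$bp), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("probe_panel", "data.frame")
  panel
}

#' Evenly spaced synthetic probe panel
#'
#' Distributes \code{n_probes} over the requested chromosomes proportionally
#' to chromosome length, with even spacing within each chromosome.
#'
#' @param n_probes total number of probes.
#' @param chroms chromosomes to cover (default autosomes 1-22).
#' @param include_xy also add X and Y probes (needed for sex-mismatch
#'   reference simulations).
#' @return a \code{probe_panel}.
#' @export
default_probe_panel <- function(n_probes = 2000, chroms = as.character(1:22),
                                include_xy = FALSE) {
  if (include_xy) chroms <- unique(c(chroms, "X", "Y"))
  lens <- CHROM_LENGTHS[chroms]
  counts <- round(n_probes * lens / sum(lens))
  counts[counts < 1] <- 1
  probe <- character(0); chrom <- character(0); bp <- numeric(0)
  for (ch in chroms) {
    k <- counts[[ch]]
    pos <- round(seq(1e5, lens[[ch]] - 1e5, length.out = k))
    chrom <- c(chrom, rep(ch, k))
    bp <- c(bp, pos)
    probe <- c(probe, sprintf("P_%s_%06d", ch, seq_len(k)))
  }
  probe_panel(probe, chrom, bp)
}

# ---------------------------------------------------------------------------
# Array-CGH cohort

#' Specify a planted copy-number aberration
#'
#' @param chrom chromosome label.
#' @param start_bp,end_bp 1-based inclusive interval carrying the aberration.
#' @param effect log2-ratio shift applied to carrier samples over covered
#'   probes (negative = loss, positive = gain).
#' @param prevalence named numeric vector: fraction of samples in each group
#'   that carry the aberration.
#' @return an \code{aberration_spec} list.
#' @export
aberration_spec <- function(chrom, start_bp, end_bp, effect, prevalence) {
  chrom <- sub("^chr", "", as.character(chrom))
  if (!chrom %in% names(CHROM_LENGTHS)) stopf("unknown chromosome: %s", chrom)
  if (!(start_bp < end_bp)) stopf("aberration start_bp must be < end_bp")
  if (is.null(names(prevalence)) || any(!nzchar(names(prevalence))))
    stopf("prevalence must be a named vector (one entry per group)")
  if (any(prevalence < 0 | prevalence > 1))
    stopf("prevalences must lie in [0, 1]")
  structure(list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 effect = effect, prevalence = prevalence),
            class = "aberration_spec")
}

#' Specify an array-CGH cohort simulation
#'
#' @param panel a \code{\link{probe_panel}}.
#' @param groups named integer vector of samples per group.
#' @param aberrations list of \code{\link{aberration_spec}} objects.
#' @param noise_sd per-probe Gaussian noise SD in log2 units (default 0.15,
#'   a typical oligo-array spread).
#' @param baseline_shift_sd SD of the per-sample baseline centering error
#'   in log2 units.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a \code{cgh_cohort_spec} list.
#' @export
cgh_cohort_spec <- function(panel, groups, aberrations = list(),
                            noise_sd = 0.15, baseline_shift_sd = 0.05,
                            seed = 1L) {
  stopifnot(inherits(panel, "probe_panel"))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stopf("groups must be a named vector of sample counts")
  groups <- stats::setNames(as.integer(groups), names(groups))
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  for (ab in aberrations) {
    stopifnot(inherits(ab, "aberration_spec"))
    missing_grp <- setdiff(names(ab$prevalence), names(groups))
    if (length(missing_grp))
      stopf("aberration prevalence names unknown group(s): %s",
            paste(missing_grp, collapse = ", "))
  }
  structure(list(panel = panel, groups = groups, aberrations = aberrations,
                 noise_sd = noise_sd, baseline_shift_sd = baseline_shift_sd,
                 seed = as.integer(seed)),
            class = "cgh_cohort_spec")
}

probes_in_interval <- function(panel, chrom, start_bp, end_bp) {
  which(panel$chrom == chrom & panel$bp >= start_bp & panel$bp <= end_bp)
}

#' Generate an array-CGH cohort with planted truth
#'
#' Each sample's log2 ratio is the sum of the effects of the aberrations it
#' carries over each covered probe, plus independent Gaussian noise and a
#' per-sample baseline shift (a centering error the calling pipeline must
#' remove). Carrier status is drawn per aberration from its group-specific
#' prevalence.
#'
#' @param spec a \code{\link{cgh_cohort_spec}}.
#' @return a list with elements \code{panel}, \code{log2} (probes x samples
#'   matrix), \code{samples} (data.frame sample, group), \code{truth_effect}
#'   (planted per-probe log2 shift), \code{truth_state} (planted per-probe
#'   state in \{loss, normal, gain\}), \code{carriers} (aberration x sample
#'   logical matrix) and \code{spec}.
#' @export
generate_acgh_cohort <- function(spec) {
  stopifnot(inherits(spec, "cgh_cohort_spec"))
  if (any(spec$groups <= 0L)) stopf("every group needs at least one sample")
  panel <- spec$panel
  set.seed(spec$seed)
  group <- rep(names(spec$groups), spec$groups)
  n <- length(group)
  sample_id <- sprintf("S%03d_%s", seq_len(n), group)
  p <- nrow(panel)

  truth_effect <- matrix(0, p, n, dimnames = list(panel$probe, sample_id))
  n_ab <- length(spec$aberrations)
  carriers <- matrix(FALSE, n_ab, n,
                     dimnames = list(NULL, sample_id))
  for (a in seq_len(n_ab)) {
    ab <- spec$aberrations[[a]]
    prev <- ab$prevalence[group]
    prev[is.na(prev)] <- 0
    carry <- stats::runif(n) < prev
    carriers[a, ] <- carry
    idx <- probes_in_interval(panel, ab$chrom, ab$start_bp, ab$end_bp)
    if (length(idx) && any(carry))
      truth_effect[idx, carry] <- truth_effect[idx, carry] + ab$effect
  }
  shift <- stats::rnorm(n, 0, spec$baseline_shift_sd)
  noise <- matrix(stats::rnorm(p * n, 0, spec$noise_sd), p, n)
  log2r <- truth_effect + noise + matrix(shift, p, n, byrow = TRUE)
  dimnames(log2r) <- dimnames(truth_effect)

  truth_state <- matrix("normal", p, n, dimnames = dimnames(truth_effect))
  truth_state[truth_effect < 0] <- "loss"
  truth_state[truth_effect > 0] <- "gain"

  list(panel = panel, log2 = log2r,
       samples = data.frame(sample = sample_id, group = group,
                            stringsAsFactors = FALSE),
       truth_effect = truth_effect, truth_state = truth_state,
       carriers = carriers, spec = spec)
}

#' Generate sex-mismatch reference profiles
#'
#' Emulates hybridizing tumor DNA against opposite-sex reference DNA: X and
#' Y probes carry a known copy-number offset while autosomes stay centered
#' at zero. The X/Y residual spread of these profiles calibrates the
#' gain/loss thresholds (\code{\link{derive_thresholds}}).
#'
#' @param spec a \code{\link{cgh_cohort_spec}} whose panel includes X and Y
#'   probes.
#' @param n_ref number of reference profiles.
#' @param mismatch_shift named vector of the expected log2 offsets, e.g.
#'   \code{c(X = 1, Y = -1)} for a female sample against male reference DNA.
#' @return list with \code{panel}, \code{log2} (probes x references),
#'   \code{mismatch_shift}.
#' @export
generate_sex_mismatch_reference <- function(spec, n_ref = 3L,
                                            mismatch_shift = c(X = 1, Y = -1)) {
  stopifnot(inherits(spec, "cgh_cohort_spec"))
  panel <- spec$panel
  if (!any(panel$chrom %in% c("X", "Y")))
    stopf("probe panel has no X/Y probes; cannot simulate a sex mismatch")
  set.seed(spec$seed + 104729L)  # offset stream, still seed-determined
  p <- nrow(panel)
  mu <- rep(0, p)
  for (ch in names(mismatch_shift)) mu[panel$chrom == ch] <- mismatch_shift[[ch]]
  log2r <- matrix(stats::rnorm(p * n_ref, 0, spec$noise_sd), p, n_ref) + mu
  dimnames(log2r) <- list(panel$probe, sprintf("REF%02d", seq_len(n_ref)))
  list(panel = panel, log2 = log2r, mismatch_shift = mismatch_shift)
}

# ---------------------------------------------------------------------------
# Microsatellite cohort

#' Specify a planted allelic-imbalance region
#'
#' @param chrom chromosome label.
#' @param start_bp,end_bp interval over which covered markers show AI.
#' @param loss_fraction fraction of tumor cells that lost one allele
#'   (tumor purity times clonal fraction); a vector means each carrier
#'   samples one value uniformly.
#' @param prevalence named fraction of carriers per group.
#' @return an \code{ai_region_spec} list.
#' @export
ai_region_spec <- function(chrom, start_bp, end_bp, loss_fraction,
                           prevalence) {
  chrom <- sub("^chr", "", as.character(chrom))
  if (!chrom %in% names(CHROM_LENGTHS)) stopf("unknown chromosome: %s", chrom)
  if (!(start_bp < end_bp)) stopf("start_bp must be < end_bp")
  if (any(loss_fraction < 0 | loss_fraction > 1))
    stopf("loss_fraction must lie in [0, 1]")
  if (any(prevalence < 0 | prevalence > 1))
    stopf("prevalences must lie in [0, 1]")
  structure(list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 loss_fraction = loss_fraction, prevalence = prevalence),
            class = "ai_region_spec")
}

#' Specify a microsatellite cohort simulation
#'
#' @param markers data.frame with columns \code{marker}, \code{chrom},
#'   \code{bp}; unique names, sorted by position within chromosome.
#' @param groups named integer vector of samples per group.
#' @param ai_regions list of \code{\link{ai_region_spec}}.
#' @param heterozygosity probability that a normal sample is heterozygous at
#'   a marker (informative).
#' @param peak_noise_cv coefficient of variation of multiplicative
#'   log-normal peak-height noise.
#' @param mean_height expected allele peak height in relative fluorescence
#'   units.
#' @param seed integer seed.
#' @return an \code{msat_cohort_spec}.
#' @export
msat_cohort_spec <- function(markers, groups, ai_regions = list(),
                             heterozygosity = 0.7, peak_noise_cv = 0.1,
                             mean_height = 1000, seed = 1L) {
  stopifnot(is.data.frame(markers),
            all(c("marker", "chrom", "bp") %in% names(markers)))
  if (anyDuplicated(markers$marker)) stopf("marker names must be unique")
  markers$chrom <- sub("^chr", "", as.character(markers$chrom))
  bad <- !markers$chrom %in% names(CHROM_LENGTHS)
  if (any(bad)) stopf("marker(s) on unknown chromosome: %s",
                      paste(markers$marker[bad], collapse = ", "))
  markers <- markers[order(chrom_rank(markers$chrom), markers$bp), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  if (heterozygosity < 0 || heterozygosity > 1)
    stopf("heterozygosity must lie in [0, 1]")
  for (r in ai_regions) stopifnot(inherits(r, "ai_region_spec"))
  structure(list(markers = markers, groups = groups, ai_regions = ai_regions,
                 heterozygosity = heterozygosity,
                 peak_noise_cv = peak_noise_cv, mean_height = mean_height,
                 seed = as.integer(seed)),
            class = "msat_cohort_spec")
}

# Multiplicative log-normal noise with expectation exactly 1.
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

#' Generate a microsatellite peak-height cohort with planted truth
#'
#' Heterozygous normals get two allele peaks of equal expected height. In a
#' tumor carrying an AI region that covers a marker, one allele's expected
#' height is multiplied by \code{1 - loss_fraction} (the classic purity
#' model: only that fraction of cells lost the allele). Homozygous normals
#' emit a single peak and are noninformative by construction. When a sample
#' carries several overlapping regions the largest loss fraction applies.
#'
#' @param spec an \code{\link{msat_cohort_spec}}.
#' @return list with \code{peaks} (data.frame sample, marker, n_allele1,
#'   n_allele2, t_allele1, t_allele2; absent alleles NA), \code{samples},
#'   \code{truth} (markers x samples character matrix in
#'   \{AI, retained, noninformative\}), \code{truth_f} (planted loss
#'   fraction per cell) and \code{spec}.
#' @export
generate_msat_cohort <- function(spec) {
  stopifnot(inherits(spec, "msat_cohort_spec"))
  if (any(spec$groups <= 0L)) stopf("every group needs at least one sample")
  set.seed(spec$seed)
  mk <- spec$markers
  group <- rep(names(spec$groups), spec$groups)
  n <- length(group)
  sample_id <- sprintf("T%03d_%s", seq_len(n), group)
  m <- nrow(mk)

  het <- matrix(stats::runif(m * n) < spec$heterozygosity, m, n,
                dimnames = list(mk$marker, sample_id))
  f_mat <- matrix(0, m, n, dimnames = dimnames(het))
  for (r in spec$ai_regions) {
    prev <- r$prevalence[group]
    prev[is.na(prev)] <- 0
    carry <- stats::runif(n) < prev
    fs <- if (length(r$loss_fraction) > 1L)
      sample(r$loss_fraction, n, replace = TRUE) else
      rep(r$loss_fraction, n)
    idx <- which(mk$chrom == r$chrom & mk$bp >= r$start_bp &
                   mk$bp <= r$end_bp)
    for (j in which(carry))
      f_mat[idx, j] <- pmax(f_mat[idx, j], fs[j])
  }

  H <- spec$mean_height
  cv <- spec$peak_noise_cv
  total <- m * n
  lost_is_allele1 <- matrix(stats::runif(total) < 0.5, m, n)
  nz <- function() matrix(lognormal_noise(total, cv), m, n)
  n1 <- H * nz(); n2 <- H * nz(); t1 <- H * nz(); t2 <- H * nz()

  # apply the purity model to the lost tumor allele
  surv <- 1 - f_mat
  t_lost <- ifelse(lost_is_allele1, t1, t2) * surv
  t_kept <- ifelse(lost_is_allele1, t2, t1)
  t1 <- ifelse(lost_is_allele1, t_lost, t_kept)
  t2 <- ifelse(lost_is_allele1, t_kept, t_lost)
  t1[t1 <= 0] <- NA_real_   # complete loss: allele absent from the trace
  t2[t2 <= 0] <- NA_real_

  # homozygous markers: one constitutive allele only
  n2[!het] <- NA_real_
  t2[!het] <- NA_real_

  truth <- matrix("retained", m, n, dimnames = dimnames(het))
  truth[f_mat > 0] <- "AI"
  truth[!het] <- "noninformative"

  peaks <- data.frame(
    sample = rep(sample_id, each = m),
    marker = rep(mk$marker, n),
    n_allele1 = as.vector(n1), n_allele2 = as.vector(n2),
    t_allele1 = as.vector(t1), t_allele2 = as.vector(t2),
    stringsAsFactors = FALSE
  )
  list(peaks = peaks,
       samples = data.frame(sample = sample_id, group = group,
                            stringsAsFactors = FALSE),
       markers = mk, truth = truth, truth_f = f_mat, spec = spec)
}

# ---------------------------------------------------------------------------
# Expression cohort

#' Specify an expression cohort simulation
#'
#' @param genes data.frame with columns \code{gene}, \code{chrom}, \code{bp}.
#' @param groups named integer vector with exactly two groups.
#' @param de_genes data.frame with columns \code{gene}, \code{log2fc}:
#'   genes shifted by \code{log2fc} in the second group.
#' @param base_mean,base_sd parameters of the per-gene baseline abundance
#'   distribution (log2 scale).
#' @param noise_sd per-measurement Gaussian noise SD (log2 scale).
#' @param seed integer seed.
#' @return an \code{expr_cohort_spec}.
#' @export
expr_cohort_spec <- function(genes, groups, de_genes = NULL,
                             base_mean = 7, base_sd = 2, noise_sd = 0.5,
                             seed = 1L) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "chrom", "bp") %in% names(genes)))
  if (anyDuplicated(genes$gene)) stopf("duplicate gene ids in annotation")
  if (length(groups) != 2L || is.null(names(groups)))
    stopf("groups must be a named vector of exactly two sample counts")
  if (!is.null(de_genes)) {
    stopifnot(is.data.frame(de_genes),
              all(c("gene", "log2fc") %in% names(de_genes)))
    unknown <- setdiff(de_genes$gene, genes$gene)
    if (length(unknown))
      stopf("de_genes not present in annotation: %s",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(list(genes = genes, groups = groups, de_genes = de_genes,
                 base_mean = base_mean, base_sd = base_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expr_cohort_spec")
}

#' Generate a two-group expression cohort with planted truth
#'
#' Per-gene baselines are drawn once; differential genes are shifted by
#' their stated log2 fold change in the second group; all measurements get
#' independent Gaussian noise on the log2 scale.
#'
#' @param spec an \code{\link{expr_cohort_spec}}.
#' @return list with \code{exprs} (genes x samples, log2), \code{samples},
#'   \code{genes}, \code{truth_de} (the planted DE table, possibly empty)
#'   and \code{spec}.
#' @export
generate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "expr_cohort_spec"))
  if (any(spec$groups <= 0L)) stopf("every group needs at least one sample")
  set.seed(spec$seed)
  genes <- spec$genes
  g <- nrow(genes)
  group <- rep(names(spec$groups), spec$groups)
  n <- length(group)
  sample_id <- sprintf("E%03d_%s", seq_len(n), group)

  base <- stats::rnorm(g, spec$base_mean, spec$base_sd)
  mu <- matrix(base, g, n)
  if (!is.null(spec$de_genes) && nrow(spec$de_genes)) {
    idx <- match(spec$de_genes$gene, genes$gene)
    in_g2 <- group == names(spec$groups)[2L]
    mu[idx, in_g2] <- mu[idx, in_g2] + spec$de_genes$log2fc
  }
  exprs <- mu + matrix(stats::rnorm(g * n, 0, spec$noise_sd), g, n)
  dimnames(exprs) <- list(genes$gene, sample_id)

  truth_de <- spec$de_genes %||%
    data.frame(gene = character(0), log2fc = numeric(0))
  list(exprs = exprs,
       samples = data.frame(sample = sample_id, group = group,
                            stringsAsFactors = FALSE),
       genes = genes, truth_de = truth_de, spec = spec)
}
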