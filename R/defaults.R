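# Study-shaped default simulation specs. These encode the cohort structure
# the package is designed around: a metastasis group versus a primary-tumor
# group sharing most aberrations, with a few strongly metastasis-enriched
# gains/losses; 10q allelic imbalance concentrated in two core regions on
# top of a low-frequency whole-arm background; and downregulated 10q
# transcripts in the metastasis expression group.

#' Default array-CGH simulation spec
#'
#' Twenty metastases versus twenty primaries on a 2000-probe autosomal
#' grid. Three planted group-differential aberrations (7p gain, 10q loss,
#' 17q loss, effects +/-0.5 log2) and two shared aberrations with nearly
#' equal prevalence in both groups (8q gain, 16q loss), noise SD 0.15.
#'
#' @param seed integer seed.
#' @param n_probes panel size.
#' @param n_per_group samples per group.
#' @return a \code{\link{cgh_cohort_spec}}.
#' @export
default_cgh_spec <- function(seed = 1L, n_probes = 2000, n_per_group = 20L) {
  panel <- default_probe_panel(n_probes)
  groups <- c(met = n_per_group, primary = n_per_group)
  aberrations <- list(
    # group-differential (the regions the cohort comparison should find)
    aberration_spec("7", 5.4e6, 27.8e6, +0.5,
                    c(met = 0.75, primary = 0.10)),
    aberration_spec("10", 71.2e6, 134.8e6, -0.5,
                    c(met = 0.80, primary = 0.05)),
    aberration_spec("17", 26.6e6, 60.0e6, -0.5,
                    c(met = 0.75, primary = 0.05)),
    # shared background aberrations (present in both groups alike)
    aberration_spec("8", 48.0e6, 146.0e6, +0.5,
                    c(met = 0.45, primary = 0.40)),
    aberration_spec("16", 46.0e6, 90.0e6, -0.5,
                    c(met = 0.35, primary = 0.30))
  )
  cgh_cohort_spec(panel, groups, aberrations,
                  noise_sd = 0.15, baseline_shift_sd = 0.05, seed = seed)
}

# Which default aberrations are group-differential (prevalence gap >= 0.3)?
# Used by tests and the acceptance script to define recovery ground truth.
differential_aberrations <- function(spec, min_gap = 0.3) {
  keep <- vapply(spec$aberrations, function(ab) {
    pr <- ab$prevalence
    (max(pr) - min(pr)) >= min_gap
  }, logical(1))
  spec$aberrations[keep]
}

#' Default 10q microsatellite panel
#'
#' Eleven synthetic microsatellite markers spanning 10q22.3-qter
#' (~84-134 Mbp) at roughly 5-Mbp spacing, emulating a dinucleotide-repeat
#' allelotyping panel. Marker names follow the D10S nomenclature but the
#' positions are synthetic.
#'
#' @return data.frame with columns marker, chrom, bp.
#' @export
default_msat_panel <- function() {
  data.frame(
    marker = c("D10S1686", "D10S1765", "D10S541", "D10S583", "D10S185",
               "D10S192", "D10S597", "D10S1236", "D10S173", "D10S190",
               "D10S212"),
    chrom = "10",
    bp = c(84.4e6, 88.9e6, 89.9e6, 95.0e6, 101.0e6, 108.0e6, 115.0e6,
           120.5e6, 125.5e6, 129.5e6, 134.0e6),
    stringsAsFactors = FALSE
  )
}

#' Default microsatellite simulation spec
#'
#' Four clinical groups (21 brain metastases, 39 primaries without relapse,
#' 10 with brain relapse, 17 with other relapse). A low-frequency whole-arm
#' AI background plus two core regions: CR1 over markers D10S1765/D10S541
#' (the PTEN locus) and CR2 over D10S173/D10S190, both enriched in the
#' metastasis and brain-relapse groups. Loss fractions 0.7 or 0.9 emulate
#' macrodissected samples with at least 70% tumor-cell content.
#'
#' @param seed integer seed.
#' @return an \code{\link{msat_cohort_spec}}.
#' @export
default_msat_spec <- function(seed = 1L) {
  markers <- default_msat_panel()
  groups <- c(met = 21L, primary_no_relapse = 39L,
              primary_brain_relapse = 10L, primary_other_relapse = 17L)
  regions <- list(
    # whole-arm background AI (samples with full 10q loss)
    ai_region_spec("10", 80.5e6, 134.3e6, c(0.7, 0.9),
                   c(met = 0.18, primary_no_relapse = 0.12,
                     primary_brain_relapse = 0.15,
                     primary_other_relapse = 0.12)),
    # CR1: around the PTEN locus
    ai_region_spec("10", 87.0e6, 91.0e6, c(0.7, 0.9),
                   c(met = 0.50, primary_no_relapse = 0.30,
                     primary_brain_relapse = 0.50,
                     primary_other_relapse = 0.30)),
    # CR2: distal hotspot
    ai_region_spec("10", 124.0e6, 130.5e6, c(0.7, 0.9),
                   c(met = 0.50, primary_no_relapse = 0.30,
                     primary_brain_relapse = 0.50,
                     primary_other_relapse = 0.30))
  )
  msat_cohort_spec(markers, groups, regions,
                   heterozygosity = 0.7, peak_noise_cv = 0.1, seed = seed)
}

#' Default expression simulation spec
#'
#' Two groups of 10 samples, 2000 annotated genes laid out genome-wide,
#' with 50 genes on 10q22.3-qter downregulated by log2 fold change -1.5 in
#' the metastasis group. Baseline abundances N(7, 2) and measurement noise
#' SD 0.5, all on the log2 scale.
#'
#' @param seed integer seed.
#' @param n_genes total genes.
#' @param n_de number of planted differential genes.
#' @param log2fc planted shift in the second (metastasis) group.
#' @param n_per_group samples per group.
#' @return an \code{\link{expr_cohort_spec}}.
#' @export
default_expr_spec <- function(seed = 1L, n_genes = 2000, n_de = 50,
                              log2fc = -1.5, n_per_group = 10L) {
  grid <- default_probe_panel(n_genes)
  genes <- data.frame(gene = sprintf("G%04d", seq_len(nrow(grid))),
                      chrom = grid$chrom, bp = grid$bp,
                      stringsAsFactors = FALSE)
  # plant the DE genes on 10q22.3-qter, emulating regional downregulation
  on_10q <- which(genes$chrom == "10" & genes$bp >= 80.5e6)
  if (length(on_10q) < n_de) {
    extra <- setdiff(order(genes$chrom == "10", decreasing = TRUE), on_10q)
    on_10q <- c(on_10q, extra[seq_len(n_de - length(on_10q))])
  }
  de <- if (n_de > 0)
    data.frame(gene = genes$gene[on_10q[seq_len(n_de)]],
               log2fc = log2fc, stringsAsFactors = FALSE) else NULL
  expr_cohort_spec(genes, c(primary = n_per_group, met = n_per_group),
                   de_genes = de, noise_sd = 0.5, seed = seed)
}
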