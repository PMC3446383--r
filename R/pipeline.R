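# Shared table IO and end-to-end pipeline orchestration over generated
# cohorts. The package's functions are its interface; run_pipeline() wires
# the stages together in the order copy number -> microsatellite ->
# expression -> association, and the writers emit self-describing TSV/CSV
# with a parameter header.

#' Write a table with a parameter header
#'
#' Tab-separated by default; header lines starting with \code{#} record
#' the generating parameters and seed so every output is self-describing.
#'
#' @param x data.frame to write.
#' @param path output file.
#' @param params named list echoed into \code{# key=value} header lines.
#' @param sep field separator (\code{"\t"} or \code{","}).
#' @export
write_table <- function(x, path, params = list(), sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s=%s", k, format(params[[k]])), con)
  utils::write.table(x, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read a table written by \code{\link{write_table}}
#'
#' Skips \code{#} header lines; an empty file yields a 0-row data.frame.
#' Extra columns beyond a required schema are preserved.
#'
#' @param path input file.
#' @param required character vector of column names that must be present.
#' @param sep field separator.
#' @return data.frame.
#' @export
read_table <- function(path, required = character(0), sep = "\t") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  x <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) data.frame())
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) && nrow(x) > 0)
    stopf("%s lacks required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  x
}

#' Default pipeline configuration
#'
#' All stage parameters at the analysis defaults: +/-0.05 log2 gain/loss
#' cutoffs, amplification cutoff 1.0, minimum segment 5 probes, two-pass
#' recentering, region cutoffs p < 0.05 and FDR < 0.04, 30-point
#' frequency-difference loci, AI ratio 2.0, core-region frequency 0.3 and
#' prominence 0.15, SAM FDR 5% with 200 permutations, 25th-percentile
#' abundance filter, chromosome 10, fold change 2.
#'
#' @param seed master seed; every stochastic stage derives from it.
#' @param out_dir optional directory for TSV outputs (created if needed);
#'   \code{NULL} keeps results in memory only.
#' @return a named list of parameters.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = as.integer(seed), out_dir = out_dir,
    stages = c("cgh", "msat", "expr"),
    gain_cut = 0.05, loss_cut = -0.05, amp_cut = 1.0,
    min_seg_probes = 5L, recenter = TRUE,
    p_max = 0.05, fdr_max = 0.04, min_diff_pct = 30,
    ai_cut = 2.0, min_freq = 0.3, min_prominence = 0.15,
    sam_fdr = 0.05, n_perm = 200L,
    min_expression_percentile = 25, chromosome = "10",
    min_fold_change = 2
  )
}

#' Run the full pipeline on generated cohorts
#'
#' Generates the default synthetic cohorts from the master seed and runs
#' every enabled stage: two-pass copy-number calling and cohort
#' comparison; microsatellite AI calling, core-region detection and
#' group-frequency/Fisher association; quantile normalization, SAM-style
#' differential expression and the 10q candidate filter. Identical
#' config + seed reproduce the result bundle bit for bit.
#'
#' @param config a \code{\link{default_pipeline_config}} list; unknown
#'   keys are rejected.
#' @return a named list of stage results (\code{cgh}, \code{msat},
#'   \code{expr}, whichever are enabled).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  known <- names(default_pipeline_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  config <- utils::modifyList(default_pipeline_config(), config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(x, name, params = list(), sep = "\t") {
    if (!is.null(out_dir))
      write_table(x, file.path(out_dir, name),
                  c(list(seed = config$seed), params), sep = sep)
  }
  bundle <- list()
  thr <- cgh_thresholds(config$gain_cut, config$loss_cut, config$amp_cut)

  if ("cgh" %in% config$stages) {
    cohort <- generate_acgh_cohort(default_cgh_spec(seed = config$seed))
    called <- call_cgh_cohort(cohort$log2, cohort$panel, thr,
                              config$min_seg_probes,
                              recenter = config$recenter)
    cmp <- compare_cohorts(called$segmean, called$calls,
                           cohort$samples$group, cohort$panel,
                           config$p_max, config$fdr_max)
    grp <- unique(cohort$samples$group)
    loci <- high_freq_difference_loci(cmp$track[[grp[1L]]],
                                      cmp$track[[grp[2L]]], cohort$panel,
                                      config$min_diff_pct)
    bundle$cgh <- list(cohort = cohort, called = called, compare = cmp,
                       high_freq_loci = loci)
    track_df <- data.frame(probe = cohort$panel$probe,
                           chrom = cohort$panel$chrom,
                           bp = cohort$panel$bp)
    for (g in grp) {
      track_df[[paste0(g, "_gain_pct")]] <- cmp$track[[g]]$gain_pct
      track_df[[paste0(g, "_loss_pct")]] <- cmp$track[[g]]$loss_pct
    }
    emit(track_df, "cgh_frequency_track.tsv",
         list(stage = "cgh", gain_cut = config$gain_cut,
              loss_cut = config$loss_cut))
    emit(cmp$regions, "cgh_significant_regions.tsv",
         list(stage = "cgh", p_max = config$p_max,
              fdr_max = config$fdr_max))
  }

  if ("msat" %in% config$stages) {
    msat <- generate_msat_cohort(default_msat_spec(seed = config$seed))
    classified <- classify_peak_table(msat$peaks, config$ai_cut)
    calls <- call_matrix(classified, msat$markers)
    cores <- core_regions(calls, msat$markers, config$min_freq,
                          config$min_prominence)
    status <- apply(calls, 1L, sample_region_status)
    freq_tab <- group_frequency_table(status, msat$samples$group, "all_AI")
    assoc <- list()
    tabs <- build_tables(status, msat$samples$group)
    for (nm in names(tabs))
      assoc[[nm]] <- list(table = tabs[[nm]],
                          p = fisher_exact_2x2(tabs[[nm]]))
    bundle$msat <- list(cohort = msat, calls = calls, cores = cores,
                        status = status, freq_table = freq_tab,
                        association = assoc)
    emit(as.data.frame(calls), "msat_call_matrix.tsv",
         list(stage = "msat", ai_cut = config$ai_cut))
    emit(freq_tab, "msat_group_frequencies.tsv", list(stage = "msat"))
    emit(cores, "msat_core_regions.tsv",
         list(stage = "msat", min_freq = config$min_freq,
              min_prominence = config$min_prominence))
  }

  if ("expr" %in% config$stages) {
    expr <- generate_expression_cohort(default_expr_spec(seed = config$seed))
    norm <- quantile_normalize(expr$exprs)
    sam <- sam_significant(norm, expr$samples$group,
                           target_fdr = config$sam_fdr,
                           n_perm = config$n_perm, seed = config$seed)
    cand <- filter_candidates(sam, norm, expr$genes, expr$samples$group,
                              config$min_expression_percentile,
                              config$chromosome,
                              min_fold_change = config$min_fold_change)
    bundle$expr <- list(cohort = expr, sam = sam, candidates = cand)
    emit(cand, "expr_candidates.tsv",
         list(stage = "expr", sam_fdr = config$sam_fdr,
              n_perm = config$n_perm))
  }
  bundle
}
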