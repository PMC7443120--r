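# End-to-end pipeline: simulate a cohort, call CNVs with both HMM profiles,
# merge fragments, intersect the callers, apply sample QC and the filter
# cascade, and run burden and association analyses.

#' Run the full rare-CNV case-control pipeline on a synthetic cohort
#'
#' Executes, in order: cohort generation ([generate_cohort()]); per-sample
#' intensity simulation ([simulate_intensities()]) and GC-wave adjustment
#' ([gc_adjust_lrr()]); HMM segmentation with both caller profiles
#' ([hmm_segment()]); fragment merging ([merge_adjacent_fragments()]);
#' dual-caller intersection ([intersect_two_callsets()]); sample QC
#' ([sample_qc_filter()]); the call-level filter cascade ([filter_calls()])
#' and control-frequency filter ([control_frequency_filter()]); burden
#' summaries and comparison ([summarize_burden()], [compare_burden()]); and
#' the segmental association test ([segmental_test()]). Deterministic given
#' `seed`.
#'
#' @param config a [cohort_config()]; its seed is replaced by `seed`.
#' @param map marker map.
#' @param n_perm permutations for the burden and association tests.
#' @param seed integer seed driving the whole run.
#' @param classes CNV classes to test for association.
#' @param burden_metrics metrics passed to [compare_burden()].
#' @param qc a [qc_thresholds()].
#' @param filters a [filter_thresholds()].
#' @param params_a,params_b the two caller parameter sets.
#' @param quiet suppress progress messages.
#' @return a `cnv_pipeline` list with the cohort, call sets, QC and filter
#'   reports, burden results and association results.
#' @export
run_cnv_pipeline <- function(config, map = toy_marker_map(),
                             n_perm = 10000, seed = config$seed,
                             classes = "DUP",
                             burden_metrics = c("total_len_dup",
                                                "total_len_del"),
                             qc = qc_thresholds(),
                             filters = filter_thresholds(),
                             params_a = hmm_params("callerA"),
                             params_b = hmm_params("callerB"),
                             quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  config$seed <- as.integer(seed)
  set.seed(config$seed)

  say("generating cohort ...")
  cohort <- generate_cohort(config, map)
  samples <- cohort$samples
  truth_by_sample <- split(cohort$truth, cohort$truth$sample_id)
  mi <- map_index(map)

  say("simulating intensities and calling CNVs for ",
      nrow(samples), " samples ...")
  empty_truth <- cohort$truth[0, , drop = FALSE]
  pre <- gc_adjust_pre(map)
  ids <- samples$sample_id; wfs <- samples$wf
  signal_fun <- function(i) {
    tr <- truth_by_sample[[ids[i]]]
    if (is.null(tr)) tr <- empty_truth
    prof <- simulate_intensities(list(sample_id = ids[i], wf = wfs[i]),
                                 tr, map, config, mi)
    prof$lrr <- gc_adjust_apply(prof$lrr, pre)
    prof
  }
  raw <- hmm_segment_cohort(signal_fun, samples$sample_id, map,
                            params_a, params_b)

  say("merging fragments and intersecting callers ...")
  merged_a <- merge_adjacent_fragments(raw$callerA, map,
                                       filters$merge_gap_frac)
  merged_b <- merge_adjacent_fragments(raw$callerB, map,
                                       filters$merge_gap_frac)
  consensus <- intersect_two_callsets(merged_a, merged_b, map)

  say("sample QC ...")
  counts <- table(consensus$sample_id)
  qc_res <- sample_qc_filter(samples, setNames(as.integer(counts),
                                               names(counts)), qc)
  samples_pass <- qc_res$pass
  consensus <- consensus[consensus$sample_id %in% samples_pass$sample_id, ,
                         drop = FALSE]

  say("filtering calls ...")
  common <- do.call(rbind, lapply(config$common_loci, function(cl)
    data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
               name = cl$name, frequency = cl$frequency,
               stringsAsFactors = FALSE)))
  filt <- filter_calls(consensus, config$artifact_regions, common, filters)
  cf <- control_frequency_filter(filt$calls, samples_pass, filters)
  curated <- cf$calls
  removed <- c(filt$removed, control_freq = cf$removed)

  say("burden analysis ...")
  burden <- summarize_burden(curated, samples_pass)
  burden_tests <- lapply(burden_metrics, function(m)
    compare_burden(burden, samples_pass, m, n_perm = n_perm))
  names(burden_tests) <- burden_metrics

  say("association testing (", paste(classes, collapse = ", "), ") ...")
  assoc <- lapply(classes, function(cl)
    segmental_test(curated, samples_pass, cl, n_perm = n_perm))
  names(assoc) <- classes

  structure(list(config = config, samples = samples,
                 samples_pass = samples_pass, qc_report = qc_res$report,
                 truth = cohort$truth,
                 calls_raw = raw, calls_consensus = consensus,
                 calls_curated = curated, removed = removed,
                 burden = burden, burden_tests = burden_tests,
                 assoc = assoc, n_perm = n_perm, seed = config$seed),
            class = "cnv_pipeline")
}

#' @export
print.cnv_pipeline <- function(x, ...) {
  cat("<cnv_pipeline>\n")
  cat(sprintf("  cohort: %d/%d samples passed QC (%d excluded)\n",
              nrow(x$samples_pass), nrow(x$samples), nrow(x$qc_report)))
  cat(sprintf("  calls: %d consensus -> %d curated (removed: %s)\n",
              nrow(x$calls_consensus), nrow(x$calls_curated),
              paste(names(x$removed), x$removed, sep = "=", collapse = ", ")))
  for (m in names(x$burden_tests)) {
    bt <- x$burden_tests[[m]]
    cat(sprintf("  burden %s: case %.4g vs control %.4g, p = %.4g\n",
                m, bt$case_mean, bt$control_mean, bt$p_value))
  }
  for (cl in names(x$assoc)) {
    a <- x$assoc[[cl]]
    cat(sprintf("  association (%s): %d segments, %d genome-wide significant\n",
                cl, nrow(a), sum(a$p_corr <= 0.05)))
  }
  invisible(x)
}

#' Check recovery of planted risk loci
#'
#' For each configured risk locus, reports whether some association segment
#' overlapping it reaches the minimum attainable corrected p
#' (`1 / (n_perm + 1)`), and whether any segment not overlapping a risk
#' locus does.
#'
#' @param assoc a `cnv_assoc` result.
#' @param risk_loci list of [risk_locus()] objects.
#' @param margin_bp slack around each locus when matching segments: planted
#'   carriers have breakpoints jittered by up to 2 markers beyond the
#'   configured span and the caller adds its own boundary uncertainty, so
#'   segments within this margin belong to the locus, not to the null.
#' @return list with `recovered` (named logical per locus) and
#'   `null_at_floor` (count of floor-significant segments away from every
#'   locus).
#' @export
risk_locus_recovery <- function(assoc, risk_loci, margin_bp = 5000) {
  floor_p <- 1 / (attr(assoc, "n_perm") + 1)
  at_floor <- assoc$p_corr <= floor_p + 1e-15
  overlaps_locus <- matrix(FALSE, nrow(assoc), length(risk_loci))
  for (j in seq_along(risk_loci)) {
    rl <- risk_loci[[j]]
    overlaps_locus[, j] <- assoc$chrom == rl$chrom &
      assoc$start <= rl$end + margin_bp & assoc$end >= rl$start - margin_bp
  }
  recovered <- vapply(seq_along(risk_loci), function(j)
    any(at_floor & overlaps_locus[, j]), TRUE)
  names(recovered) <- vapply(risk_loci, `[[`, "", "name")
  list(recovered = recovered,
       null_at_floor = sum(at_floor & rowSums(overlaps_locus) == 0))
}
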