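# Shared fixtures: tiny marker maps, call tables and cohorts built in code.

tiny_map <- function(n = 300, spacing = 1000, chrom = "1", start = 1e6,
                     gc = NULL) {
  if (is.null(gc)) gc <- rep(0.5, n)
  as_marker_map(data.frame(
    marker_id = sprintf("m%s_%04d", chrom, seq_len(n)),
    chrom = chrom, pos = start + (seq_len(n) - 1) * spacing, gc = gc,
    stringsAsFactors = FALSE))
}

two_chrom_map <- function(n = 200, spacing = 1000) {
  rbind_maps <- rbind(
    data.frame(marker_id = sprintf("mA%04d", 1:n), chrom = "1",
               pos = 1e6 + (0:(n - 1)) * spacing, gc = 0.5),
    data.frame(marker_id = sprintf("mB%04d", 1:n), chrom = "2",
               pos = 2e6 + (0:(n - 1)) * spacing, gc = 0.5))
  as_marker_map(rbind_maps)
}

mk_call <- function(sample_id, chrom, start, end, copy_state,
                    n_markers = 10L, confidence = 50, caller = "callerA") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             copy_state = as.integer(copy_state),
             n_markers = as.integer(n_markers), confidence = confidence,
             caller = caller, stringsAsFactors = FALSE)
}

mk_samples <- function(n_cases, n_controls) {
  n <- n_cases + n_controls
  data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    subtype = rep(c("nonaccommodative", "none"), c(n_cases, n_controls)),
    family_id = NA_character_,
    call_rate = 0.995, lrr_sd = 0.15, wf = 0.01, baf_drift = 0.001,
    stringsAsFactors = FALSE)
}

empty_calls_df <- function() {
  mk_call("x", "1", 1, 2, 3)[0, ]
}

cohort_truth0 <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), copy_state = integer(), origin = character(),
             stringsAsFactors = FALSE)
}

noiseless_config <- function(...) {
  cohort_config(n_cases = 2, n_controls = 2, del_rate = 0, dup_rate = 0,
                risk_loci = list(), common_loci = list(),
                lrr_sd = 0, baf_sd = 0, wave_gain = 0,
                qc_fail_frac = 0, family_frac = 0, seed = 1L, ...)
}

# independent per-marker emission oracle mirroring the model definition:
# Gaussian LRR; BAF mixture with uniform outlier; homozygous band (within
# 3 sd of 0 or 1) reduced to cluster-weight constants
oracle_emission <- function(lrr, baf, params) {
  mix <- params$baf_mix
  n <- length(lrr)
  out <- matrix(0, n, 5)
  for (i in seq_len(n)) {
    for (s in 1:5) {
      mu <- mix$means[[s]]; w <- mix$weights[[s]]; u <- mix$unif[s]
      if (baf[i] <= 3 * mix$baf_sd) {
        bll <- log(u + sum(w[mu == 0]))
      } else if (baf[i] >= 1 - 3 * mix$baf_sd) {
        bll <- log(u + sum(w[mu == 1]))
      } else {
        comp <- ifelse(abs(baf[i] - mu) <= 8 * mix$baf_sd,
                       w * dnorm(baf[i], mu, mix$baf_sd), 0)
        bll <- log(u + sum(comp))
      }
      out[i, s] <- dnorm(lrr[i], params$lrr_means[s], params$lrr_sd,
                         log = TRUE) + bll
    }
  }
  out
}
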