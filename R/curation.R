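# Quality-control and filtering cascade: sample-level exclusion on intensity
# metrics, merging of HMM call fragments, intersection of the two callers'
# call sets, and call-level size / marker / artifact / common-CNV /
# confidence / control-frequency filters.

#' Sample QC thresholds
#'
#' Defaults are the published empirical cutoffs: LRR standard deviation
#' < 0.3, |waviness factor| < 0.43, BAF drift < 0.01, call rate >= 0.98, and
#' at most 50 CNV calls per sample.
#'
#' @param max_lrr_sd,max_abs_wf,max_baf_drift,min_call_rate,max_cnv_calls
#'   threshold values.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_lrr_sd = 0.3, max_abs_wf = 0.43,
                          max_baf_drift = 0.01, min_call_rate = 0.98,
                          max_cnv_calls = 50) {
  stopifnot(max_lrr_sd > 0, max_abs_wf > 0, max_baf_drift > 0,
            min_call_rate > 0, max_cnv_calls > 0)
  structure(list(max_lrr_sd = max_lrr_sd, max_abs_wf = max_abs_wf,
                 max_baf_drift = max_baf_drift,
                 min_call_rate = min_call_rate,
                 max_cnv_calls = max_cnv_calls),
            class = "qc_thresholds")
}

#' Call-level filter thresholds
#'
#' Defaults follow the published cascade: calls must be > 10 kb and span 10
#' or more markers; calls overlapped (> 50% of the call) by artifact regions
#' or by catalog CNVs with population frequency > 10% are removed; deletions
#' need confidence >= 25 and duplications >= 10; CNVs present (50% reciprocal
#' overlap) in more than 1% of controls are removed.
#'
#' @param min_length_bp,min_markers,del_min_conf,dup_min_conf size / support
#'   and confidence cutoffs.
#' @param artifact_overlap_frac,common_overlap_frac,common_freq overlap and
#'   frequency rules for artifact and common-CNV removal.
#' @param max_control_freq control-frequency cutoff (fraction of controls).
#' @param presence_reciprocal_frac reciprocal overlap defining "the same CNV"
#'   when clustering calls across samples.
#' @param merge_gap_frac fragment-merge rule: gap markers must be fewer than
#'   this fraction of the two segments' combined markers.
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_length_bp = 10000, min_markers = 10,
                              del_min_conf = 25, dup_min_conf = 10,
                              artifact_overlap_frac = 0.5,
                              common_overlap_frac = 0.5, common_freq = 0.10,
                              max_control_freq = 0.01,
                              presence_reciprocal_frac = 0.5,
                              merge_gap_frac = 0.2) {
  stopifnot(min_length_bp > 0, min_markers >= 1,
            artifact_overlap_frac > 0, artifact_overlap_frac <= 1,
            common_overlap_frac > 0, common_overlap_frac <= 1,
            common_freq >= 0, common_freq <= 1,
            max_control_freq >= 0, max_control_freq <= 1,
            presence_reciprocal_frac > 0, presence_reciprocal_frac <= 1,
              merge_gap_frac > 0, merge_gap_frac <= 1)
  structure(list(min_length_bp = min_length_bp, min_markers = min_markers,
                 del_min_conf = del_min_conf, dup_min_conf = dup_min_conf,
                 artifact_overlap_frac = artifact_overlap_frac,
                 common_overlap_frac = common_overlap_frac,
                 common_freq = common_freq,
                 max_control_freq = max_control_freq,
                 presence_reciprocal_frac = presence_reciprocal_frac,
                 merge_gap_frac = merge_gap_frac),
            class = "filter_thresholds")
}

#' Sample-level QC filter
#'
#' A sample passes iff `lrr_sd < 0.3` and `|wf| < 0.43` and
#' `baf_drift < 0.01` (all strict) and `call_rate >= 0.98` and its CNV call
#' count is `<= 50`. Samples with a missing metric are excluded with reason
#' `"missing_metric"`. The exclusion report lists every failed criterion per
#' sample.
#'
#' @param samples sample sheet data.frame.
#' @param call_counts named integer vector of per-sample CNV call counts
#'   (samples absent from the vector count 0).
#' @param thresholds a [qc_thresholds()].
#' @return list with `pass` (subset of `samples`) and `report` (data.frame
#'   `sample_id`, `reasons`).
#' @export
sample_qc_filter <- function(samples, call_counts = integer(),
                             thresholds = qc_thresholds()) {
  counts <- call_counts[match(samples$sample_id, names(call_counts))]
  counts[is.na(counts)] <- 0L
  reasons <- vector("list", nrow(samples))
  metrics <- samples[c("lrr_sd", "wf", "baf_drift", "call_rate")]
  for (i in seq_len(nrow(samples))) {
    r <- character(0)
    if (anyNA(metrics[i, ])) {
      r <- "missing_metric"
    } else {
      if (!(samples$lrr_sd[i] < thresholds$max_lrr_sd)) r <- c(r, "lrr_sd")
      if (!(abs(samples$wf[i]) < thresholds$max_abs_wf)) r <- c(r, "wf")
      if (!(samples$baf_drift[i] < thresholds$max_baf_drift))
        r <- c(r, "baf_drift")
      if (!(samples$call_rate[i] >= thresholds$min_call_rate))
        r <- c(r, "call_rate")
      if (!(counts[i] <= thresholds$max_cnv_calls)) r <- c(r, "n_cnv_calls")
    }
    reasons[[i]] <- r
  }
  failed <- lengths(reasons) > 0
  report <- data.frame(
    sample_id = samples$sample_id[failed],
    reasons = vapply(reasons[failed], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  list(pass = samples[!failed, , drop = FALSE], report = report)
}

#' Merge adjacent call fragments
#'
#' HMM callers can artificially break up large CNVs. Within each sample,
#' caller and chromosome, adjacent calls of the same copy state are merged
#' when the number of intervening markers is less than `gap_frac` times the
#' combined marker count of the two segments (gap excluded from the
#' denominator by default — the literal reading of the rule; set
#' `include_gap = TRUE` for the alternative). Merging iterates to a
#' fixpoint; the merged call spans both segments and the gap, its marker
#' count is the sum of both segments plus the gap, and its confidence is the
#' sum of the parts.
#'
#' @param calls call data.frame.
#' @param map marker map (to count intervening markers).
#' @param gap_frac merge threshold (default 0.2).
#' @param include_gap include the gap markers in the rule's denominator.
#' @return merged call data.frame.
#' @export
merge_adjacent_fragments <- function(calls, map, gap_frac = 0.2,
                                     include_gap = FALSE) {
  if (nrow(calls) == 0) return(calls)
  validate_calls(calls)
  mi <- map_index(map)
  key <- paste(calls$sample_id, calls$caller, calls$chrom, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    g <- calls[idx[order(calls$start[idx])], , drop = FALSE]
    if (any(g$start[-1] <= g$end[-nrow(g)]))
      stop("overlapping same-sample, same-caller calls on chromosome ",
           g$chrom[1], " for ", g$sample_id[1],
           " violate the caller contract")
    ci <- mi[[g$chrom[1]]]
    start_i <- findInterval(g$start, ci$pos)
    end_i <- findInterval(g$end, ci$pos)
    repeat {
      if (nrow(g) < 2) break
      merged <- FALSE
      i <- 1
      while (i < nrow(g)) {
        gap <- start_i[i + 1] - end_i[i] - 1L
        denom <- g$n_markers[i] + g$n_markers[i + 1] +
          if (include_gap) gap else 0L
        if (g$copy_state[i] == g$copy_state[i + 1] &&
            gap < gap_frac * denom) {
          g$end[i] <- g$end[i + 1]
          end_i[i] <- end_i[i + 1]
          g$n_markers[i] <- g$n_markers[i] + g$n_markers[i + 1] + gap
          g$confidence[i] <- g$confidence[i] + g$confidence[i + 1]
          g <- g[-(i + 1), , drop = FALSE]
          start_i <- start_i[-(i + 1)]; end_i <- end_i[-(i + 1)]
          merged <- TRUE
        } else i <- i + 1
      }
      if (!merged) break
    }
    g
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$sample_id, chrom_rank(out$chrom), out$start), , drop = FALSE]
}

#' Intersect two callers' call sets
#'
#' Only CNVs detected by both callers are retained: for every overlapping
#' pair of calls of the same copy-number class (DEL vs DUP by default; set
#' `strict_state = TRUE` to require identical integer copy number), the
#' intersection interval is emitted with the marker count recomputed from
#' the map, confidence the minimum of the pair, copy state taken from the
#' more confident member, and caller tag `"consensus"`. Calls seen by only
#' one caller are dropped.
#'
#' @param calls_a,calls_b fragment-merged call data.frames from the two
#'   callers.
#' @param map marker map.
#' @param strict_state require identical integer copy state.
#' @return consensus call data.frame.
#' @export
intersect_two_callsets <- function(calls_a, calls_b, map,
                                   strict_state = FALSE) {
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) return(empty_calls())
  mi <- map_index(map)
  key_a <- paste(calls_a$sample_id, calls_a$chrom, sep = "\r")
  key_b <- paste(calls_b$sample_id, calls_b$chrom, sep = "\r")
  out <- list()
  for (key in intersect(unique(key_a), unique(key_b))) {
    a <- calls_a[key_a == key, , drop = FALSE]
    b <- calls_b[key_b == key, , drop = FALSE]
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (strict_state) {
        if (a$copy_state[i] != b$copy_state[j]) next
      } else if (copy_class(a$copy_state[i]) != copy_class(b$copy_state[j]))
        next
      s <- max(a$start[i], b$start[j])
      e <- min(a$end[i], b$end[j])
      if (s > e) next
      ci <- mi[[a$chrom[i]]]
      nmk <- findInterval(e, ci$pos) - findInterval(s - 0.5, ci$pos)
      state <- if (a$confidence[i] >= b$confidence[j]) a$copy_state[i]
               else b$copy_state[j]
      out[[length(out) + 1]] <- data.frame(
        sample_id = a$sample_id[i], chrom = a$chrom[i], start = s, end = e,
        copy_state = state, n_markers = as.integer(max(1L, nmk)),
        confidence = min(a$confidence[i], b$confidence[j]),
        caller = "consensus", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_calls())
  res <- do.call(rbind, out)
  res[order(res$sample_id, chrom_rank(res$chrom), res$start), , drop = FALSE]
}

#' Call-level filter cascade
#'
#' Applies, in order: minimum length (>= `min_length_bp`), minimum marker
#' support, artifact-region overlap (> `artifact_overlap_frac` of the call
#' with any single artifact region), common-CNV overlap (>
#' `common_overlap_frac` of the call with any catalog entry of population
#' frequency > `common_freq`), and the class-specific confidence cutoffs.
#' Removal counts are reported per rule in application order.
#'
#' @param calls consensus call data.frame.
#' @param artifact_regions data.frame of artifact regions (1-based
#'   inclusive, as from [read_bed_regions()]).
#' @param common_catalog data.frame of catalog CNVs with a `frequency`
#'   column.
#' @param thresholds a [filter_thresholds()].
#' @return list with `calls` (retained) and `removed` (named integer counts
#'   per rule).
#' @export
filter_calls <- function(calls, artifact_regions = NULL,
                         common_catalog = NULL,
                         thresholds = filter_thresholds()) {
  removed <- c(size = 0L, markers = 0L, artifact = 0L, common = 0L,
               confidence = 0L)
  if (nrow(calls)) {
    keep <- (calls$end - calls$start + 1) >= thresholds$min_length_bp
    removed["size"] <- sum(!keep)
    calls <- calls[keep, , drop = FALSE]
  }
  if (nrow(calls)) {
    keep <- calls$n_markers >= thresholds$min_markers
    removed["markers"] <- sum(!keep)
    calls <- calls[keep, , drop = FALSE]
  }
  if (nrow(calls) && !is.null(artifact_regions) && nrow(artifact_regions)) {
    keep <- !max_overlap_exceeds(calls, artifact_regions,
                                 thresholds$artifact_overlap_frac)
    removed["artifact"] <- sum(!keep)
    calls <- calls[keep, , drop = FALSE]
  }
  if (nrow(calls) && !is.null(common_catalog) && nrow(common_catalog)) {
    cat_common <- common_catalog[
      !is.na(common_catalog$frequency) &
        common_catalog$frequency > thresholds$common_freq, , drop = FALSE]
    if (nrow(cat_common)) {
      keep <- !max_overlap_exceeds(calls, cat_common,
                                   thresholds$common_overlap_frac)
      removed["common"] <- sum(!keep)
      calls <- calls[keep, , drop = FALSE]
    }
  }
  if (nrow(calls)) {
    cls <- copy_class(calls$copy_state)
    keep <- ifelse(cls == "DEL",
                   calls$confidence >= thresholds$del_min_conf,
                   calls$confidence >= thresholds$dup_min_conf)
    removed["confidence"] <- sum(!keep)
    calls <- calls[keep, , drop = FALSE]
  }
  rownames(calls) <- NULL
  list(calls = calls, removed = removed)
}

# TRUE for calls whose overlap with any single region exceeds frac of the
# call's length
max_overlap_exceeds <- function(calls, regions, frac) {
  hit <- logical(nrow(calls))
  for (ch in unique(calls$chrom)) {
    ri <- regions[regions$chrom == ch, , drop = FALSE]
    if (!nrow(ri)) next
    ci <- which(calls$chrom == ch)
    for (i in ci) {
      ov <- pmax(0, pmin(ri$end, calls$end[i]) -
                    pmax(ri$start, calls$start[i]) + 1)
      len <- calls$end[i] - calls$start[i] + 1
      if (any(ov / len > frac)) hit[i] <- TRUE
    }
  }
  hit
}

# single-linkage clustering of same-class calls by reciprocal overlap;
# returns an integer cluster id per call
cluster_calls <- function(calls, reciprocal_frac) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  cls <- copy_class(calls$copy_state)
  key <- paste(cls, calls$chrom, sep = "\r")
  for (idx in split(seq_len(n), key)) {
    idx <- idx[order(calls$start[idx])]
    s <- calls$start[idx]; e <- calls$end[idx]; len <- e - s + 1
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) && s[b] <= e[a]) {
        ov <- min(e[a], e[b]) - s[b] + 1
        if (ov / len[a] >= reciprocal_frac && ov / len[b] >= reciprocal_frac)
          union2(idx[a], idx[b])
        b <- b + 1L
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Remove CNVs common in the study's own controls
#'
#' Calls of the same class are clustered by reciprocal overlap
#' (single linkage, >= `presence_reciprocal_frac`); for each cluster the
#' control carrier fraction is the number of distinct control carriers over
#' the number of controls, and all member calls (cases and controls) of
#' clusters exceeding `max_control_freq` are removed.
#'
#' @param calls call data.frame.
#' @param samples sample sheet (provides case/control groups).
#' @param thresholds a [filter_thresholds()].
#' @return list with `calls` (retained) and `removed` (count).
#' @export
control_frequency_filter <- function(calls, samples,
                                     thresholds = filter_thresholds()) {
  n_controls <- sum(samples$group == "control")
  if (n_controls == 0) stop("control_frequency_filter: no controls")
  if (nrow(calls) == 0) return(list(calls = calls, removed = 0L))
  cl <- cluster_calls(calls, thresholds$presence_reciprocal_frac)
  grp <- samples$group[match(calls$sample_id, samples$sample_id)]
  drop <- logical(nrow(calls))
  for (idx in split(seq_len(nrow(calls)), cl)) {
    ctrl_carriers <- length(unique(calls$sample_id[idx][grp[idx] == "control"]))
    if (ctrl_carriers / n_controls > thresholds$max_control_freq)
      drop[idx] <- TRUE
  }
  list(calls = calls[!drop, , drop = FALSE], removed = sum(drop))
}
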