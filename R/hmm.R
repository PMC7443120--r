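# Simplified hidden-Markov CNV segmentation over LRR/BAF with GC-wave
# correction. Two bundled parameter profiles ("callerA", "callerB") differ in
# their LRR noise prior and transition penalty, standing in for the two
# independent HMM callers whose consensus feeds the downstream filtering.

# BAF emission mixtures shared by all parameter profiles. Every state carries
# components at 0 and 1 with substantial weight (homozygous markers are
# nearly uninformative across states, so runs of homozygotes cannot mimic a
# deletion) plus a small uniform outlier component for robustness.
baf_mixture <- function(baf_sd = 0.04) {
  list(
    means = list(c(0, 1),                     # CN0: signal is noise
                 c(0, 1),                     # CN1: heterozygote band absent
                 c(0, 0.5, 1),                # CN2
                 c(0, 1 / 3, 2 / 3, 1),       # CN3
                 c(0, 0.25, 0.5, 0.75, 1)),   # CN4
    weights = list(c(0.25, 0.25),
                   c(0.49, 0.49),
                   c(0.32, 0.34, 0.32),
                   c(0.26, 0.23, 0.23, 0.26),
                   c(0.22, 0.18, 0.20, 0.18, 0.22)),
    unif = c(0.5, 0.02, 0.02, 0.02, 0.02),
    baf_sd = baf_sd
  )
}

build_transition <- function(trans_leave, trans_return) {
  eps <- 1e-9
  tm <- matrix(eps, 5, 5)
  cnv <- c(1, 2, 4, 5)
  tm[3, cnv] <- trans_leave / 4
  tm[3, 3] <- 1 - trans_leave - eps  # row normalised below
  for (s in cnv) {
    tm[s, 3] <- trans_return
    tm[s, s] <- 1 - trans_return - 3 * eps
  }
  tm <- tm / rowSums(tm)
  dimnames(tm) <- list(0:4, 0:4)
  tm
}

#' HMM caller parameters
#'
#' Two bundled profiles emulate two independent HMM-based CNV callers:
#' `"callerA"` assumes noisier LRR (sd 0.20) with a milder transition
#' penalty, `"callerB"` assumes cleaner LRR (sd 0.16) with a stiffer one.
#' Both share the BAF emission mixtures. Transitions are
#' distance-independent: a per-marker probability of leaving the diploid
#' state (`trans_leave`, split over the four CNV states) and of returning to
#' it (`trans_return`).
#'
#' @param profile `"callerA"` or `"callerB"`.
#' @param lrr_means named numeric LRR emission means per copy state 0..4,
#'   strictly increasing.
#' @param lrr_sd LRR emission standard deviation (profile default if `NULL`).
#' @param baf_sd BAF cluster standard deviation.
#' @param trans_leave per-marker probability of leaving CN2 (profile default
#'   if `NULL`).
#' @param trans_return per-marker probability of returning to CN2.
#' @return an `hmm_params` list.
#' @export
hmm_params <- function(profile = c("callerA", "callerB"),
                       lrr_means = c(`0` = -3.5, `1` = -0.55, `2` = 0,
                                     `3` = 0.35, `4` = 0.65),
                       lrr_sd = NULL, baf_sd = 0.04,
                       trans_leave = NULL, trans_return = NULL) {
  profile <- match.arg(profile)
  defaults <- list(
    callerA = list(lrr_sd = 0.20, trans_leave = 1e-4, trans_return = 0.02),
    callerB = list(lrr_sd = 0.16, trans_leave = 5e-5, trans_return = 0.015))
  d <- defaults[[profile]]
  if (is.null(lrr_sd)) lrr_sd <- d$lrr_sd
  if (is.null(trans_leave)) trans_leave <- d$trans_leave
  if (is.null(trans_return)) trans_return <- d$trans_return
  if (any(diff(lrr_means) <= 0))
    stop("lrr_means must be strictly increasing in copy number")
  stopifnot(lrr_sd > 0, trans_leave > 0, trans_leave < 1,
            trans_return > 0, trans_return < 1)
  trans <- build_transition(trans_leave, trans_return)
  init <- c(rep(trans_leave / 4, 2), 1 - trans_leave, rep(trans_leave / 4, 2))
  structure(list(profile = profile, lrr_means = unname(lrr_means),
                 lrr_sd = lrr_sd, baf_mix = baf_mixture(baf_sd),
                 trans_leave = trans_leave, trans_return = trans_return,
                 transition = trans, log_trans = log(trans),
                 log_init = log(init)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params %s: lrr_sd %.3g, leave %.2g, return %.2g>\n",
              x$profile, x$lrr_sd, x$trans_leave, x$trans_return))
  invisible(x)
}

caller_param_list <- function(params) {
  list(lrr_means = params$lrr_means, lrr_sd = params$lrr_sd,
       log_init = params$log_init, log_trans = params$log_trans)
}

#' GC-wave adjustment of LRR
#'
#' Replaces LRR with the residuals of a per-chromosome least-squares linear
#' fit of LRR on marker GC content, removing the sinusoidal "genomic wave"
#' artifact. The adjusted LRR has mean zero per chromosome. BAF is unchanged.
#' A chromosome with constant GC is only mean-centred (with a message).
#'
#' @param profile an [intensity_profile()].
#' @param map marker map (provides per-marker `gc`).
#' @return the adjusted [intensity_profile()].
#' @export
gc_adjust_lrr <- function(profile, map) {
  if (length(profile$lrr) != nrow(map))
    stop("profile does not align to the marker map")
  pre <- gc_adjust_pre(map)
  intensity_profile(profile$sample_id, gc_adjust_apply(profile$lrr, pre),
                    profile$baf)
}

# precomputed per-chromosome regression design shared by all samples
gc_adjust_pre <- function(map, quiet = FALSE) {
  blk <- map_blocks(map)
  lapply(seq_along(blk$chrom), function(i) {
    idx <- (blk$start0[i] + 1L):(blk$start0[i] + blk$len[i])
    xc <- map$gc[idx] - mean(map$gc[idx])
    ssx <- sum(xc^2)
    if (ssx == 0 && !quiet)
      message("gc_adjust_lrr: constant GC on chromosome ", blk$chrom[i],
              "; mean-centering only")
    list(idx = idx, xc = xc, ssx = ssx)
  })
}

gc_adjust_apply <- function(lrr, pre) {
  for (p in pre) {
    y <- lrr[p$idx]
    yc <- y - mean(y)
    lrr[p$idx] <- if (p$ssx == 0) yc else yc - (sum(p$xc * yc) / p$ssx) * p$xc
  }
  lrr
}

# contiguous chromosome blocks of a sorted marker map as 0-based offsets;
# also reports chromosomes too short to segment
map_blocks <- function(map) {
  r <- rle(map$chrom)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  list(chrom = r$values, start0 = as.integer(starts),
       len = as.integer(r$lengths))
}

#' Segment an intensity profile into CNV calls
#'
#' Runs the Viterbi path of the five-state HMM per chromosome and turns
#' maximal runs of a non-diploid state into calls. Call boundaries are the
#' first and last marker of the run; `n_markers` is the run length;
#' confidence is the log-likelihood ratio of the called state against
#' diploid summed over the run. Chromosomes with fewer than 2 markers are
#' skipped with a message.
#'
#' @param profile an [intensity_profile()] (typically GC-adjusted).
#' @param map marker map aligned to the profile.
#' @param params an [hmm_params()].
#' @return data.frame of calls with columns `sample_id`, `chrom`, `start`,
#'   `end`, `copy_state`, `n_markers`, `confidence`, `caller`.
#' @export
hmm_segment <- function(profile, map, params = hmm_params("callerA")) {
  if (length(profile$lrr) != nrow(map))
    stop("profile does not align to the marker map")
  blk <- map_blocks(map)
  short <- blk$len < 2
  if (any(short))
    message("hmm_segment: skipping chromosome(s) with < 2 markers: ",
            paste(blk$chrom[short], collapse = ", "))
  # pass every block boundary; blocks of length < 2 are skipped downstream
  blocks <- c(blk$start0, length(profile$lrr))
  res <- cpp_hmm_sample(profile$lrr, profile$baf, as.integer(blocks),
                        list(caller_param_list(params)), params$baf_mix)[[1]]
  calls_from_matrix(res, profile$sample_id, map, params$profile)
}

calls_from_matrix <- function(m, sample_id, map, caller) {
  if (nrow(m) == 0) return(empty_calls())
  data.frame(sample_id = sample_id,
             chrom = map$chrom[m[, 1]],
             start = map$pos[m[, 1]],
             end = map$pos[m[, 2]],
             copy_state = as.integer(m[, 3]),
             n_markers = as.integer(m[, 4]),
             confidence = m[, 5],
             caller = caller,
             stringsAsFactors = FALSE)
}

#' Confidence score of a call
#'
#' The log-likelihood of the segment's emissions under the called state
#' minus the log-likelihood under the diploid state, summed over the
#' segment's markers — positive for well-supported calls and monotone
#' non-decreasing in segment length at fixed per-marker evidence.
#'
#' @param profile the [intensity_profile()] the call was made on.
#' @param map marker map.
#' @param call a single-row call data.frame (or list) with `chrom`, `start`,
#'   `end`, `copy_state`.
#' @param params the [hmm_params()] used for calling.
#' @return numeric confidence score.
#' @export
segment_confidence <- function(profile, map, call,
                               params = hmm_params("callerA")) {
  idx <- markers_in_span(map, norm_chrom(call$chrom), call$start, call$end)
  if (!length(idx)) stop("call spans no markers")
  ll <- cpp_emission_ll(profile$lrr[idx], profile$baf[idx],
                        params$lrr_means, params$lrr_sd, params$baf_mix)
  sum(ll[, call$copy_state + 1L] - ll[, 3L])
}

# Batch segmentation of many samples with both caller profiles, sharing the
# BAF emission computation. `signal` is a function(i) returning the
# (GC-adjusted) intensity_profile of sample i. Returns list(callerA=,
# callerB=) call data.frames.
hmm_segment_cohort <- function(signal, sample_ids, map,
                               params_a = hmm_params("callerA"),
                               params_b = hmm_params("callerB"),
                               chunk = 200L) {
  n <- nrow(map)
  blocks <- {
    blk <- map_blocks(map)
    as.integer(c(blk$start0, n))
  }
  callers <- list(caller_param_list(params_a), caller_param_list(params_b))
  out_a <- list(); out_b <- list()
  ns <- length(sample_ids)
  starts <- seq(1L, ns, by = chunk)
  lrr <- matrix(0, n, min(chunk, ns)); baf <- matrix(0, n, min(chunk, ns))
  for (cs in starts) {
    ce <- min(cs + chunk - 1L, ns)
    k <- ce - cs + 1L
    if (k < ncol(lrr)) { lrr <- lrr[, seq_len(k), drop = FALSE]
                         baf <- baf[, seq_len(k), drop = FALSE] }
    for (j in seq_len(k)) {
      prof <- signal(cs + j - 1L)
      lrr[, j] <- prof$lrr; baf[, j] <- prof$baf
    }
    res <- cpp_hmm_batch(lrr, baf, blocks, callers, params_a$baf_mix)
    for (c in 1:2) {
      m <- res[[c]]
      if (nrow(m) == 0) next
      df <- data.frame(sample_id = sample_ids[cs + m[, 1] - 1],
                       chrom = map$chrom[m[, 2]],
                       start = map$pos[m[, 2]],
                       end = map$pos[m[, 3]],
                       copy_state = as.integer(m[, 4]),
                       n_markers = as.integer(m[, 5]),
                       confidence = m[, 6],
                       caller = if (c == 1) params_a$profile else params_b$profile,
                       stringsAsFactors = FALSE)
      if (c == 1) out_a[[length(out_a) + 1]] <- df
      else out_b[[length(out_b) + 1]] <- df
    }
  }
  list(callerA = if (length(out_a)) do.call(rbind, out_a) else empty_calls(),
       callerB = if (length(out_b)) do.call(rbind, out_b) else empty_calls())
}
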