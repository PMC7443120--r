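# Synthetic cohort generator. Produces sample sheets, marker-level LRR/BAF
# intensity profiles with embedded CNVs, and a ground-truth CNV table, so the
# calling, curation, burden and association stages can be exercised end to
# end without any genotype download. Defaults encode the study conditions:
# 1614 cases / 3922 controls, ~0.8 rare deletions and ~1.1 rare duplications
# per person, case-enriched CNV length burden, and three planted risk
# duplication loci at their published carrier frequencies (with the nested
# full/partial structure of the chr10 locus).

#' Toy SNP-array marker map
#'
#' A deterministic four-chromosome marker grid ("1", "2", "4", "10") with
#' evenly spaced markers and a smooth GC profile. Chromosomes 2, 4 and 10
#' start below the hg19 coordinates of the three published risk loci so those
#' loci fall inside the grid; chromosome 1 is pure background.
#'
#' @param n_per_chrom markers per chromosome.
#' @param spacing marker spacing in bp.
#' @return a `marker_map` data.frame.
#' @export
toy_marker_map <- function(n_per_chrom = 5000, spacing = 1000) {
  chroms <- c("1", "2", "4", "10")
  starts <- c(1e6, 87.4e6, 25.5e6, 47.0e6)
  pieces <- lapply(seq_along(chroms), function(k) {
    i <- seq_len(n_per_chrom)
    gc <- 0.5 + 0.13 * sin(2 * pi * i / 613) + 0.04 * sin(2 * pi * i / 89)
    data.frame(
      marker_id = sprintf("m%s_%05d", chroms[k], i),
      chrom = chroms[k],
      pos = starts[k] + (i - 1) * spacing,
      gc = pmin(0.7, pmax(0.3, gc)),
      stringsAsFactors = FALSE)
  })
  as_marker_map(do.call(rbind, pieces), source = "toy marker map")
}

#' Define a risk duplication locus
#'
#' @param name locus label (used in truth `origin` as `risk_locus:<name>`).
#' @param chrom,start,end locus coordinates (1-based inclusive).
#' @param case_freq,control_freq carrier frequencies per group.
#' @param nested optional list(`start`, `end`, `case_freq`, `control_freq`)
#'   describing a smaller duplication nested inside the locus with its own
#'   carrier frequencies (drawn among non-carriers of the full locus).
#' @return a `risk_locus` list.
#' @export
risk_locus <- function(name, chrom, start, end, case_freq, control_freq,
                       nested = NULL) {
  stopifnot(case_freq >= 0, case_freq <= 1,
            control_freq >= 0, control_freq <= 1)
  if (!is.null(nested)) {
    if (nested$start < start || nested$end > end)
      stop("nested sub-interval must lie within the locus")
  }
  structure(list(name = name, chrom = norm_chrom(chrom),
                 start = start, end = end,
                 case_freq = case_freq, control_freq = control_freq,
                 nested = nested),
            class = "risk_locus")
}

#' The three published risk duplication loci
#'
#' hg19 coordinates with carrier frequencies taken from the reported carrier
#' counts over 1614 cases and 3922 controls: chr2 23/4, chr4 27/6, chr10
#' 64/18 split into 36/0 full-length carriers and 28/18 carriers of the
#' smaller ~300 kb nested duplication.
#'
#' @return list of [risk_locus()] objects.
#' @export
study_risk_loci <- function() {
  list(
    risk_locus("chr2_dup", "2", 87428677, 87965359,
               case_freq = 23 / 1614, control_freq = 4 / 3922),
    risk_locus("chr4_dup", "4", 25554332, 25577184,
               case_freq = 27 / 1614, control_freq = 6 / 3922),
    risk_locus("chr10_dup", "10", 47049547, 47703870,
               case_freq = 36 / 1614, control_freq = 0,
               nested = list(start = 47403871, end = 47703870,
                             case_freq = 28 / 1614,
                             control_freq = 18 / 3922))
  )
}

#' Default common-CNV loci for the toy genome
#'
#' Two polymorphic loci with population frequency above the 10% rarity
#' cutoff, so the common-CNV catalog filter is exercised by the pipeline.
#'
#' @return list of common-locus descriptors.
#' @export
default_common_loci <- function() {
  list(
    list(name = "common_dup_1", chrom = "1", start = 2.0e6, end = 2.15e6,
         frequency = 0.15, copy_state = 3L),
    list(name = "common_del_4", chrom = "4", start = 27.0e6, end = 27.08e6,
         frequency = 0.12, copy_state = 1L)
  )
}

#' Default artifact regions for the toy genome
#'
#' Stand-ins for the segmental-duplication / immunoglobulin / centromeric
#' regions that are masked before association testing.
#'
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
default_artifact_regions <- function() {
  data.frame(chrom = c("1", "10"),
             start = c(4.5e6, 51.0e6),
             end = c(4.6e6, 51.12e6),
             name = c("artifact_segdup", "artifact_igh"),
             stringsAsFactors = FALSE)
}

#' Toy gene models
#'
#' Synthetic gene models (with exon blocks) covering the three risk loci and
#' a handful of background genes on chromosome 1, for the exon-conditioned
#' gene-based association test. The chr4 gene mimics the published situation
#' where only exon 1 lies inside the duplicated interval; the chr10 genes are
#' split between the case-only distinguishing region and the shared ~300 kb
#' segment.
#'
#' @return data.frame as returned by [read_gene_models()].
#' @export
toy_gene_models <- function() {
  gene <- function(name, chrom, start, end, exon_starts, exon_len = 2000) {
    list(name = name, chrom = chrom, start = start, end = end,
         exons = data.frame(start = exon_starts,
                            end = exon_starts + exon_len - 1))
  }
  gl <- list(
    gene("G2A", "2", 87500000, 87700000,
         c(87505000, 87560000, 87620000, 87690000)),
    gene("G4A", "4", 25554900, 25610000,
         c(25556000, 25585000, 25600000, 25607000), exon_len = 3000),
    gene("G10A", "10", 47060000, 47200000,
         c(47062000, 47110000, 47150000, 47195000)),
    gene("G10B", "10", 47250000, 47390000,
         c(47252000, 47300000, 47385000)),
    gene("G10C", "10", 47450000, 47650000,
         c(47452000, 47520000, 47600000, 47645000)),
    gene("BG1", "1", 1.2e6, 1.35e6, c(1.201e6, 1.26e6, 1.34e6)),
    gene("BG2", "1", 2.8e6, 2.95e6, c(2.81e6, 2.87e6, 2.94e6)),
    gene("BG3", "1", 3.9e6, 4.1e6, c(3.91e6, 4.0e6, 4.09e6)),
    gene("BG4", "1", 5.1e6, 5.3e6, c(5.11e6, 5.2e6, 5.29e6))
  )
  out <- data.frame(name = vapply(gl, `[[`, "", "name"),
                    chrom = vapply(gl, `[[`, "", "chrom"),
                    start = vapply(gl, `[[`, 0, "start"),
                    end = vapply(gl, `[[`, 0, "end"),
                    stringsAsFactors = FALSE)
  out$exons <- lapply(gl, `[[`, "exons")
  out
}

#' Cohort simulation configuration
#'
#' Defaults are the study conditions: cohort sizes 1614/3922, background
#' rare-CNV rates of 0.8 deletions and 1.1 duplications per person,
#' log-normal CNV lengths parameterised by the reported group mean total
#' lengths (deletions 220.7/177.8 kb, duplications 419.6/258 kb for
#' cases/controls, so the per-CNV mean is total/rate), and the three
#' published risk duplication loci at their published carrier frequencies.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param del_rate,dup_rate mean background rare deletions / duplications per
#'   person (Poisson).
#' @param del_total_mean,dup_total_mean named numeric `c(case=, control=)`
#'   mean total background CNV length per person in bp; the per-CNV
#'   log-normal mean is `total / rate`.
#' @param length_sdlog log-scale standard deviation of CNV lengths.
#' @param risk_loci list of [risk_locus()] objects.
#' @param common_loci list of common-CNV loci (see [default_common_loci()]).
#' @param artifact_regions data.frame of artifact regions (BED-like, 1-based).
#' @param gene_models gene models data.frame (see [toy_gene_models()]).
#' @param lrr_means named numeric of LRR mean shift per copy state 0..4.
#' @param lrr_sd per-marker LRR noise standard deviation.
#' @param baf_sd per-marker BAF noise standard deviation.
#' @param wave_gain scale of the GC-correlated LRR waviness; the wave added
#'   to a sample is `wf * wave_gain * standardised(gc)`.
#' @param qc_fail_frac fraction of samples given QC metrics beyond the
#'   exclusion thresholds.
#' @param family_frac fraction of case samples grouped into families whose
#'   members share risk-locus carrier status.
#' @param seed integer seed; cohorts are deterministic given the seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 1614, n_controls = 3922,
                          del_rate = 0.8, dup_rate = 1.1,
                          del_total_mean = c(case = 220.7e3, control = 177.8e3),
                          dup_total_mean = c(case = 419.6e3, control = 258e3),
                          length_sdlog = 0.7,
                          risk_loci = study_risk_loci(),
                          common_loci = default_common_loci(),
                          artifact_regions = default_artifact_regions(),
                          gene_models = toy_gene_models(),
                          lrr_means = c(`0` = -3.5, `1` = -0.55, `2` = 0,
                                        `3` = 0.35, `4` = 0.65),
                          lrr_sd = 0.18, baf_sd = 0.03, wave_gain = 1,
                          qc_fail_frac = 0.02, family_frac = 0.05,
                          seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            del_rate >= 0, dup_rate >= 0, length_sdlog > 0,
            lrr_sd >= 0, baf_sd >= 0,
            qc_fail_frac >= 0, qc_fail_frac <= 1,
            family_frac >= 0, family_frac <= 1)
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    del_rate = del_rate, dup_rate = dup_rate,
    del_total_mean = del_total_mean, dup_total_mean = dup_total_mean,
    length_sdlog = length_sdlog,
    risk_loci = risk_loci, common_loci = common_loci,
    artifact_regions = artifact_regions, gene_models = gene_models,
    lrr_means = lrr_means, lrr_sd = lrr_sd, baf_sd = baf_sd,
    wave_gain = wave_gain,
    qc_fail_frac = qc_fail_frac, family_frac = family_frac,
    seed = as.integer(seed)), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  cohort: %d cases / %d controls (seed %d)\n",
              x$n_cases, x$n_controls, x$seed))
  cat(sprintf("  background rates: %.3g del + %.3g dup per person\n",
              x$del_rate, x$dup_rate))
  cat(sprintf("  risk loci: %s\n",
              paste(vapply(x$risk_loci, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  noise: lrr_sd %.3g, baf_sd %.3g, wave gain %.3g\n",
              x$lrr_sd, x$baf_sd, x$wave_gain))
  invisible(x)
}

#' Scaled study configuration for the toy genome
#'
#' The toy genome holds 20,000 markers (about 1/35 of a genotyping array), so
#' the full per-person background CNV load cannot be transplanted: at the
#' published rates and lengths the toy genome would be tiled many times over
#' and the reciprocal-overlap machinery (the 1%-in-controls filter, the
#' breakpoint carrier sets) would degenerate. This configuration scales the
#' background load to the toy genome — rates 0.11 deletions and 0.15
#' duplications per person, per-CNV mean lengths about one fifth of the
#' published per-CNV means, preserving the published case:control length
#' ratios — while keeping cohort sizes and the three risk loci at their
#' published carrier frequencies, exactly. See the methods vignette for the
#' derivation.
#'
#' @param seed integer seed.
#' @return a [cohort_config()].
#' @export
scaled_study_config <- function(seed = 1L) {
  # full-scale per-CNV means: total/rate = 275.9/222.25 kb (del),
  # 381.5/234.5 kb (dup); scaled by 1/5 and re-expressed as totals at the
  # scaled rates so cohort_config's total/rate parameterisation is preserved.
  del_mean <- c(case = 275.9e3, control = 222.25e3) / 5
  dup_mean <- c(case = 381.45e3, control = 234.5e3) / 5
  cohort_config(
    del_rate = 0.11, dup_rate = 0.15,
    del_total_mean = 0.11 * del_mean,
    dup_total_mean = 0.15 * dup_mean,
    length_sdlog = 0.7,
    qc_fail_frac = 0, family_frac = 0,
    seed = seed)
}

snap_span <- function(mi, chrom, start, end, what = "locus") {
  ci <- mi[[chrom]]
  if (!is.null(ci)) {
    lo <- findInterval(start - 0.5, ci$pos) + 1L
    hi <- findInterval(end + 0.5, ci$pos)
  }
  if (is.null(ci) || hi < lo)
    stop(what, " ", chrom, ":", format_pos(start), "-", format_pos(end),
         " contains no markers")
  list(lo = lo, hi = hi, pos = ci$pos, n = length(ci$pos))
}

#' Generate a synthetic cohort
#'
#' Draws sample metadata (group, subtype, family structure, QC metrics) and
#' a ground-truth CNV table: per-sample background rare CNVs, common CNVs at
#' the configured polymorphic loci, and independent Bernoulli carrier draws
#' at each risk locus at the group-specific frequency. Risk-locus carriers
#' receive the configured boundaries with a jitter of 0-2 markers per
#' endpoint, so different carriers have different breakpoints. All truth
#' interval endpoints coincide with marker positions. Deterministic given
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param map a `marker_map`.
#' @return a `cnv_cohort` list with elements `samples` (sample sheet
#'   data.frame), `truth` (data.frame with columns `sample_id`, `chrom`,
#'   `start`, `end`, `copy_state`, `origin`) and `config`.
#' @export
generate_cohort <- function(config, map = toy_marker_map()) {
  set.seed(config$seed)
  mi <- map_index(map)
  n_cases <- config$n_cases; n_controls <- config$n_controls
  n <- n_cases + n_controls
  group <- rep(c("case", "control"), c(n_cases, n_controls))
  sample_id <- sprintf("%s_%04d", ifelse(group == "case", "case", "ctrl"),
                       c(seq_len(n_cases), seq_len(n_controls)))

  subtype <- rep("none", n)
  subtype[group == "case"] <- sample(
    c("nonaccommodative", "infantile", "accommodative"), n_cases,
    replace = TRUE, prob = c(1075, 317, 224) / 1614)

  # QC metrics: well-behaved by default, a configured fraction pushed past
  # the exclusion thresholds on one randomly chosen metric
  lrr_sd_m <- pmin(0.28, pmax(0.06, rnorm(n, 0.16, 0.035)))
  wf_m <- pmin(0.4, pmax(-0.4, rnorm(n, 0, 0.05)))
  baf_drift_m <- abs(rnorm(n, 0, 0.002))
  baf_drift_m <- pmin(baf_drift_m, 0.009)
  call_rate_m <- 0.985 + 0.015 * rbeta(n, 3, 1)
  n_fail <- round(config$qc_fail_frac * n)
  if (n_fail > 0) {
    fail_idx <- sample.int(n, n_fail)
    kind <- sample(4, n_fail, replace = TRUE)
    lrr_sd_m[fail_idx[kind == 1]] <- runif(sum(kind == 1), 0.31, 0.5)
    wf_m[fail_idx[kind == 2]] <-
      sample(c(-1, 1), sum(kind == 2), TRUE) * runif(sum(kind == 2), 0.44, 0.7)
    baf_drift_m[fail_idx[kind == 3]] <- runif(sum(kind == 3), 0.011, 0.03)
    call_rate_m[fail_idx[kind == 4]] <- runif(sum(kind == 4), 0.9, 0.979)
  }

  # family structure: a fraction of cases grouped into families of 2-3 whose
  # members share risk-locus carrier status (index = first member)
  family_id <- rep(NA_character_, n)
  families <- list()
  n_fam_members <- round(config$family_frac * n_cases)
  if (n_fam_members >= 2) {
    pool <- sample.int(n_cases, n_fam_members)
    f <- 0L
    while (length(pool) >= 2) {
      size <- min(length(pool), sample(2:3, 1))
      f <- f + 1L
      members <- pool[seq_len(size)]
      pool <- pool[-seq_len(size)]
      family_id[members] <- sprintf("F%03d", f)
      families[[f]] <- members
    }
  }

  samples <- data.frame(sample_id = sample_id, group = group,
                        subtype = subtype, family_id = family_id,
                        call_rate = call_rate_m, lrr_sd = lrr_sd_m,
                        wf = wf_m, baf_drift = baf_drift_m,
                        stringsAsFactors = FALSE)

  truth <- list()

  # risk loci: independent Bernoulli carrier draws at group frequencies,
  # exact configured boundaries plus 0-2 markers of jitter per endpoint
  plant_locus <- function(chrom, start, end, case_freq, control_freq,
                          origin) {
    sp <- snap_span(mi, chrom, start, end, what = paste("risk locus", origin))
    freq <- ifelse(group == "case", case_freq, control_freq)
    carrier <- which(runif(n) < freq)
    if (!length(carrier)) return(NULL)
    k <- length(carrier)
    lo <- pmin(pmax(sp$lo + sample(-2:2, k, TRUE), 1L), sp$n)
    hi <- pmin(pmax(sp$hi + sample(-2:2, k, TRUE), lo), sp$n)
    data.frame(sample_id = sample_id[carrier], chrom = chrom,
               start = sp$pos[lo], end = sp$pos[hi], copy_state = 3L,
               origin = origin, stringsAsFactors = FALSE)
  }
  for (rl in config$risk_loci) {
    full <- plant_locus(rl$chrom, rl$start, rl$end, rl$case_freq,
                        rl$control_freq, paste0("risk_locus:", rl$name))
    truth <- c(truth, list(full))
    if (!is.null(rl$nested)) {
      ns <- rl$nested
      nested <- plant_locus(rl$chrom, ns$start, ns$end, ns$case_freq,
                            ns$control_freq,
                            paste0("risk_locus:", rl$name))
      if (!is.null(nested) && !is.null(full)) {
        # a sample carries at most one form of the duplication
        nested <- nested[!(nested$sample_id %in% full$sample_id), ,
                         drop = FALSE]
      }
      truth <- c(truth, list(nested))
    }
  }

  # common CNV loci at population frequency, identical in both groups
  for (cl in config$common_loci) {
    sp <- snap_span(mi, cl$chrom, cl$start, cl$end,
                    what = paste("common locus", cl$name))
    carrier <- which(runif(n) < cl$frequency)
    if (!length(carrier)) next
    truth <- c(truth, list(data.frame(
      sample_id = sample_id[carrier], chrom = cl$chrom,
      start = sp$pos[sp$lo], end = sp$pos[sp$hi],
      copy_state = as.integer(cl$copy_state), origin = "common",
      stringsAsFactors = FALSE)))
  }

  # background rare CNVs: Poisson count per person, log-normal lengths with
  # group-specific means (total/rate), placed uniformly over markers
  chrom_names <- names(mi)
  chrom_sizes <- vapply(mi, function(ci) length(ci$idx), 0L)
  draw_background <- function(rate, total_mean, states, state_probs,
                              origin) {
    counts <- rpois(n, rate)
    tot <- sum(counts)
    if (tot == 0) return(NULL)
    who <- rep.int(seq_len(n), counts)
    mean_len <- unname(total_mean[ifelse(group[who] == "case",
                                         "case", "control")]) / rate
    len <- rlnorm(tot, log(mean_len) - config$length_sdlog^2 / 2,
                  config$length_sdlog)
    ch <- sample(chrom_names, tot, replace = TRUE,
                 prob = chrom_sizes / sum(chrom_sizes))
    st <- as.integer(sample(states, tot, replace = TRUE, prob = state_probs))
    rows <- vector("list", tot)
    for (j in seq_len(tot)) {
      ci <- mi[[ch[j]]]
      nm <- length(ci$pos)
      lo <- sample.int(nm, 1L)
      hi <- min(nm, lo + max(1L, as.integer(round(
        (len[j] - 1) / max(1, (ci$pos[nm] - ci$pos[1]) / (nm - 1))))))
      rows[[j]] <- list(sample_id[who[j]], ch[j], ci$pos[lo], ci$pos[hi], st[j])
    }
    data.frame(sample_id = vapply(rows, `[[`, "", 1),
               chrom = vapply(rows, `[[`, "", 2),
               start = vapply(rows, `[[`, 0, 3),
               end = vapply(rows, `[[`, 0, 4),
               copy_state = vapply(rows, function(r) r[[5]], 0L),
               origin = origin, stringsAsFactors = FALSE)
  }
  if (config$del_rate > 0)
    truth <- c(truth, list(draw_background(
      config$del_rate, config$del_total_mean, c(1L, 0L), c(0.9, 0.1),
      "background_rare")))
  if (config$dup_rate > 0)
    truth <- c(truth, list(draw_background(
      config$dup_rate, config$dup_total_mean, c(3L, 4L), c(0.85, 0.15),
      "background_rare")))

  truth <- do.call(rbind, Filter(Negate(is.null), truth))
  if (is.null(truth) || nrow(truth) == 0) {
    truth <- data.frame(sample_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        copy_state = integer(), origin = character(),
                        stringsAsFactors = FALSE)
  } else {
    truth <- drop_same_sample_overlaps(truth)
  }

  # relatives share the index member's risk-locus carrier status
  if (length(families)) {
    is_risk <- grepl("^risk_locus:", truth$origin)
    for (members in families) {
      idx_id <- sample_id[members[1]]
      rel_ids <- sample_id[members[-1]]
      keep <- !(is_risk & truth$sample_id %in% rel_ids)
      idx_rows <- truth[is_risk & truth$sample_id == idx_id, , drop = FALSE]
      truth <- truth[keep, , drop = FALSE]
      is_risk <- is_risk[keep]
      if (nrow(idx_rows)) {
        add <- do.call(rbind, lapply(rel_ids, function(rid) {
          r <- idx_rows; r$sample_id <- rid; r
        }))
        truth <- rbind(truth, add)
        is_risk <- c(is_risk, rep(TRUE, nrow(add)))
      }
    }
  }

  ord <- order(truth$sample_id, chrom_rank(truth$chrom), truth$start)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL

  structure(list(samples = samples, truth = truth, config = config),
            class = "cnv_cohort")
}

# drop truth rows that overlap an earlier-kept row of the same sample;
# risk-locus and common rows take precedence over background rows
drop_same_sample_overlaps <- function(truth) {
  prio <- ifelse(grepl("^risk_locus:", truth$origin), 0L,
                 ifelse(truth$origin == "common", 1L, 2L))
  ord <- order(truth$sample_id, chrom_rank(truth$chrom), prio, truth$start)
  truth <- truth[ord, , drop = FALSE]
  keep <- logical(nrow(truth))
  kept_end <- list()
  for (i in seq_len(nrow(truth))) {
    key <- paste0(truth$sample_id[i], "|", truth$chrom[i])
    spans <- kept_end[[key]]
    ok <- TRUE
    if (!is.null(spans)) {
      ok <- !any(truth$start[i] <= spans[, 2] & truth$end[i] >= spans[, 1])
    }
    keep[i] <- ok
    if (ok)
      kept_end[[key]] <- rbind(spans, c(truth$start[i], truth$end[i]))
  }
  truth[keep, , drop = FALSE]
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("<cnv_cohort>\n")
  cat(sprintf("  %d cases / %d controls\n",
              sum(x$samples$group == "case"),
              sum(x$samples$group == "control")))
  tab <- table(sub(":.*$", "", x$truth$origin))
  cat(sprintf("  truth CNVs: %d (%s)\n", nrow(x$truth),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Simulate marker-level LRR/BAF intensities for one sample
#'
#' LRR is the per-state mean shift plus Gaussian noise plus a GC-correlated
#' wave scaled by the sample's waviness factor (`wf`). BAF is generated from
#' a genotype model: the B-allele count is binomial in the local copy number,
#' so diploid markers cluster near 0, 0.5 and 1, single-copy deletions lose
#' the heterozygote band, and three-copy duplications cluster near 0, 1/3,
#' 2/3 and 1; copy-zero markers emit uniform noise. Gaussian BAF noise is
#' clipped to \[0, 1\].
#'
#' @param sample one row of a sample sheet (needs `sample_id` and `wf`).
#' @param truth truth CNV data.frame (rows for other samples are ignored).
#' @param map marker map.
#' @param config a [cohort_config()] (noise and LRR shift parameters).
#' @param mi optional precomputed [map_index()] of `map`.
#' @return an [intensity_profile()].
#' @export
simulate_intensities <- function(sample, truth, map, config, mi = NULL) {
  sample_id <- sample$sample_id
  wf <- sample$wf
  truth <- truth[truth$sample_id == sample_id, , drop = FALSE]
  n <- nrow(map)
  if (is.null(mi)) mi <- map_index(map)

  cn <- rep(2L, n)
  if (nrow(truth)) {
    for (j in seq_len(nrow(truth))) {
      idx <- markers_in_span(map, truth$chrom[j], truth$start[j],
                             truth$end[j], mi)
      if (!length(idx))
        stop("truth interval ", truth$chrom[j], ":",
             format_pos(truth$start[j]), "-", format_pos(truth$end[j]),
             " for sample ", sample_id, " spans no markers")
      cn[idx] <- truth$copy_state[j]
    }
  }

  gc <- map$gc
  gsd <- stats::sd(gc)
  wave <- if (is.na(gsd) || gsd == 0) 0 else
    wf * config$wave_gain * (gc - mean(gc)) / gsd
  state_means <- unname(config$lrr_means)  # indexed by copy state + 1
  sig <- cpp_simulate_signal(cn, state_means[cn + 1L] + wave,
                             config$lrr_sd, config$baf_sd)
  structure(list(sample_id = sample_id, lrr = sig$lrr, baf = sig$baf),
            class = "intensity_profile")
}

#' Write a complete simulated fixture to disk
#'
#' Generates a cohort and its intensity profiles and writes marker map,
#' per-sample signal TSVs, sample sheet, truth BED, artifact-region BED,
#' common-CNV catalog BED, gene models (BED12) and a YAML manifest recording
#' the configuration and seed. The write is atomic: files are assembled in a
#' temporary directory that is renamed to `outdir` on success.
#'
#' @param outdir output directory (must not already exist).
#' @param config a [cohort_config()].
#' @param map marker map (default [toy_marker_map()]).
#' @return `outdir`, invisibly.
#' @export
emit_fixture <- function(outdir, config, map = toy_marker_map()) {
  if (file.exists(outdir)) stop("output directory ", outdir, " already exists")
  tmp <- paste0(outdir, ".tmp", Sys.getpid())
  dir.create(tmp, recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)

  cohort <- generate_cohort(config, map)
  mi <- map_index(map)

  utils::write.table(
    data.frame(marker_id = map$marker_id, chrom = map$chrom,
               pos = format_pos(map$pos), gc = map$gc),
    file.path(tmp, "markers.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_sample_sheet(cohort$samples, file.path(tmp, "samples.tsv"))
  write_truth_bed(cohort$truth, file.path(tmp, "truth.bed"))
  write_bed_regions(config$artifact_regions, file.path(tmp, "artifacts.bed"))
  common <- do.call(rbind, lapply(config$common_loci, function(cl)
    data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
               name = cl$name, frequency = cl$frequency,
               stringsAsFactors = FALSE)))
  write_bed_regions(common, file.path(tmp, "common_cnv.bed"),
                    with_frequency = TRUE)
  write_gene_models(config$gene_models, file.path(tmp, "genes.bed"))

  sigdir <- file.path(tmp, "signals")
  dir.create(sigdir)
  for (i in seq_len(nrow(cohort$samples))) {
    prof <- simulate_intensities(cohort$samples[i, ], cohort$truth, map,
                                 config, mi)
    write_signal(prof, map, file.path(sigdir, paste0(prof$sample_id, ".tsv")))
  }

  manifest <- list(seed = config$seed,
                   n_cases = config$n_cases, n_controls = config$n_controls,
                   config = config_to_list(config))
  yaml::write_yaml(manifest, file.path(tmp, "manifest.yaml"))

  if (!file.rename(tmp, outdir))
    stop("could not move fixture into place at ", outdir)
  on.exit()
  invisible(outdir)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$artifact_regions <- as.list(out$artifact_regions)
  out$gene_models <- lapply(seq_len(nrow(out$gene_models)), function(i) {
    g <- out$gene_models[i, ]
    list(name = g$name, chrom = g$chrom, start = g$start, end = g$end,
         exon_start = g$exons[[1]]$start, exon_end = g$exons[[1]]$end)
  })
  out$risk_loci <- lapply(out$risk_loci, unclass)
  out
}
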