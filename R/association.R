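# Locus-level association testing: carrier 2x2 tables and odds ratios,
# segmental (breakpoint) and exon-conditioned gene-based tests with
# label-swapping permutations and max(T) family-wise correction,
# full/partial classification of carriers at a nested duplication, and the
# subtype chi-square.

#' Carrier 2x2 table
#'
#' Builds the table from counts: `a` case carriers, `b` case non-carriers,
#' `c` control carriers, `d` control non-carriers.
#'
#' @param a,b,c,d non-negative counts.
#' @return a `carrier_table` object.
#' @export
carrier_table_counts <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = a, b = b, c = c, d = d), class = "carrier_table")
}

#' @export
print.carrier_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

#' Carrier table at a locus
#'
#' A sample is a carrier iff it has at least one retained call of the given
#' class overlapping the locus by >= 1 bp (configurable via `min_overlap`);
#' samples with several overlapping calls are counted once.
#'
#' @param calls curated call data.frame.
#' @param samples sample sheet partitioned into cases/controls.
#' @param locus a [genomic_interval()].
#' @param class `"DUP"` or `"DEL"`.
#' @param min_overlap minimum overlap in bp to count as a carrier.
#' @return a `carrier_table`.
#' @export
carrier_table <- function(calls, samples, locus, class = c("DUP", "DEL"),
                          min_overlap = 1) {
  class <- match.arg(class)
  locus <- as_interval(locus)
  carriers <- character(0)
  if (nrow(calls)) {
    sel <- copy_class(calls$copy_state) == class & calls$chrom == locus$chrom
    if (any(sel)) {
      ov <- pmin(calls$end[sel], locus$end) -
        pmax(calls$start[sel], locus$start) + 1
      carriers <- unique(calls$sample_id[sel][ov >= min_overlap])
    }
  }
  grp <- samples$group
  is_car <- samples$sample_id %in% carriers
  carrier_table_counts(sum(is_car & grp == "case"),
                       sum(!is_car & grp == "case"),
                       sum(is_car & grp == "control"),
                       sum(!is_car & grp == "control"))
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a d) / (b c)` with a log-scale (Woolf) interval. When any cell is
#' zero, the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied and flagged; the uncorrected OR may then be 0 or infinite.
#'
#' @param table a [carrier_table_counts()] (or list with `a`, `b`, `c`, `d`).
#' @param level confidence level.
#' @return list with `or`, `lower`, `upper`, `haldane`, `or_raw`.
#' @export
odds_ratio_ci <- function(table, level = 0.95) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  haldane <- any(c(a, b, c, d) == 0)
  or_raw <- (a * d) / (b * c)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       haldane = haldane, or_raw = or_raw)
}

pearson_chisq_2x2 <- function(a, k, n1, n0) {
  N <- n1 + n0
  b <- n1 - a; c <- k - a; d <- n0 - (k - a)
  den <- n1 * n0 * k * (N - k)
  if (den <= 0) return(0)
  N * (a * d - b * c)^2 / den
}

# Build carrier sets at every unique breakpoint position of the class, then
# collapse adjacent positions with identical carrier sets into segments.
# Returns a list of segments: chrom, start, end, carriers (sample ids).
breakpoint_carrier_segments <- function(calls, class) {
  sel <- copy_class(calls$copy_state) == class
  calls <- calls[sel, , drop = FALSE]
  if (!nrow(calls)) return(list())
  segments <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    pos <- sort(unique(c(cc$start, cc$end)))
    prev_key <- NULL
    for (p in pos) {
      cov <- cc$start <= p & cc$end >= p
      carriers <- sort(unique(cc$sample_id[cov]))
      if (!length(carriers)) next
      key <- paste(carriers, collapse = "\r")
      if (identical(key, prev_key)) {
        segments[[length(segments)]]$end <- p
      } else {
        segments[[length(segments) + 1]] <-
          list(chrom = ch, start = p, end = p, carriers = carriers)
        prev_key <- key
      }
    }
  }
  segments
}

run_carrier_perm <- function(segments, samples, n_perm, seed, one_sided) {
  if (!is.null(seed)) set.seed(seed)
  is_case <- as.integer(samples$group == "case")
  sets <- lapply(segments, function(s)
    match(s$carriers, samples$sample_id))
  if (any(vapply(sets, anyNA, TRUE)))
    stop("calls reference samples absent from the sample sheet")
  res <- cpp_perm_carrier_test(sets, is_case, as.integer(n_perm),
                               one_sided)
  n1 <- sum(is_case); n0 <- length(is_case) - n1
  rows <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    k <- length(s$carriers)
    a <- sum(is_case[sets[[i]]])
    orci <- odds_ratio_ci(carrier_table_counts(a, n1 - a, k - a,
                                               n0 - (k - a)))
    data.frame(locus = paste0(s$chrom, ":", format_pos(s$start), "-",
                              format_pos(s$end)),
               chrom = s$chrom, start = s$start, end = s$end,
               n_case_carriers = a, n_control_carriers = k - a,
               or = orci$or, statistic = res$obs[i],
               p_point = (res$point[i] + 1) / (n_perm + 1),
               p_corr = (res$maxcnt[i] + 1) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Segmental (breakpoint) association test
#'
#' Evaluation positions are the unique start/end positions of the retained
#' calls of the class; at each position the statistic is the Pearson
#' chi-square of the carrier 2x2 table of calls covering it. Pointwise
#' empirical p values use `(r + 1) / (n_perm + 1)` under case/control label
#' swapping preserving group sizes; the genome-wide corrected p compares the
#' observed statistic with the per-permutation maximum over all positions
#' (the max(T) method). Adjacent positions with identical carrier sets are
#' collapsed into one reported segment. Deterministic given `seed`.
#'
#' @param calls curated call data.frame.
#' @param samples sample sheet.
#' @param class `"DUP"` or `"DEL"`.
#' @param n_perm number of label-swapping permutations.
#' @param seed optional seed.
#' @param alternative `"two.sided"` (default) or `"case_enriched"` (the
#'   statistic is zeroed when controls are enriched).
#' @return a `cnv_assoc` data.frame, one row per collapsed segment, with
#'   carrier counts, odds ratio, statistic, `p_point` and `p_corr`.
#' @export
segmental_test <- function(calls, samples, class = c("DUP", "DEL"),
                           n_perm = 10000, seed = NULL,
                           alternative = c("two.sided", "case_enriched")) {
  class <- match.arg(class)
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1)
  segments <- breakpoint_carrier_segments(calls, class)
  if (!length(segments)) {
    out <- data.frame(locus = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_case_carriers = integer(),
                      n_control_carriers = integer(), or = numeric(),
                      statistic = numeric(), p_point = numeric(),
                      p_corr = numeric(), stringsAsFactors = FALSE)
    return(as_cnv_assoc(out, class, n_perm, seed, "segmental"))
  }
  out <- run_carrier_perm(segments, samples, n_perm, seed,
                          alternative == "case_enriched")
  as_cnv_assoc(out, class, n_perm, seed, "segmental")
}

#' Exon-conditioned gene-based association test
#'
#' A call counts towards a gene iff it overlaps at least one exonic bp of
#' the gene. Per-gene carrier tables, statistics and max(T) correction are
#' as in [segmental_test()]. Genes without exon models are skipped with a
#' message.
#'
#' @param calls curated call data.frame.
#' @param samples sample sheet.
#' @param genes gene models (see [read_gene_models()] / [toy_gene_models()]).
#' @param class `"DUP"` or `"DEL"`.
#' @param n_perm,seed,alternative as in [segmental_test()].
#' @return a `cnv_assoc` data.frame, one row per gene with >= 1 carrier.
#' @export
gene_test <- function(calls, samples, genes, class = c("DUP", "DEL"),
                      n_perm = 10000, seed = NULL,
                      alternative = c("two.sided", "case_enriched")) {
  class <- match.arg(class)
  alternative <- match.arg(alternative)
  sel <- nrow(calls) > 0 & copy_class(calls$copy_state) == class
  cc <- calls[sel, , drop = FALSE]
  segments <- list()
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0) {
      message("gene_test: skipping gene without exon model: ", genes$name[i])
      next
    }
    carriers <- character(0)
    gi <- which(cc$chrom == genes$chrom[i])
    if (length(gi)) {
      hit <- vapply(gi, function(j) {
        any(pmin(ex$end, cc$end[j]) - pmax(ex$start, cc$start[j]) + 1 >= 1)
      }, TRUE)
      carriers <- sort(unique(cc$sample_id[gi[hit]]))
    }
    if (!length(carriers)) next
    segments[[length(segments) + 1]] <-
      list(chrom = genes$chrom[i], start = genes$start[i],
           end = genes$end[i], carriers = carriers, name = genes$name[i])
  }
  if (!length(segments)) {
    out <- data.frame(locus = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_case_carriers = integer(),
                      n_control_carriers = integer(), or = numeric(),
                      statistic = numeric(), p_point = numeric(),
                      p_corr = numeric(), stringsAsFactors = FALSE)
    return(as_cnv_assoc(out, class, n_perm, seed, "gene"))
  }
  out <- run_carrier_perm(segments, samples, n_perm, seed,
                          alternative == "case_enriched")
  out$locus <- vapply(segments, `[[`, "", "name")
  as_cnv_assoc(out, class, n_perm, seed, "gene")
}

as_cnv_assoc <- function(df, class, n_perm, seed, test) {
  structure(df, class = c("cnv_assoc", "data.frame"),
            cnv_class = class, n_perm = n_perm, seed = seed, test = test)
}

#' @export
print.cnv_assoc <- function(x, n = 10, ...) {
  if (!all(c("p_corr", "p_point", "statistic") %in% names(x)))
    return(print.data.frame(x))
  cat(sprintf("CNV %s association test (%s class, %d permutations)\n",
              attr(x, "test"), attr(x, "cnv_class"), attr(x, "n_perm")))
  cat(sprintf("%d loci; minimum attainable p = %.3g\n", nrow(x),
              1 / (attr(x, "n_perm") + 1)))
  if (nrow(x)) {
    ord <- order(x$p_corr, x$p_point, -x$statistic)
    print.data.frame(head(x[ord, , drop = FALSE], n), digits = 4,
                     row.names = FALSE)
    if (nrow(x) > n) cat("... (", nrow(x) - n, " more loci)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cnv_assoc <- function(object, alpha = 0.05, ...) {
  sig <- object[object$p_corr <= alpha, , drop = FALSE]
  cat(sprintf("%d of %d loci genome-wide significant at corrected p <= %g\n",
              nrow(sig), nrow(object), alpha))
  if (nrow(sig)) print.data.frame(sig, digits = 4, row.names = FALSE)
  invisible(sig)
}

#' Manhattan-style plot of association results
#'
#' @param x a `cnv_assoc` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cnv_assoc <- function(x, ...) {
  if (!nrow(x)) { graphics::plot.new(); return(invisible(x)) }
  chroms <- unique(x$chrom)
  offset <- setNames(cumsum(c(0, vapply(chroms, function(ch)
    max(x$end[x$chrom == ch]) * 1.05, 0)))[seq_along(chroms)], chroms)
  pos <- offset[x$chrom] + (x$start + x$end) / 2
  graphics::plot(pos, -log10(x$p_corr), pch = 19, cex = 0.6,
                 col = (match(x$chrom, chroms) %% 2) + 1,
                 xlab = "genome position", xaxt = "n",
                 ylab = expression(-log[10](p[corr])), ...)
  graphics::axis(1, at = offset + diff(c(offset, max(pos))) / 2,
                 labels = chroms)
  graphics::abline(h = -log10(1 / (attr(x, "n_perm") + 1)), lty = 2)
  invisible(x)
}

#' Classify carriers at a nested duplication locus
#'
#' Distinguishes carriers of the full-length duplication from carriers of
#' the smaller shared segment: `full` = the sample's call(s) of the class
#' overlap the distinguishing (full-only) region by >= 1 bp; `partial` =
#' carrier at the full locus but not the distinguishing region; `none`
#' otherwise.
#'
#' @param calls curated call data.frame.
#' @param samples sample sheet.
#' @param full_locus the full locus interval.
#' @param distinguishing_region sub-interval present only in full-length
#'   carriers (must lie within `full_locus`).
#' @param class `"DUP"` or `"DEL"`.
#' @return data.frame with `sample_id`, `group`, `label`.
#' @export
classify_nested_carriers <- function(calls, samples, full_locus,
                                     distinguishing_region,
                                     class = c("DUP", "DEL")) {
  class <- match.arg(class)
  full_locus <- as_interval(full_locus)
  distinguishing_region <- as_interval(distinguishing_region)
  if (distinguishing_region$chrom != full_locus$chrom ||
      distinguishing_region$start < full_locus$start ||
      distinguishing_region$end > full_locus$end)
    stop("distinguishing_region must lie within full_locus")
  sel <- nrow(calls) > 0 & copy_class(calls$copy_state) == class &
    calls$chrom == full_locus$chrom
  cc <- calls[sel, , drop = FALSE]
  ov_full <- pmax(0, pmin(cc$end, full_locus$end) -
                    pmax(cc$start, full_locus$start) + 1)
  ov_dist <- pmax(0, pmin(cc$end, distinguishing_region$end) -
                    pmax(cc$start, distinguishing_region$start) + 1)
  at_locus <- unique(cc$sample_id[ov_full >= 1])
  at_dist <- unique(cc$sample_id[ov_dist >= 1])
  label <- ifelse(samples$sample_id %in% at_dist, "full",
                  ifelse(samples$sample_id %in% at_locus, "partial", "none"))
  data.frame(sample_id = samples$sample_id, group = samples$group,
             label = label, stringsAsFactors = FALSE)
}

#' Subtype-by-locus chi-square test
#'
#' Pearson chi-square of a contingency table of phenotype subtype against
#' locus group, with `df = (rows - 1)(columns - 1)`.
#'
#' @param table a count matrix with at least 2 rows and 2 columns.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
subtype_chisq <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("subtype_chisq needs at least 2 rows and 2 columns")
  if (any(table < 0)) stop("counts must be non-negative")
  rz <- rowSums(table) == 0; cz <- colSums(table) == 0
  if (any(rz)) stop("zero row margin: ",
                    paste(rownames(table)[rz], which(rz), collapse = ", "))
  if (any(cz)) stop("zero column margin: ",
                    paste(colnames(table)[cz], which(cz), collapse = ", "))
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Keep one sample per family
#'
#' From each family (shared `family_id`) the member with the best intensity
#' quality (lowest `lrr_sd`) is kept; samples without a family are kept.
#' Used to re-run association tests on an unrelated subset.
#'
#' @param samples sample sheet.
#' @return subset of `samples`.
#' @export
keep_unrelated <- function(samples) {
  has_fam <- !is.na(samples$family_id)
  keep <- !has_fam
  for (fid in unique(samples$family_id[has_fam])) {
    idx <- which(samples$family_id == fid & has_fam)
    keep[idx[which.min(samples$lrr_sd[idx])]] <- TRUE
  }
  samples[keep, , drop = FALSE]
}
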