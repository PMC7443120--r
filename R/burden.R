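# Per-sample rare-CNV burden summaries and case-control burden comparisons:
# label-swapping permutation tests of group mean differences, and
# size/frequency-partitioned 2x2 odds ratios with Woolf confidence intervals
# and Fisher exact p values.

#' Per-sample CNV burden summary
#'
#' One row per sample in `samples` (zeros for samples with no calls):
#' deletion and duplication counts, total lengths, and mean lengths (`NA`
#' when the count is zero).
#'
#' @param calls curated call data.frame.
#' @param samples sample sheet.
#' @return data.frame of burden summaries.
#' @export
summarize_burden <- function(calls, samples) {
  unknown <- setdiff(calls$sample_id, samples$sample_id)
  if (length(unknown))
    stop("calls reference unknown sample(s): ",
         paste(head(unknown, 3), collapse = ", "))
  out <- data.frame(sample_id = samples$sample_id,
                    n_del = 0L, n_dup = 0L,
                    total_len_del = 0, total_len_dup = 0,
                    mean_len_del = NA_real_, mean_len_dup = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(calls)) {
    cls <- copy_class(calls$copy_state)
    len <- calls$end - calls$start + 1
    for (class in c("DEL", "DUP")) {
      sel <- cls == class
      cnt <- table(factor(calls$sample_id[sel], levels = samples$sample_id))
      tot <- tapply(len[sel], factor(calls$sample_id[sel],
                                     levels = samples$sample_id), sum)
      tot[is.na(tot)] <- 0
      if (class == "DEL") {
        out$n_del <- as.integer(cnt); out$total_len_del <- as.numeric(tot)
      } else {
        out$n_dup <- as.integer(cnt); out$total_len_dup <- as.numeric(tot)
      }
    }
    out$mean_len_del <- ifelse(out$n_del > 0, out$total_len_del / out$n_del,
                               NA_real_)
    out$mean_len_dup <- ifelse(out$n_dup > 0, out$total_len_dup / out$n_dup,
                               NA_real_)
  }
  out
}

burden_metric_values <- function(summaries, metric) {
  switch(metric,
         rate_del = summaries$n_del,
         rate_dup = summaries$n_dup,
         total_len_del = summaries$total_len_del,
         total_len_dup = summaries$total_len_dup,
         mean_len_del = summaries$mean_len_del,
         mean_len_dup = summaries$mean_len_dup,
         pct_with_del = as.numeric(summaries$n_del > 0),
         pct_with_dup = as.numeric(summaries$n_dup > 0),
         stop("unknown burden metric: ", metric))
}

#' Case-control burden comparison by label permutation
#'
#' The observed statistic is the case mean minus the control mean of the
#' chosen per-sample metric (a proportion difference for the `pct_*`
#' metrics; samples where a mean-length metric is undefined are excluded
#' from the group means). The two-sided empirical p value is
#' `(#{|T*| >= |T|} + 1) / (n_perm + 1)` under random case/control label
#' swapping preserving group sizes.
#'
#' @param summaries output of [summarize_burden()].
#' @param samples sample sheet (same samples).
#' @param metric one of `rate_del`, `rate_dup`, `total_len_del`,
#'   `total_len_dup`, `mean_len_del`, `mean_len_dup`, `pct_with_del`,
#'   `pct_with_dup`.
#' @param n_perm number of permutations.
#' @param seed optional seed (`set.seed` is called when non-`NULL`).
#' @return a `burden_comparison` list.
#' @export
compare_burden <- function(summaries, samples, metric, n_perm = 10000,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grp <- samples$group[match(summaries$sample_id, samples$sample_id)]
  if (sum(grp == "case") < 2 || sum(grp == "control") < 2)
    stop("compare_burden needs at least 2 samples per group")
  x <- burden_metric_values(summaries, metric)
  ok <- !is.na(x)
  if (!any(ok)) stop("metric ", metric, " undefined for every sample")
  x <- x[ok]; grp <- grp[ok]
  n <- length(x); n1 <- sum(grp == "case")
  stat <- function(is_case) mean(x[is_case]) - mean(x[!is_case])
  obs <- stat(grp == "case")
  count <- 0L
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    perm <- logical(n); perm[idx] <- TRUE
    if (abs(stat(perm)) >= abs(obs) - 1e-12) count <- count + 1L
  }
  structure(list(metric = metric,
                 case_mean = mean(x[grp == "case"]),
                 control_mean = mean(x[grp == "control"]),
                 observed = obs,
                 p_value = (count + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "burden_comparison")
}

#' @export
print.burden_comparison <- function(x, ...) {
  cat(sprintf("burden comparison (%s): case %.4g vs control %.4g, p = %.4g (%d permutations)\n",
              x$metric, x$case_mean, x$control_mean, x$p_value, x$n_perm))
  invisible(x)
}

#' Odds ratios across burden bins
#'
#' Partitions samples by their burden (total length or count, per class or
#' combined) into bins delimited by the given thresholds — `(0, t1)`,
#' `[t1, t2)`, ..., `[tk, Inf)`; zero-burden samples fall in no bin — and,
#' for each bin, forms the 2x2 table of bin membership against case/control
#' status (reference = all samples outside the bin). Reports the
#' cross-product odds ratio, a Woolf confidence interval and a two-sided
#' Fisher exact p value; tables with a zero cell get the Haldane-Anscombe
#' 0.5 correction and are flagged.
#'
#' @param summaries output of [summarize_burden()].
#' @param samples sample sheet.
#' @param bins strictly increasing numeric thresholds (bp for `total_*`
#'   kinds, counts for `count_*`).
#' @param kind one of `total_dup`, `total_del`, `total_all`, `count_dup`,
#'   `count_del`.
#' @param level confidence level.
#' @return data.frame, one row per bin, with the 2x2 cells, `or`, `lower`,
#'   `upper`, `fisher_p` and a `haldane` flag.
#' @export
burden_bin_odds <- function(summaries, samples, bins = c(5e5, 1e6),
                            kind = c("total_dup", "total_del", "total_all",
                                     "count_dup", "count_del"),
                            level = 0.95) {
  kind <- match.arg(kind)
  if (any(diff(bins) <= 0)) stop("bins must be strictly increasing")
  x <- switch(kind,
              total_dup = summaries$total_len_dup,
              total_del = summaries$total_len_del,
              total_all = summaries$total_len_del + summaries$total_len_dup,
              count_dup = summaries$n_dup,
              count_del = summaries$n_del)
  grp <- samples$group[match(summaries$sample_id, samples$sample_id)]
  is_case <- grp == "case"
  lo <- c(0, bins); hi <- c(bins, Inf)
  rows <- lapply(seq_along(lo), function(i) {
    exposed <- x > 0 & x >= lo[i] & x < hi[i]
    a <- sum(exposed & is_case); b <- sum(!exposed & is_case)
    c_ <- sum(exposed & !is_case); d <- sum(!exposed & !is_case)
    label <- if (is.infinite(hi[i])) paste0(">=", format_pos(lo[i]))
             else paste0("[", format_pos(lo[i]), ",", format_pos(hi[i]), ")")
    if (a + c_ == 0) {
      return(data.frame(bin = label, case_in = a, case_out = b,
                        control_in = c_, control_out = d,
                        or = NA_real_, lower = NA_real_, upper = NA_real_,
                        fisher_p = NA_real_, haldane = FALSE, empty = TRUE,
                        stringsAsFactors = FALSE))
    }
    orci <- odds_ratio_ci(carrier_table_counts(a, b, c_, d), level = level)
    fp <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    data.frame(bin = label, case_in = a, case_out = b, control_in = c_,
               control_out = d, or = orci$or, lower = orci$lower,
               upper = orci$upper, fisher_p = fp, haldane = orci$haldane,
               empty = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
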