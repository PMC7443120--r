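# Genomic intervals are 1-based and inclusive at both ends, matching the
# convention in which a printed span chr10:47049547-47703870 has length
# end - start + 1. Chromosome labels are plain strings without a "chr" prefix;
# readers strip the prefix at the boundary.

#' Normalise chromosome labels
#'
#' Strips a leading "chr" (any case) and returns a plain string label.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector without "chr" prefixes.
#' @export
norm_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

# order chromosomes numerically where possible, then lexically (X, Y, ...);
# equal labels share a rank so a secondary sort key can break ties
chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(u))
  match(chrom, u[order(is.na(num), num, u)])
}

#' Construct a genomic interval
#'
#' A 1-based, fully inclusive span on a single chromosome. This is the unit
#' of all overlap algebra in the package.
#'
#' @param chrom chromosome label (a leading "chr" is stripped).
#' @param start 1-based inclusive start position (bp).
#' @param end 1-based inclusive end position (bp), `end >= start`.
#' @return an object of class `genomic_interval`: a list with elements
#'   `chrom`, `start`, `end`.
#' @examples
#' gi <- genomic_interval("10", 47049547, 47703870)
#' interval_length(gi)  # 654324 bp
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- norm_chrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop("genomic_interval() takes scalar chrom, start, end")
  if (is.na(start) || is.na(end) || start < 1)
    stop("interval start must be >= 1")
  if (end < start)
    stop("interval end must be >= start (got ", start, "-", end, ")")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval %s:%.0f-%.0f (%.0f bp)>\n",
              x$chrom, x$start, x$end, interval_length(x)))
  invisible(x)
}

as_interval <- function(x) {
  if (inherits(x, "genomic_interval")) return(x)
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x)))
    return(genomic_interval(x$chrom, x$start, x$end))
  stop("cannot interpret object as a genomic interval")
}

#' Length of a genomic interval in bp
#'
#' @param x a [genomic_interval()] (or anything with chrom/start/end fields).
#' @return numeric length `end - start + 1`.
#' @export
interval_length <- function(x) {
  x <- as_interval(x)
  x$end - x$start + 1
}

#' Overlap between two intervals in bp
#'
#' Returns 0 when the chromosomes differ or the spans are disjoint.
#' Symmetric; `overlap_bp(a, a)` equals `interval_length(a)`.
#'
#' @param a,b intervals (see [genomic_interval()]).
#' @return numeric overlap in bp.
#' @export
overlap_bp <- function(a, b) {
  a <- as_interval(a); b <- as_interval(b)
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
}

#' Overlap fraction between two intervals
#'
#' `of_a` divides the overlap by the length of `a`; `reciprocal` is the
#' smaller of the two mutual fractions, the standard criterion for treating
#' two CNV calls as the same event.
#'
#' @param a,b intervals.
#' @param mode `"of_a"` or `"reciprocal"`.
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(a, b, mode = c("of_a", "reciprocal")) {
  mode <- match.arg(mode)
  ov <- overlap_bp(a, b)
  if (mode == "of_a") {
    ov / interval_length(a)
  } else {
    min(ov / interval_length(a), ov / interval_length(b))
  }
}

# Vectorised overlap in bp of one interval against columns chrom/start/end of
# a data.frame. Used by the filtering and carrier machinery.
overlap_bp_vec <- function(chrom, start, end, df) {
  out <- numeric(nrow(df))
  same <- df$chrom == chrom
  if (any(same)) {
    ov <- pmin(df$end[same], end) - pmax(df$start[same], start) + 1
    out[same] <- pmax(0, ov)
  }
  out
}

#' Copy-number class of an integer copy state
#'
#' States 0 and 1 are deletions (`"DEL"`), 3 and 4 duplications (`"DUP"`).
#'
#' @param copy_state integer vector of copy states (2 is not a CNV).
#' @return character vector `"DEL"`/`"DUP"`.
#' @export
copy_class <- function(copy_state) {
  if (any(copy_state == 2)) stop("copy_state 2 is not a CNV")
  ifelse(copy_state < 2, "DEL", "DUP")
}
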