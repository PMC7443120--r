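# Readers and writers for the plain-text formats the pipeline touches:
# marker map TSV, per-sample signal TSV (PennCNV-style layout), sample sheet,
# CNV call TSV, BED region files (0-based half-open, converted at the
# boundary) and BED12 gene models with exon blocks.

read_tsv_checked <- function(path, required, numeric_cols = character()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad))
      stop("malformed row in ", path, ": line ", bad[1] + 1L,
           " has non-numeric '", col, "' value '", df[[col]][bad[1]], "'")
    df[[col]] <- val
  }
  df
}

#' Read a marker map
#'
#' Reads a TSV with columns `marker_id`, `chrom`, `pos`, `gc` describing the
#' SNP-array grid. Records are sorted by (chromosome, position); input that
#' arrives unsorted is sorted silently with a message. Duplicate positions on
#' a chromosome are rejected.
#'
#' @param path path to the marker map TSV.
#' @return a `marker_map` data.frame with columns `marker_id`, `chrom`,
#'   `pos`, `gc`.
#' @export
read_marker_map <- function(path) {
  df <- read_tsv_checked(path, c("marker_id", "chrom", "pos", "gc"),
                         numeric_cols = c("pos", "gc"))
  df$chrom <- norm_chrom(df$chrom)
  as_marker_map(df[c("marker_id", "chrom", "pos", "gc")], source = path)
}

#' Assemble a marker map from columns
#'
#' @param df data.frame with columns `marker_id`, `chrom`, `pos`, `gc`.
#' @param source optional label used in messages.
#' @return a `marker_map` data.frame sorted by (chromosome, position).
#' @export
as_marker_map <- function(df, source = "marker map") {
  if (anyDuplicated(df$marker_id))
    stop(source, ": duplicate marker_id values")
  if (any(df$gc < 0 | df$gc > 1, na.rm = TRUE))
    stop(source, ": gc fraction outside [0, 1]")
  ord <- order(chrom_rank(df$chrom), df$pos)
  if (any(ord != seq_len(nrow(df)))) {
    message(source, ": records unsorted; sorting by (chrom, pos)")
    df <- df[ord, , drop = FALSE]
  }
  dup <- duplicated(df[c("chrom", "pos")])
  if (any(dup))
    stop(source, ": duplicate position ", df$pos[dup][1],
         " on chromosome ", df$chrom[dup][1])
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

# Per-chromosome index of a marker map: list of integer ranges plus position
# vectors, so segment lookups avoid scanning all markers repeatedly.
map_index <- function(map) {
  idx <- split(seq_len(nrow(map)), factor(map$chrom, unique(map$chrom)))
  lapply(idx, function(i) list(idx = i, pos = map$pos[i]))
}

# marker indices (rows of map) covered by [start, end] on chrom; integer(0)
# when none. `mi` is an optional precomputed map_index().
markers_in_span <- function(map, chrom, start, end, mi = NULL) {
  if (is.null(mi)) {
    which(map$chrom == chrom & map$pos >= start & map$pos <= end)
  } else {
    ci <- mi[[chrom]]
    if (is.null(ci)) return(integer(0))
    lo <- findInterval(start - 0.5, ci$pos) + 1L
    hi <- findInterval(end + 0.5, ci$pos)
    if (hi < lo) integer(0) else ci$idx[lo:hi]
  }
}

#' Read BED regions
#'
#' Reads a BED file (0-based half-open coordinates) into the package's
#' 1-based inclusive convention: internal `start = bed_start + 1`,
#' `end = bed_end`. Column 4, when present, is a region name; column 5, when
#' `has_frequency = TRUE`, is a population frequency in \[0, 1\].
#'
#' @param path path to the BED file.
#' @param has_frequency logical; read column 5 as a frequency.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `frequency` (`NA` when absent).
#' @export
read_bed_regions <- function(path, has_frequency = FALSE) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#", fill = TRUE,
                          colClasses = "character")
  if (ncol(df) < 3) stop("BED file ", path, " has fewer than 3 columns")
  out <- data.frame(
    chrom = norm_chrom(df[[1]]),
    start = suppressWarnings(as.numeric(df[[2]])) + 1,
    end = suppressWarnings(as.numeric(df[[3]])),
    name = if (ncol(df) >= 4) df[[4]] else NA_character_,
    frequency = NA_real_,
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad))
    stop("malformed BED row in ", path, ": line ", bad[1])
  empty <- which(out$end < out$start)
  if (length(empty))
    stop("empty or inverted interval in ", path, ": line ", empty[1],
         " (", out$chrom[empty[1]], ":", out$start[empty[1]] - 1, "-",
         out$end[empty[1]], ")")
  if (has_frequency) {
    if (ncol(df) < 5) stop("BED file ", path, " lacks a frequency column")
    freq <- suppressWarnings(as.numeric(df[[5]]))
    if (any(is.na(freq) | freq < 0 | freq > 1))
      stop("frequency outside [0, 1] in ", path, ": line ",
           which(is.na(freq) | freq < 0 | freq > 1)[1])
    out$frequency <- freq
  }
  out
}

#' Write regions as BED
#'
#' Inverse of [read_bed_regions()]: internal 1-based inclusive intervals are
#' written as 0-based half-open BED rows.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `frequency`.
#' @param path output path.
#' @param with_frequency logical; emit the frequency column.
#' @export
write_bed_regions <- function(regions, path, with_frequency = FALSE) {
  cols <- list(regions$chrom, format_pos(regions$start - 1),
               format_pos(regions$end))
  nm <- if (!is.null(regions$name)) regions$name else rep(".", nrow(regions))
  nm[is.na(nm)] <- "."
  cols <- c(cols, list(nm))
  if (with_frequency) cols <- c(cols, list(regions$frequency))
  df <- do.call(data.frame, c(cols, list(stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_pos <- function(x) sprintf("%.0f", x)

#' Read gene models from BED12
#'
#' Exon blocks are converted to 1-based inclusive sub-intervals.
#'
#' @param path path to a BED12 file.
#' @return data.frame with columns `name`, `chrom`, `start`, `end` and a
#'   list-column `exons` of data.frames with `start`, `end`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 12) stop("gene model file ", path, " is not BED12")
  chrom <- norm_chrom(df[[1]])
  start0 <- as.numeric(df[[2]]); end0 <- as.numeric(df[[3]])
  n_blocks <- as.integer(df[[10]])
  exons <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    sizes <- as.numeric(strsplit(df[[11]][i], ",")[[1]])[seq_len(n_blocks[i])]
    offs <- as.numeric(strsplit(df[[12]][i], ",")[[1]])[seq_len(n_blocks[i])]
    ex <- data.frame(start = start0[i] + offs + 1,
                     end = start0[i] + offs + sizes)
    if (any(ex$start < start0[i] + 1 | ex$end > end0[i]))
      stop("exon block outside gene span in ", path, ": line ", i)
    exons[[i]] <- ex
  }
  out <- data.frame(name = df[[4]], chrom = chrom, start = start0 + 1,
                    end = end0, stringsAsFactors = FALSE)
  out$exons <- exons
  out
}

#' Write gene models as BED12
#'
#' @param genes data.frame as returned by [read_gene_models()].
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  rows <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    ex <- ex[order(ex$start), , drop = FALSE]
    start0 <- genes$start[i] - 1
    rows[i] <- paste(
      genes$chrom[i], format_pos(start0), format_pos(genes$end[i]),
      genes$name[i], 0, "+", format_pos(start0), format_pos(genes$end[i]),
      "0", nrow(ex),
      paste0(paste(format_pos(ex$end - ex$start + 1), collapse = ","), ","),
      paste0(paste(format_pos(ex$start - 1 - start0), collapse = ","), ","),
      sep = "\t")
  }
  writeLines(rows, path)
  invisible(path)
}

validate_calls <- function(calls, where = "CNV calls") {
  if (any(calls$copy_state == 2))
    stop(where, ": copy_state 2 is not a CNV call")
  if (!all(calls$copy_state %in% c(0, 1, 3, 4)))
    stop(where, ": copy_state must be one of 0, 1, 3, 4")
  if (any(calls$n_markers < 1))
    stop(where, ": n_markers must be >= 1")
  if (any(calls$end < calls$start))
    stop(where, ": interval end before start")
  calls
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = numeric(), end = numeric(), copy_state = integer(),
             n_markers = integer(), confidence = numeric(),
             caller = character(), stringsAsFactors = FALSE)
}

#' Read a CNV call table
#'
#' TSV with columns `sample_id`, `chrom`, `start`, `end`, `copy_state`,
#' `n_markers`, `confidence`, `caller`; 1-based inclusive coordinates.
#'
#' @param path path to the call TSV.
#' @return data.frame of calls.
#' @export
read_cnv_calls <- function(path) {
  df <- read_tsv_checked(
    path,
    c("sample_id", "chrom", "start", "end", "copy_state", "n_markers",
      "confidence", "caller"),
    numeric_cols = c("start", "end", "copy_state", "n_markers", "confidence"))
  if (nrow(df) == 0) return(empty_calls())
  df$chrom <- norm_chrom(df$chrom)
  df$copy_state <- as.integer(df$copy_state)
  df$n_markers <- as.integer(df$n_markers)
  validate_calls(df[names(empty_calls())], where = path)
}

#' Write a CNV call table
#'
#' Writes calls so that [read_cnv_calls()] reproduces them exactly
#' (confidence serialised at full double precision).
#'
#' @param calls data.frame of calls.
#' @param path output path.
#' @export
write_cnv_calls <- function(calls, path) {
  validate_calls(calls)
  out <- calls
  out$start <- format_pos(out$start)
  out$end <- format_pos(out$end)
  out$confidence <- sprintf("%.17g", out$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an intensity profile
#'
#' Ordered per-marker LRR and BAF values for one sample, aligned to a marker
#' map.
#'
#' @param sample_id sample identifier.
#' @param lrr numeric vector of log R ratios, one per marker.
#' @param baf numeric vector of B allele frequencies in \[0, 1\].
#' @return an `intensity_profile` object.
#' @export
intensity_profile <- function(sample_id, lrr, baf) {
  if (length(lrr) != length(baf))
    stop("lrr and baf must have one value per marker")
  if (any(baf < 0 | baf > 1, na.rm = TRUE))
    stop("baf outside [0, 1]")
  structure(list(sample_id = sample_id, lrr = as.numeric(lrr),
                 baf = as.numeric(baf)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity profile %s: %d markers, LRR sd %.3f>\n",
              x$sample_id, length(x$lrr), stats::sd(x$lrr)))
  invisible(x)
}

#' Read a per-sample signal file
#'
#' TSV with columns `marker_id`, `lrr`, `baf`, in marker-map order.
#'
#' @param path path to the signal TSV.
#' @param map marker map the profile must align to.
#' @param sample_id sample identifier (defaults to the file stem).
#' @return an [intensity_profile()].
#' @export
read_signal <- function(path, map, sample_id = NULL) {
  df <- read_tsv_checked(path, c("marker_id", "lrr", "baf"),
                         numeric_cols = c("lrr", "baf"))
  if (nrow(df) != nrow(map) || !all(df$marker_id == map$marker_id))
    stop("signal file ", path, " does not align to the marker map")
  if (is.null(sample_id))
    sample_id <- sub("\\.tsv$", "", basename(path))
  intensity_profile(sample_id, df$lrr, df$baf)
}

#' Write a per-sample signal file
#'
#' @param profile an [intensity_profile()].
#' @param map marker map the profile aligns to.
#' @param path output path.
#' @export
write_signal <- function(profile, map, path) {
  if (length(profile$lrr) != nrow(map))
    stop("profile does not align to the marker map")
  df <- data.frame(marker_id = map$marker_id,
                   lrr = sprintf("%.6g", profile$lrr),
                   baf = sprintf("%.6g", profile$baf))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `group` (case/control), `subtype`,
#' `family_id`, `call_rate`, `lrr_sd`, `wf`, `baf_drift`.
#'
#' @param path path to the sample sheet TSV.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(
    path,
    c("sample_id", "group", "subtype", "family_id", "call_rate", "lrr_sd",
      "wf", "baf_drift"),
    numeric_cols = c("call_rate", "lrr_sd", "wf", "baf_drift"))
  df$family_id[df$family_id == "."] <- NA_character_
  if (!all(df$group %in% c("case", "control")))
    stop(path, ": group must be 'case' or 'control'")
  bad <- df$group == "control" & df$subtype != "none"
  if (any(bad))
    stop(path, ": controls must have subtype 'none' (", df$sample_id[bad][1], ")")
  df
}

#' Write a sample sheet
#'
#' @param samples data.frame of sample metadata.
#' @param path output path.
#' @export
write_sample_sheet <- function(samples, path) {
  out <- samples
  out$family_id[is.na(out$family_id)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CNV truth set as BED
#'
#' Columns: chrom, 0-based start, end, sample_id, copy_state, strand (`.`),
#' origin. Round-trips through [read_truth_bed()].
#'
#' @param truth data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `copy_state`, `origin`.
#' @param path output path.
#' @export
write_truth_bed <- function(truth, path) {
  df <- data.frame(truth$chrom, format_pos(truth$start - 1),
                   format_pos(truth$end), truth$sample_id, truth$copy_state,
                   ".", truth$origin, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CNV truth set written by [write_truth_bed()]
#'
#' @param path path to the truth BED.
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `copy_state`, `origin`.
#' @export
read_truth_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  data.frame(sample_id = df[[4]], chrom = norm_chrom(df[[1]]),
             start = as.numeric(df[[2]]) + 1, end = as.numeric(df[[3]]),
             copy_state = as.integer(df[[5]]), origin = df[[7]],
             stringsAsFactors = FALSE)
}
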