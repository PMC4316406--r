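#' Construct a table of genomic intervals
#'
#' Intervals are the universal coordinate unit of the pipeline: plain
#' data.frames with 0-based half-open coordinates (`start` inclusive, `end`
#' exclusive), the convention of the BED format. All readers convert to this
#' convention and all module functions expect it.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"` (unstranded).
#' @return data.frame with columns `chrom`, `start`, `end` and, when supplied,
#'   `strand`.
#' @export
gintervals <- function(chrom, start, end, strand = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'")
    df$strand <- strand
  }
  validate_intervals(df)
  df
}

#' Validate interval invariants
#'
#' Checks the coordinate invariants every module relies on: non-empty
#' chromosome names, non-negative starts, and `start < end`.
#'
#' @param df data.frame with `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `df`, invisibly.
#' @export
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " table must have columns chrom, start, end")
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": chrom must be non-empty")
  if (any(df$start < 0))
    stop(what, ": negative start coordinate")
  if (any(df$start >= df$end))
    stop(what, ": start must be < end (0-based half-open)")
  invisible(df)
}

# Convert 0-based half-open interval table to GRanges (1-based closed).
as_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

# Hits between two 0-based half-open interval tables (>= minoverlap shared bp).
interval_hits <- function(query, subject, minoverlap = 1L) {
  qh <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                    minoverlap = minoverlap,
                                    ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(qh),
             subject = S4Vectors::subjectHits(qh))
}

# Logical: does each row of `query` overlap >= 1 row of `subject`?
overlaps_any <- function(query, subject, minoverlap = 1L) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges(query), as_granges(subject),
                       minoverlap = minoverlap, ignore.strand = TRUE)
}

# Midpoint of a 0-based half-open interval (position index, 0-based).
interval_midpoint <- function(start, end) {
  floor((start + end) / 2)
}

# Round half away from zero to `digits` decimals (base round() is banker's).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of methylated elements
#'
#' Tiny summary helper shared by the annotation tallies: the percentage
#' `100 * n_methylated / n_total`, rounded half-up to one decimal, as results
#' are conventionally reported.
#'
#' @param n_methylated count of methylated elements.
#' @param n_total total elements (> 0).
#' @param digits decimals to keep.
#' @return numeric percentage.
#' @export
pct_methylated <- function(n_methylated, n_total, digits = 1) {
  stopifnot(n_total > 0, n_methylated >= 0, n_methylated <= n_total)
  round_half_up(100 * n_methylated / n_total, digits)
}
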