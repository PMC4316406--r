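#' Unify two tissues' peak sets into methylation regions
#'
#' Pools the embryo and endosperm peak sets and forms one methylation region
#' per connected component of the overlap graph (two peaks are connected when
#' they share at least one bp on the same chromosome; book-ended peaks do not
#' merge). Each region is reported as the covering span of its member peaks,
#' with per-tissue summed read counts and an origin label recording which
#' tissues contributed peaks. Every input peak belongs to exactly one region
#' and regions never overlap one another.
#'
#' @param embryo_peaks,endosperm_peaks peak data.frames (`chrom`, `start`,
#'   `end`, `read_count`, ...).
#' @param chroms optional character vector of known chromosome names; peaks
#'   on other chromosomes are an error.
#' @return data.frame `chrom`, `start`, `end`, `origin`
#'   (both/embryo_only/endosperm_only), `k_embryo`, `k_endosperm`,
#'   `n_peaks_embryo`, `n_peaks_endosperm`, sorted by chrom then start.
#' @export
unify <- function(embryo_peaks, endosperm_peaks, chroms = NULL) {
  validate_intervals(embryo_peaks, "embryo peak")
  validate_intervals(endosperm_peaks, "endosperm peak")
  pool <- rbind(
    data.frame(chrom = embryo_peaks$chrom, start = embryo_peaks$start,
               end = embryo_peaks$end, read_count = embryo_peaks$read_count,
               tissue = rep("embryo", nrow(embryo_peaks)),
               stringsAsFactors = FALSE),
    data.frame(chrom = endosperm_peaks$chrom, start = endosperm_peaks$start,
               end = endosperm_peaks$end,
               read_count = endosperm_peaks$read_count,
               tissue = rep("endosperm", nrow(endosperm_peaks)),
               stringsAsFactors = FALSE))
  if (!is.null(chroms)) {
    bad <- setdiff(unique(pool$chrom), chroms)
    if (length(bad))
      stop("peaks on unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(pool) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), origin = character(0),
                      k_embryo = numeric(0), k_endosperm = numeric(0),
                      n_peaks_embryo = integer(0),
                      n_peaks_endosperm = integer(0)))
  gr <- as_granges(pool)
  # min.gapwidth = 0: merge only truly overlapping ranges, never book-ended
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(gr, red, ignore.strand = TRUE)
  stopifnot(length(hit) == nrow(pool))  # each peak in exactly one region
  comp <- S4Vectors::subjectHits(hit)
  ke <- tapply(pool$read_count * (pool$tissue == "embryo"), comp, sum)
  kn <- tapply(pool$read_count * (pool$tissue == "endosperm"), comp, sum)
  ne <- tapply(pool$tissue == "embryo", comp, sum)
  nn <- tapply(pool$tissue == "endosperm", comp, sum)
  idx <- as.integer(names(ke))
  res <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red))[idx],
    start = GenomicRanges::start(red)[idx] - 1L,
    end = GenomicRanges::end(red)[idx],
    k_embryo = as.numeric(ke),
    k_endosperm = as.numeric(kn),
    n_peaks_embryo = as.integer(ne),
    n_peaks_endosperm = as.integer(nn),
    stringsAsFactors = FALSE)
  res$origin <- ifelse(res$n_peaks_embryo > 0 & res$n_peaks_endosperm > 0,
                       "both",
                       ifelse(res$n_peaks_embryo > 0, "embryo_only",
                              "endosperm_only"))
  res <- res[order(res$chrom, res$start),
             c("chrom", "start", "end", "origin", "k_embryo", "k_endosperm",
               "n_peaks_embryo", "n_peaks_endosperm")]
  rownames(res) <- NULL
  res
}

#' Re-count raw reads within methylation regions
#'
#' Replaces the peak-derived per-tissue read sums with direct counts of raw
#' aligned reads: a read is assigned to the region containing its midpoint,
#' so each read is counted at most once even when it bridges two adjacent
#' regions.
#'
#' @param regions region data.frame from [unify()].
#' @param reads interval data.frame of aligned-read positions.
#' @param tissue which count column to replace: "embryo" or "endosperm".
#' @return `regions` with the corresponding `k_` column updated.
#' @export
count_reads_in_regions <- function(regions, reads, tissue) {
  tissue <- match.arg(tissue, c("embryo", "endosperm"))
  validate_intervals(regions, "region")
  col <- paste0("k_", tissue)
  if (nrow(reads) == 0) { regions[[col]] <- 0; return(regions) }
  validate_intervals(reads, "read")
  mids <- data.frame(chrom = reads$chrom,
                     start = interval_midpoint(reads$start, reads$end),
                     stringsAsFactors = FALSE)
  mids$end <- mids$start + 1
  hits <- interval_hits(mids, regions)
  cnt <- tabulate(hits$subject, nbins = nrow(regions))
  regions[[col]] <- cnt
  regions
}
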