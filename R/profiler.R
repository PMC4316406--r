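#' Windowed chromosome read-count profiles
#'
#' Splits each chromosome into fixed-width windows (default 10 kb; the last
#' window may be shorter) and counts the reads whose midpoint falls in each
#' window, so every read is assigned to exactly one window and window counts
#' sum to the per-chromosome read total.
#'
#' @param reads interval data.frame of aligned-read positions.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param width window width in bp (default 10,000).
#' @return data.frame `chrom`, `window` (1-based index), `start`, `end`,
#'   `count`.
#' @export
window_counts <- function(reads, chrom_lengths, width = 10000) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a positive number")
  if (nrow(reads)) validate_intervals(reads, "read")
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- unname(chrom_lengths[[chrom]])
    nw <- ceiling(len / width)
    r <- reads[reads$chrom == chrom, , drop = FALSE]
    idx <- floor(interval_midpoint(r$start, r$end) / width) + 1
    idx <- idx[idx >= 1 & idx <= nw]
    out[[chrom]] <- data.frame(
      chrom = chrom, window = seq_len(nw),
      start = (seq_len(nw) - 1) * width,
      end = pmin(seq_len(nw) * width, len),
      count = tabulate(idx, nbins = nw),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# mean per-base depth of x in nb equal bins (lengths may differ by 1 base)
bin_means <- function(x, nb) {
  idx <- ceiling(seq_along(x) * nb / length(x))
  as.numeric(tapply(x, factor(idx, levels = seq_len(nb)), mean,
                    default = 0))
}

#' Metagene methylation-level profile
#'
#' Averages library-size-normalized per-base read depth over genes in a
#' fixed promoter / gene-body / TTR layout: the promoter (`promoter_len` bp
#' upstream of the TSS) and TTR (`ttr_len` bp downstream of the TES) are
#' binned directly; the gene body is length-rescaled into its bin count.
#' Profiles are strand-flipped so the x-axis always runs 5' to 3', and depth
#' is expressed per 10 million library reads so tissues of different
#' sequencing depth are comparable.
#'
#' @param reads interval data.frame of aligned-read positions (one tissue).
#' @param models `gene_models` object (strand required).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param library_size total mapped reads of the tissue's library.
#' @param promoter_len,ttr_len flank extents (bp).
#' @param bins integer vector of length 3: bin counts for promoter, body,
#'   TTR (default 20/40/20).
#' @return data.frame `bin` (1..sum(bins)), `segment`
#'   (promoter/body/ttr), `level` (mean normalized depth), with attribute
#'   `n_genes`.
#' @export
metagene <- function(reads, models, chrom_lengths, library_size,
                     promoter_len = 2000, ttr_len = 2000,
                     bins = c(20, 40, 20)) {
  g <- models$genes
  if (nrow(g) == 0) stop("metagene requires at least one gene")
  if (any(!g$strand %in% c("+", "-"))) stop("unstranded gene(s)")
  stopifnot(length(bins) == 3, all(bins > 0), library_size > 0)
  cov <- list()
  for (chrom in names(chrom_lengths)) {
    r <- reads[reads$chrom == chrom, , drop = FALSE]
    cov[[chrom]] <- IRanges::coverage(
      IRanges::IRanges(start = r$start + 1, end = r$end),
      width = unname(chrom_lengths[[chrom]]))
  }
  total <- matrix(0, nrow = nrow(g), ncol = sum(bins))
  for (i in seq_len(nrow(g))) {
    cv <- cov[[g$chrom[i]]]
    clen <- unname(chrom_lengths[[g$chrom[i]]])
    plus <- g$strand[i] == "+"
    seg <- function(s, e) {  # 0-based half-open, clipped; per-base depth
      s <- max(0, s); e <- min(clen, e)
      if (s >= e) return(numeric(0))
      as.numeric(S4Vectors::window(cv, start = s + 1, end = e))
    }
    if (plus) {
      prom <- seg(g$start[i] - promoter_len, g$start[i])
      body <- seg(g$start[i], g$end[i])
      ttr <- seg(g$end[i], g$end[i] + ttr_len)
    } else {
      prom <- rev(seg(g$end[i], g$end[i] + promoter_len))
      body <- rev(seg(g$start[i], g$end[i]))
      ttr <- rev(seg(g$start[i] - ttr_len, g$start[i]))
    }
    total[i, ] <- c(
      if (length(prom)) bin_means(prom, bins[1]) else rep(0, bins[1]),
      bin_means(body, bins[2]),
      if (length(ttr)) bin_means(ttr, bins[3]) else rep(0, bins[3]))
  }
  level <- colMeans(total) * 1e7 / library_size
  res <- data.frame(
    bin = seq_len(sum(bins)),
    segment = rep(c("promoter", "body", "ttr"), times = bins),
    level = level)
  attr(res, "n_genes") <- nrow(g)
  res
}
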