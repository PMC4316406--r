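# Base-level indicator vectors for C, G and CpG-dinucleotide starts.
dna_indicators <- function(seq) {
  v <- charToRaw(seq)
  n <- length(v)
  isC <- v == as.raw(67)  # 'C'
  isG <- v == as.raw(71)  # 'G'
  cpg <- if (n >= 2) c(isC[-n] & isG[-1], FALSE) else rep(FALSE, n)
  list(n = n, isC = isC, isG = isG, cpg = cpg)
}

#' CpG statistics of a sequence interval
#'
#' Counts C, G and CpG dinucleotides in `[start, end)` of `seq` (0-based
#' half-open) and derives GC percentage and the observed/expected CpG ratio
#' O/E = (#CpG * length) / (#C * #G), defined as 0 when #C * #G = 0. N and
#' other ambiguity codes count toward length but not toward any tally.
#'
#' @param seq uppercase DNA string.
#' @param start,end 0-based half-open bounds (defaults: whole sequence).
#' @return list with `length`, `n_c`, `n_g`, `n_cpg`, `gc_pct`, `obs_exp`.
#' @export
cpg_stats <- function(seq, start = 0, end = nchar(seq)) {
  sub <- substr(seq, start + 1, end)
  ind <- dna_indicators(sub)
  n_c <- as.numeric(sum(ind$isC)); n_g <- as.numeric(sum(ind$isG))
  n_cpg <- as.numeric(sum(ind$cpg))
  len <- end - start
  list(length = len, n_c = n_c, n_g = n_g, n_cpg = n_cpg,
       gc_pct = 100 * (n_c + n_g) / len,
       obs_exp = if (n_c * n_g == 0) 0 else n_cpg * len / (n_c * n_g))
}

#' Find CpG islands in genomic sequence
#'
#' Sliding-window CpG-island detection with the classical thresholds:
#' minimum island length 200 bp, observed/expected CpG ratio >= 0.6 and
#' GC >= 50%. A 100-bp window slides by 1 bp; a window passes when its GC
#' percentage and O/E both meet the thresholds (O/E = (#CpG * width) /
#' (#C * #G), 0 when #C * #G = 0). Overlapping/adjacent passing windows are
#' merged into candidates, candidate ends are trimmed inward to the outermost
#' CpG dinucleotide, candidates closer than `merge_gap` bp are merged, and
#' each resulting interval is kept only if its island-level length, O/E and
#' GC pass all three thresholds. Reported `obs_exp`/`gc_pct` are island-level
#' values.
#'
#' @param seqs named character vector of uppercase chromosome sequences (a
#'   single unnamed string is treated as chromosome "seq").
#' @param min_length minimum island length (bp).
#' @param min_oe minimum observed/expected CpG ratio.
#' @param min_gc minimum GC percentage.
#' @param window sliding window width (bp).
#' @param merge_gap islands separated by less than this many bp are merged
#'   before the final filter.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `length`,
#'   `obs_exp`, `gc_pct`, sorted by chrom then start.
#' @export
find_cgis <- function(seqs, min_length = 200, min_oe = 0.6, min_gc = 50,
                      window = 100, merge_gap = 100) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- list()
  for (chrom in names(seqs)) {
    isl <- find_cgis_one(seqs[[chrom]], min_length, min_oe, min_gc,
                         window, merge_gap)
    if (nrow(isl)) { isl$chrom <- chrom; out[[chrom]] <- isl }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      obs_exp = numeric(0), gc_pct = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "length", "obs_exp", "gc_pct")]
}

find_cgis_one <- function(seq, min_length, min_oe, min_gc, window,
                          merge_gap) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0), obs_exp = numeric(0),
                      gc_pct = numeric(0))
  ind <- dna_indicators(seq)
  n <- ind$n
  if (n < window) return(empty)
  csC <- c(0, cumsum(as.numeric(ind$isC)))
  csG <- c(0, cumsum(as.numeric(ind$isG)))
  csP <- c(0, cumsum(as.numeric(ind$cpg)))
  starts <- seq_len(n - window + 1)           # 1-based window starts
  wc <- csC[starts + window] - csC[starts]
  wg <- csG[starts + window] - csG[starts]
  # CpG dinucleotides fully inside the window start at positions
  # start .. start+window-2
  wp <- csP[starts + window - 1] - csP[starts]
  prod <- wc * wg
  oe <- ifelse(prod == 0, 0, wp * window / prod)
  pass <- (100 * (wc + wg) / window >= min_gc) & (oe >= min_oe)
  ps <- starts[pass]
  if (!length(ps)) return(empty)

  # merge overlapping/adjacent passing windows into candidate intervals
  brk <- which(diff(ps) > window)
  grp_first <- ps[c(1, brk + 1)]
  grp_last <- ps[c(brk, length(ps))]
  cand_a <- grp_first                  # 1-based inclusive
  cand_b <- grp_last + window - 1

  # trim each candidate inward to the outermost CpG dinucleotide
  cpg_pos <- which(ind$cpg)            # 1-based start of each CG
  t_start <- numeric(0); t_end <- numeric(0)  # 0-based half-open
  for (k in seq_along(cand_a)) {
    inside <- cpg_pos[cpg_pos >= cand_a[k] & cpg_pos + 1 <= cand_b[k]]
    if (!length(inside)) next
    t_start <- c(t_start, inside[1] - 1)
    t_end <- c(t_end, inside[length(inside)] + 1)
  }
  if (!length(t_start)) return(empty)

  # merge trimmed islands separated by < merge_gap bp
  m_start <- t_start[1]; m_end <- t_end[1]
  if (length(t_start) > 1) {
    for (k in 2:length(t_start)) {
      last <- length(m_end)
      if (t_start[k] - m_end[last] < merge_gap) {
        m_end[last] <- t_end[k]
      } else {
        m_start <- c(m_start, t_start[k]); m_end <- c(m_end, t_end[k])
      }
    }
  }

  # island-level statistics and final filter
  len <- m_end - m_start
  ic <- csC[m_end + 1] - csC[m_start + 1]
  ig <- csG[m_end + 1] - csG[m_start + 1]
  ip <- csP[m_end] - csP[m_start + 1]       # CpG starts within [start, end-1)
  gc_pct <- 100 * (ic + ig) / len
  prod <- ic * ig
  obs_exp <- ifelse(prod == 0, 0, ip * len / prod)
  keep <- len >= min_length & obs_exp >= min_oe & gc_pct >= min_gc
  data.frame(start = m_start, end = m_end, length = len,
             obs_exp = obs_exp, gc_pct = gc_pct)[keep, , drop = FALSE]
}

#' Derive CpG-island shores
#'
#' A shore is the flank up to `shore_width` bp (default 2,000) on either side
#' of an island, clipped at chromosome ends. Where two islands lie closer
#' than `2 * shore_width`, the inter-island gap is split at its midpoint
#' between the two facing shores, so shores never overlap islands or each
#' other. Empty shores (e.g. an island starting at position 0) are dropped.
#'
#' @param islands island data.frame from [find_cgis()] (non-overlapping,
#'   any order).
#' @param chrom_lengths named vector of chromosome lengths (bp) covering
#'   every island chromosome.
#' @param shore_width flank width (bp).
#' @return data.frame `chrom`, `start`, `end`, `side` (upstream/downstream),
#'   `island_id` (row index of the parent island in the sorted island table).
#' @export
derive_shores <- function(islands, chrom_lengths, shore_width = 2000) {
  validate_intervals(islands, "island")
  if (nrow(islands) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), side = character(0),
                      island_id = integer(0)))
  miss <- setdiff(unique(islands$chrom), names(chrom_lengths))
  if (length(miss))
    stop("no chromosome length for: ", paste(miss, collapse = ", "))
  o <- order(islands$chrom, islands$start)
  islands <- islands[o, , drop = FALSE]
  islands$island_id <- seq_len(nrow(islands))
  out <- list()
  for (chrom in unique(islands$chrom)) {
    isl <- islands[islands$chrom == chrom, , drop = FALSE]
    if (nrow(isl) > 1 && any(isl$start[-1] < isl$end[-nrow(isl)]))
      stop("overlapping input islands on ", chrom)
    len <- unname(chrom_lengths[[chrom]])
    up_start <- pmax(0, isl$start - shore_width)
    up_end <- isl$start
    dn_start <- isl$end
    dn_end <- pmin(len, isl$end + shore_width)
    if (nrow(isl) > 1) {
      for (k in seq_len(nrow(isl) - 1)) {
        gap <- isl$start[k + 1] - isl$end[k]
        if (gap < 2 * shore_width) {
          mid <- floor((isl$end[k] + isl$start[k + 1]) / 2)
          dn_end[k] <- min(dn_end[k], mid)
          up_start[k + 1] <- max(up_start[k + 1], mid)
        }
      }
    }
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = c(up_start, dn_start),
      end = c(up_end, dn_end),
      side = rep(c("upstream", "downstream"), each = nrow(isl)),
      island_id = rep(isl$island_id, 2),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[res$start < res$end, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
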