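# Shared fixture builders and independent oracles.

peak_df <- function(chrom, start, end, read_count = 10,
                    diff_score = 60) {
  data.frame(chrom = rep_len(chrom, length(start)), start = start,
             end = end,
             read_count = rep_len(read_count, length(start)),
             diff_score = rep_len(diff_score, length(start)),
             stringsAsFactors = FALSE)
}

iv <- function(chrom, start, end) {
  data.frame(chrom = rep_len(chrom, length(start)), start = start,
             end = end, stringsAsFactors = FALSE)
}

# random test sequence: i.i.d. at a GC fraction, optional CpG depletion
# implemented independently of the package generator (sequential rejection)
random_seq <- function(n, gc = 0.5, cpg_keep = 1) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(names(p), n, replace = TRUE, prob = p)
  if (cpg_keep < 1) {
    for (i in which(x[-n] == "C" & x[-1] == "G")) {
      if (x[i] == "C" && x[i + 1] == "G" && runif(1) > cpg_keep)
        x[i + 1] <- sample(c("A", "T"), 1)
    }
  }
  paste(x, collapse = "")
}

# Independent CpG-island oracle: plain double-loop re-derivation of the
# windowed algorithm on a character vector, with window statistics counted
# directly per window.
oracle_find_cgis <- function(seq, min_length = 200, min_oe = 0.6,
                             min_gc = 50, window = 100, merge_gap = 100) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  empty <- data.frame(start = numeric(0), end = numeric(0))
  if (n < window) return(empty)
  stats_of <- function(a, b) {  # 1-based inclusive
    cs <- chars[a:b]
    nc <- sum(cs == "C"); ng <- sum(cs == "G")
    ncpg <- sum(cs[-length(cs)] == "C" & cs[-1] == "G")
    len <- b - a + 1
    list(gc = 100 * (nc + ng) / len,
         oe = if (nc * ng == 0) 0 else ncpg * len / (nc * ng))
  }
  pass <- logical(n - window + 1)
  for (i in seq_len(n - window + 1)) {
    st <- stats_of(i, i + window - 1)
    pass[i] <- st$gc >= min_gc && st$oe >= min_oe
  }
  ps <- which(pass)
  if (!length(ps)) return(empty)
  # merge overlapping/adjacent passing windows
  cands <- list(); a <- ps[1]; b <- ps[1] + window - 1
  for (i in ps[-1]) {
    if (i <= b + 1) b <- i + window - 1
    else { cands[[length(cands) + 1]] <- c(a, b); a <- i; b <- i + window - 1 }
  }
  cands[[length(cands) + 1]] <- c(a, b)
  # trim to outermost CpG
  trimmed <- list()
  for (cd in cands) {
    cpgs <- integer(0)
    for (i in cd[1]:(cd[2] - 1))
      if (chars[i] == "C" && chars[i + 1] == "G") cpgs <- c(cpgs, i)
    if (!length(cpgs)) next
    trimmed[[length(trimmed) + 1]] <- c(min(cpgs), max(cpgs) + 1)
  }
  if (!length(trimmed)) return(empty)
  # merge islands separated by < merge_gap
  merged <- list(trimmed[[1]])
  for (tr in trimmed[-1]) {
    last <- merged[[length(merged)]]
    if (tr[1] - last[2] - 1 < merge_gap)
      merged[[length(merged)]] <- c(last[1], tr[2])
    else merged[[length(merged) + 1]] <- tr
  }
  keep <- list()
  for (m in merged) {
    len <- m[2] - m[1] + 1
    st <- stats_of(m[1], m[2])
    if (len >= min_length && st$oe >= min_oe && st$gc >= min_gc)
      keep[[length(keep) + 1]] <- data.frame(start = m[1] - 1, end = m[2])
  }
  if (!length(keep)) return(empty)
  do.call(rbind, keep)
}

# tiny GFF3 text fixture writer (1-based inclusive, as the format demands)
write_gff_fixture <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
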