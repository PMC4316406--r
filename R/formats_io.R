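#' Read a FASTA file into a named vector of uppercase sequences
#'
#' Sequences are uppercased on read; IUPAC ambiguity codes (including N) are
#' preserved. Record order follows the file.
#'
#' @param path FASTA file.
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0)
    stop("FASTA format error: empty file at line 1: ", path)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA format error: expected '>' header at line ", first)
  ss <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(ss)))
    stop("FASTA format error: duplicate sequence name: ",
         names(ss)[duplicated(names(ss))][1])
  seqs <- toupper(as.character(ss))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  out <- character(0)
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    n <- nchar(s)
    starts <- seq(1, n, by = width)
    out <- c(out, paste0(">", nm),
             substring(s, starts, pmin(starts + width - 1, n)))
  }
  writeLines(out, path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS/UTR features (via \pkg{rtracklayer}) and builds
#' one model per gene from its longest transcript (largest summed exon
#' length). GFF3 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. Introns are derived as the gaps between
#' sorted exons. Genes without exons are skipped with a warning giving the
#' skipped count; an exon outside its gene span is a format error.
#'
#' @param path GFF3 file.
#' @return object of class `gene_models`: a list with `genes` (data.frame
#'   `gene_id`, `chrom`, `start`, `end`, `strand`) and `features` (long
#'   data.frame `gene_id`, `feature` in exon/intron/cds/utr5/utr3, `chrom`,
#'   `start`, `end`).
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L  # to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  feat_map <- c(exon = "exon", CDS = "cds",
                five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  is_feat <- type %in% names(feat_map)

  tx_gene <- stats::setNames(parent[is_tx], id[is_tx])
  gene_ids <- id[is_gene]
  gene_row <- stats::setNames(which(is_gene), gene_ids)

  # feature -> owning transcript (or directly the gene when no mRNA layer)
  feat_idx <- which(is_feat)
  feat_parent <- parent[feat_idx]
  feat_tx <- ifelse(feat_parent %in% gene_ids,
                    paste0(feat_parent, ".synthetic_tx"), feat_parent)
  tx_gene <- c(tx_gene,
               stats::setNames(feat_parent[feat_parent %in% gene_ids],
                               feat_tx[feat_parent %in% gene_ids]))
  tx_gene <- tx_gene[!duplicated(names(tx_gene))]

  genes_out <- list(); feats_out <- list(); skipped <- 0L
  for (g in gene_ids) {
    gi <- gene_row[[g]]
    txs <- names(tx_gene)[tx_gene == g]
    best <- NULL; best_len <- -1
    for (tx in txs) {
      sel <- feat_idx[feat_tx == tx]
      ex <- sel[type[sel] == "exon"]
      if (length(ex) == 0) next
      len <- sum(end0[ex] - start0[ex])
      if (len > best_len) { best_len <- len; best <- tx }
    }
    if (is.null(best)) { skipped <- skipped + 1L; next }
    sel <- feat_idx[feat_tx == best]
    ex <- sel[type[sel] == "exon"]
    if (any(start0[ex] < start0[gi]) || any(end0[ex] > end0[gi]))
      stop("GFF3 format error: exon outside gene span for gene ", g)
    o <- order(start0[ex])
    ex_start <- start0[ex][o]; ex_end <- end0[ex][o]
    fl <- data.frame(gene_id = g, feature = "exon", chrom = chrom[gi],
                     start = ex_start, end = ex_end,
                     stringsAsFactors = FALSE)
    if (length(ex_start) > 1) {
      int_start <- ex_end[-length(ex_end)]
      int_end <- ex_start[-1]
      keep <- int_start < int_end
      if (any(keep))
        fl <- rbind(fl, data.frame(gene_id = g, feature = "intron",
                                   chrom = chrom[gi],
                                   start = int_start[keep],
                                   end = int_end[keep],
                                   stringsAsFactors = FALSE))
    }
    for (ft in c("CDS", "five_prime_UTR", "three_prime_UTR")) {
      fsel <- sel[type[sel] == ft]
      if (length(fsel))
        fl <- rbind(fl, data.frame(gene_id = g, feature = feat_map[[ft]],
                                   chrom = chrom[fsel],
                                   start = start0[fsel], end = end0[fsel],
                                   stringsAsFactors = FALSE))
    }
    genes_out[[g]] <- data.frame(gene_id = g, chrom = chrom[gi],
                                 start = start0[gi], end = end0[gi],
                                 strand = strand[gi], stringsAsFactors = FALSE)
    feats_out[[g]] <- fl
  }
  if (skipped > 0)
    warning(skipped, " gene(s) without exons skipped")
  genes <- if (length(genes_out)) do.call(rbind, genes_out) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), strand = character(0))
  feats <- if (length(feats_out)) do.call(rbind, feats_out) else
    data.frame(gene_id = character(0), feature = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0))
  rownames(genes) <- rownames(feats) <- NULL
  structure(list(genes = genes, features = feats), class = "gene_models")
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3_genes()] for round-tripping: emits gene, mRNA, exon
#' and (when present) CDS/UTR rows, converting internal 0-based half-open
#' coordinates back to GFF3 1-based inclusive.
#'
#' @param models `gene_models` object.
#' @param path output file.
#' @export
write_gff3_genes <- function(models, path) {
  g <- models$genes
  f <- models$features
  type_map <- c(exon = "exon", cds = "CDS",
                utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
      paste(g$chrom[i], "medipdmr", "gene", g$start[i] + 1, g$end[i], ".",
            g$strand[i], ".", paste0("ID=", gid), sep = "\t"),
      paste(g$chrom[i], "medipdmr", "mRNA", g$start[i] + 1, g$end[i], ".",
            g$strand[i], ".", paste0("ID=", tid, ";Parent=", gid), sep = "\t"))
    fg <- f[f$gene_id == gid & f$feature %in% names(type_map), , drop = FALSE]
    fg <- fg[order(match(fg$feature, names(type_map)), fg$start), ,
             drop = FALSE]
    k <- 0L
    for (j in seq_len(nrow(fg))) {
      k <- k + 1L
      lines <- c(lines,
        paste(fg$chrom[j], "medipdmr", type_map[[fg$feature[j]]],
              fg$start[j] + 1, fg$end[j], ".", g$strand[i],
              if (fg$feature[j] == "cds") "0" else ".",
              paste0("ID=", tid, ".", fg$feature[j], k, ";Parent=", tid),
              sep = "\t"))
    }
  }
  writeLines(lines, path)
}

#' Read a methylation peak table
#'
#' Reads the minimal 5-column tab-separated peak table (`chrom`, `start`,
#' `end`, `read_count`, `diff_score`) emitted by the peak-calling step, with
#' coordinates already 0-based half-open. Comment (`#`) and header lines are
#' skipped. Peaks are filtered by caller significance: `diff_score` is
#' -10*log10(p) of the peak caller, so the default `min_diff_score = 50` is
#' equivalent to the default `max_p = 1e-5`; the stricter of the two bounds
#' applies.
#'
#' @param path peak TSV.
#' @param min_diff_score minimum diffScore retained (default 50).
#' @param max_p maximum peak p-value retained (default 1e-5).
#' @param tissue optional tissue label added as a column.
#' @return data.frame `chrom`, `start`, `end`, `read_count`, `diff_score`
#'   (plus `tissue` when given).
#' @export
read_peaks <- function(path, min_diff_score = 50, max_p = 1e-5,
                       tissue = NULL) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), read_count = numeric(0),
                      diff_score = numeric(0), stringsAsFactors = FALSE)
  if (length(lines) == 0)
    return(if (is.null(tissue)) empty else cbind(empty, tissue = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate a non-numeric header row
  if (suppressWarnings(is.na(as.numeric(parts[[1]][2]))))
    parts <- parts[-1]
  if (length(parts) == 0)
    return(if (is.null(tissue)) empty else cbind(empty, tissue = character(0)))
  bad <- which(vapply(parts, length, 1L) < 5)
  if (length(bad))
    stop("peak table format error: fewer than 5 columns at data line ", bad[1])
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)),
    end = as.numeric(vapply(parts, `[`, "", 3)),
    read_count = as.numeric(vapply(parts, `[`, "", 4)),
    diff_score = as.numeric(vapply(parts, `[`, "", 5)),
    stringsAsFactors = FALSE)
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("peak table format error: non-numeric coordinates")
  if (any(df$start >= df$end))
    stop("peak table format error: start >= end at data line ",
         which(df$start >= df$end)[1])
  if (any(df$read_count < 0) || any(df$diff_score < 0))
    stop("peak table format error: negative read_count or diff_score")
  thr <- max(min_diff_score, -10 * log10(max_p))
  df <- df[df$diff_score >= thr, , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(tissue)) df$tissue <- tissue
  df
}

#' Write a peak table
#' @param peaks peak data.frame as returned by [read_peaks()].
#' @param path output TSV.
#' @export
write_peaks <- function(peaks, path) {
  lines <- c("#chrom\tstart\tend\tread_count\tdiff_score",
             paste(peaks$chrom, peaks$start, peaks$end,
                   peaks$read_count, peaks$diff_score, sep = "\t"))
  writeLines(lines, path)
}

#' Read aligned-read positions from BED
#'
#' BED is natively 0-based half-open so coordinates pass through unchanged.
#' When chromosome lengths are supplied, intervals running past a chromosome
#' end are clipped with a warning; negative coordinates are a format error.
#'
#' @param path BED3(+) file.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @return interval data.frame (`chrom`, `start`, `end`).
#' @export
read_reads_bed <- function(path, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)),
    end = as.numeric(vapply(parts, `[`, "", 3)),
    stringsAsFactors = FALSE)
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("BED format error: non-numeric coordinates")
  if (any(df$start < 0))
    stop("BED format error: negative coordinate at data line ",
         which(df$start < 0)[1])
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[df$chrom]
    over <- !is.na(len) & df$end > len
    if (any(over)) {
      warning(sum(over), " interval(s) extend past chromosome end; clipped")
      df$end[over] <- len[over]
    }
  }
  validate_intervals(df, "BED")
  df
}

#' Write intervals to BED3
#' @param intervals interval data.frame.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals, "BED")
  writeLines(paste(intervals$chrom, format(intervals$start, scientific = FALSE,
                                           trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
}

#' Write a generic record table as TSV
#' @param records data.frame.
#' @param path output file.
#' @export
write_table_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read an expression table (gene_id, rpkm_embryo, rpkm_endosperm)
#' @param path TSV with header.
#' @return data.frame with non-negative RPKM columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "rpkm_embryo", "rpkm_endosperm")
  if (!all(need %in% names(df)))
    stop("expression table must have columns ", paste(need, collapse = ", "))
  if (any(df$rpkm_embryo < 0) || any(df$rpkm_endosperm < 0))
    stop("expression table: negative RPKM")
  df
}

#' Read a gene-to-GO mapping (gene_id, go_id[, go_name])
#' @param path two- or three-column TSV with header.
#' @return data.frame `gene_id`, `go_id` and optionally `go_name`.
#' @export
read_go_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "go_id") %in% names(df)))
    stop("GO map must have columns gene_id, go_id")
  df
}
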