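#' Derive promoter and TTR intervals for gene models
#'
#' The promoter is the `promoter_len` bp immediately upstream of the TSS and
#' the transcriptional termination region (TTR) the `ttr_len` bp immediately
#' downstream of the TES, oriented by gene strand and clipped at chromosome
#' bounds. Zero lengths yield no feature rows.
#'
#' @param models `gene_models` object (see [read_gff3_genes()]).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param promoter_len,ttr_len extents in bp (defaults 2,000, the same scale
#'   as CpG-island shores).
#' @return `models` with `promoter` and `ttr` rows appended to `$features`.
#' @export
derive_promoter_ttr <- function(models, chrom_lengths, promoter_len = 2000,
                                ttr_len = 2000) {
  g <- models$genes
  if (any(!g$strand %in% c("+", "-")))
    stop("unstranded gene(s): ",
         paste(g$gene_id[!g$strand %in% c("+", "-")], collapse = ", "))
  len <- chrom_lengths[g$chrom]
  plus <- g$strand == "+"
  prom_start <- ifelse(plus, g$start - promoter_len, g$end)
  prom_end <- ifelse(plus, g$start, g$end + promoter_len)
  ttr_start <- ifelse(plus, g$end, g$start - ttr_len)
  ttr_end <- ifelse(plus, g$end + ttr_len, g$start)
  clip <- function(s, e) {
    s <- pmax(0, s); e <- pmin(unname(len), e)
    list(s = s, e = e)
  }
  pr <- clip(prom_start, prom_end)
  tt <- clip(ttr_start, ttr_end)
  add <- rbind(
    data.frame(gene_id = g$gene_id, feature = "promoter", chrom = g$chrom,
               start = pr$s, end = pr$e, stringsAsFactors = FALSE),
    data.frame(gene_id = g$gene_id, feature = "ttr", chrom = g$chrom,
               start = tt$s, end = tt$e, stringsAsFactors = FALSE))
  add <- add[add$start < add$end, , drop = FALSE]
  models$features <- rbind(models$features, add)
  rownames(models$features) <- NULL
  models
}

#' Extract one feature class as an interval table
#' @param models `gene_models` object.
#' @param feature feature name (exon, intron, cds, utr5, utr3, promoter, ttr).
#' @return interval data.frame with a `gene_id` column.
#' @export
feature_intervals <- function(models, feature) {
  f <- models$features
  f[f$feature == feature, c("gene_id", "chrom", "start", "end"),
    drop = FALSE]
}

#' Overlap items with feature classes and tally methylation
#'
#' A feature is methylated iff it shares at least one bp with at least one
#' item (peak, region or DMR). Emits, per feature class, the number of
#' features and the number methylated, and the distribution of items over
#' classes. An item counts in every class it hits; when the classes include
#' `cgi` and `shore`, items hitting neither are tallied as `other`. With
#' `exclusive = TRUE` the item distribution over cgi/shore/other instead uses
#' the precedence cgi > shore > other so the three counts partition the
#' items.
#'
#' @param items interval data.frame.
#' @param feature_sets named list of interval data.frames, one per class.
#' @param exclusive logical; see above.
#' @return list with `counts` (data.frame `class`, `n_features`,
#'   `n_methylated`), `status` (named list of per-feature logical vectors)
#'   and `item_classes` (data.frame `class`, `n_items`).
#' @export
annotate_overlaps <- function(items, feature_sets, exclusive = FALSE) {
  validate_intervals(items, "item")
  status <- lapply(feature_sets, function(f) overlaps_any(f, items))
  counts <- data.frame(
    class = names(feature_sets),
    n_features = vapply(feature_sets, nrow, 1L),
    n_methylated = vapply(status, sum, 1L),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  hit_item <- lapply(feature_sets, function(f) overlaps_any(items, f))
  item_classes <- data.frame(
    class = names(feature_sets),
    n_items = vapply(hit_item, sum, 1L),
    stringsAsFactors = FALSE)
  if (all(c("cgi", "shore") %in% names(feature_sets))) {
    in_cgi <- hit_item[["cgi"]]; in_shore <- hit_item[["shore"]]
    if (exclusive) {
      item_classes$n_items[item_classes$class == "shore"] <-
        sum(in_shore & !in_cgi)
    }
    item_classes <- rbind(item_classes,
                          data.frame(class = "other",
                                     n_items = sum(!in_cgi & !in_shore)))
  }
  rownames(item_classes) <- NULL
  list(counts = counts, status = status, item_classes = item_classes)
}

#' Classify promoter/TTR CpG content (HCP/LCP, HCTTR/LCTTR)
#'
#' Slides a `window`-bp window (step `step`) across each feature, or takes
#' the whole feature when shorter, and scores each window by its CpG
#' observed/expected ratio and GC fraction. The feature's class is decided by
#' the window maximizing the CpG ratio: high-CpG (HCP/HCTTR) iff that
#' window's CpG ratio >= `r_min` and GC fraction >= `g_min`, else low-CpG.
#'
#' @param seqs named vector of chromosome sequences (uppercase).
#' @param features interval data.frame (e.g. from [feature_intervals()]).
#' @param kind "promoter" or "ttr" (selects label names).
#' @param window,step sliding-window width and step (bp).
#' @param r_min,g_min class thresholds on the max window's CpG ratio and GC
#'   fraction.
#' @return `features` with `cpg_ratio`, `gc_frac` and `label` columns.
#' @export
classify_promoter_cpg <- function(seqs, features, kind = c("promoter",
                                                           "ttr"),
                                  window = 500, step = 5,
                                  r_min = 0.75, g_min = 0.55) {
  kind <- match.arg(kind)
  labels <- if (kind == "promoter") c("HCP", "LCP") else c("HCTTR", "LCTTR")
  validate_intervals(features, "feature")
  n <- nrow(features)
  cpg_ratio <- numeric(n); gc_frac <- numeric(n)
  for (i in seq_len(n)) {
    s <- substr(seqs[[features$chrom[i]]], features$start[i] + 1,
                features$end[i])
    len <- nchar(s)
    ind <- dna_indicators(s)
    csC <- c(0, cumsum(ind$isC)); csG <- c(0, cumsum(ind$isG))
    csP <- c(0, cumsum(ind$cpg))
    if (len <= window) {
      starts <- 1L; w <- len
    } else {
      starts <- seq.int(1L, len - window + 1L, by = step)
      w <- window
    }
    wc <- csC[starts + w] - csC[starts]
    wg <- csG[starts + w] - csG[starts]
    wp <- csP[starts + w - 1] - csP[starts]
    prod <- wc * wg
    oe <- ifelse(prod == 0, 0, wp * w / prod)
    best <- which.max(oe)
    cpg_ratio[i] <- oe[best]
    gc_frac[i] <- (wc[best] + wg[best]) / w
  }
  features$cpg_ratio <- cpg_ratio
  features$gc_frac <- gc_frac
  features$label <- ifelse(cpg_ratio >= r_min & gc_frac >= g_min,
                           labels[1], labels[2])
  features
}

#' Annotate transposable elements with per-tissue methylation status
#'
#' A TE is methylated in a tissue iff it overlaps (>= 1 bp) at least one of
#' that tissue's methylation peaks.
#'
#' @param tes interval data.frame of TEs (optionally with `te_id`, `family`).
#' @param peaks_by_tissue named list of peak data.frames (e.g.
#'   `list(embryo = ..., endosperm = ...)`).
#' @return list with `te_status` (the TE table plus one logical
#'   `methylated_<tissue>` column per tissue) and `summary` (data.frame
#'   `tissue`, `n_te`, `n_methylated`, `pct_methylated`,
#'   `pct_unmethylated`).
#' @export
annotate_tes <- function(tes, peaks_by_tissue) {
  validate_intervals(tes, "TE")
  summ <- list()
  for (tissue in names(peaks_by_tissue)) {
    st <- overlaps_any(tes, peaks_by_tissue[[tissue]])
    tes[[paste0("methylated_", tissue)]] <- st
    summ[[tissue]] <- data.frame(
      tissue = tissue, n_te = nrow(tes), n_methylated = sum(st),
      pct_methylated = if (nrow(tes)) pct_methylated(sum(st), nrow(tes))
                       else NA_real_,
      pct_unmethylated = if (nrow(tes))
        pct_methylated(nrow(tes) - sum(st), nrow(tes)) else NA_real_,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  list(te_status = tes, summary = summary)
}

#' Distribution of DMRs over feature classes, by direction
#'
#' Counts, for each feature class, the DMRs (status up_embryo or
#' up_endosperm) overlapping at least one feature of the class; a DMR
#' overlapping several classes is counted once in each.
#'
#' @param calls output of [call_dmrs()].
#' @param feature_sets named list of interval data.frames.
#' @return data.frame `class`, `up_embryo`, `up_endosperm`.
#' @export
dmr_distribution <- function(calls, feature_sets) {
  stopifnot("status" %in% names(calls))
  out <- data.frame(class = names(feature_sets),
                    up_embryo = 0L, up_endosperm = 0L,
                    stringsAsFactors = FALSE)
  for (dir in c("up_embryo", "up_endosperm")) {
    dmrs <- calls[calls$status == dir, , drop = FALSE]
    if (nrow(dmrs) == 0) next
    out[[dir]] <- vapply(feature_sets, function(f)
      sum(overlaps_any(dmrs, f)), 1L)
  }
  rownames(out) <- NULL
  out
}
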