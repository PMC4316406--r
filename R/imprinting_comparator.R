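#' Classify gene methylation pattern across tissues
#'
#' A gene is methylated in a tissue when any of its features (gene body,
#' promoter or TTR, i.e. the gene's full extent including derived flanks)
#' overlaps a methylation region that contains at least one peak from that
#' tissue (region origin `both` or `<tissue>_only`); background read counts
#' alone do not make a gene methylated. Genes methylated in both tissues are
#' then sub-classified by the DMR calls of their overlapping regions: if all
#' overlapping DMRs (ignoring non-differential regions) are up-methylated in
#' one tissue, the gene is `more_in_<tissue>`; with no overlapping DMR it is
#' `similar`; with DMRs in both directions it is `mixed` (reported, counted
#' as differential).
#'
#' @param models `gene_models` object, ideally after
#'   [derive_promoter_ttr()].
#' @param calls output of [call_dmrs()] (regions with `origin` and
#'   `status`).
#' @return data.frame `gene_id`, `methylated_embryo`,
#'   `methylated_endosperm`, `n_dmr_up_embryo`, `n_dmr_up_endosperm`,
#'   `category` in {embryo_only, endosperm_only, more_in_embryo,
#'   more_in_endosperm, similar, mixed, unmethylated}.
#' @export
classify_gene_methylation <- function(models, calls) {
  stopifnot(all(c("origin", "status") %in% names(calls)))
  g <- models$genes
  f <- models$features
  ext <- g[, c("gene_id", "chrom", "start", "end")]
  for (i in seq_len(nrow(ext))) {
    fg <- f[f$gene_id == ext$gene_id[i], , drop = FALSE]
    if (nrow(fg)) {
      ext$start[i] <- min(ext$start[i], fg$start)
      ext$end[i] <- max(ext$end[i], fg$end)
    }
  }
  hits <- interval_hits(ext, calls)
  res <- data.frame(gene_id = g$gene_id,
                    methylated_embryo = FALSE,
                    methylated_endosperm = FALSE,
                    n_dmr_up_embryo = 0L, n_dmr_up_endosperm = 0L,
                    category = "unmethylated",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    ridx <- hits$subject[hits$query == i]
    if (!length(ridx)) next
    org <- calls$origin[ridx]
    st <- calls$status[ridx]
    me <- any(org %in% c("both", "embryo_only"))
    mn <- any(org %in% c("both", "endosperm_only"))
    ue <- sum(st == "up_embryo")
    un <- sum(st == "up_endosperm")
    res$methylated_embryo[i] <- me
    res$methylated_endosperm[i] <- mn
    res$n_dmr_up_embryo[i] <- ue
    res$n_dmr_up_endosperm[i] <- un
    res$category[i] <-
      if (me && !mn) "embryo_only"
      else if (!me && mn) "endosperm_only"
      else if (ue > 0 && un == 0) "more_in_embryo"
      else if (un > 0 && ue == 0) "more_in_endosperm"
      else if (ue == 0 && un == 0) "similar"
      else "mixed"
  }
  res
}

#' Expression-ratio class of a gene
#'
#' `higher_endosperm` when endosperm/embryo RPKM > `fold` (default 1.5),
#' `higher_embryo` symmetrically, else `similar`. A zero denominator with a
#' nonzero numerator yields the corresponding "higher" label; 0/0 is
#' `similar`.
#'
#' @param rpkm_embryo,rpkm_endosperm non-negative RPKM vectors.
#' @param fold ratio threshold.
#' @return character vector of class labels.
#' @export
expression_class <- function(rpkm_embryo, rpkm_endosperm, fold = 1.5) {
  stopifnot(all(rpkm_embryo >= 0), all(rpkm_endosperm >= 0))
  ifelse(rpkm_embryo == 0 & rpkm_endosperm == 0, "similar",
    ifelse(rpkm_embryo == 0, "higher_endosperm",
      ifelse(rpkm_endosperm == 0, "higher_embryo",
        ifelse(rpkm_endosperm / rpkm_embryo > fold, "higher_endosperm",
          ifelse(rpkm_embryo / rpkm_endosperm > fold, "higher_embryo",
                 "similar")))))
}

#' Cross-tabulate methylation categories against expression classes
#'
#' Builds the contingency table of methylation category by expression class
#' over the methylated genes, and the overall percentages of genes
#' similarly vs differentially methylated (differential = embryo_only,
#' endosperm_only, more_in_embryo, more_in_endosperm or mixed). Percentages
#' are rounded half-up to one decimal. Genes lacking an expression record
#' are listed separately and excluded from the table (but not from the
#' overall split, which depends only on methylation).
#'
#' @param methylation output of [classify_gene_methylation()] (unmethylated
#'   genes are ignored).
#' @param expression data.frame `gene_id`, `rpkm_embryo`, `rpkm_endosperm`
#'   (see [read_expression()]); duplicate gene ids are an error.
#' @param fold expression-ratio threshold passed to [expression_class()].
#' @return list with `table` (expression class x methylation category),
#'   `summary` (list `n_methylated`, `n_similar`, `n_differential`,
#'   `similar_pct`, `differential_pct`) and `missing_expression` (gene ids).
#' @export
cross_tabulate <- function(methylation, expression, fold = 1.5) {
  if (anyDuplicated(methylation$gene_id))
    stop("duplicate gene ids in methylation table")
  if (anyDuplicated(expression$gene_id))
    stop("duplicate gene ids in expression table")
  meth <- methylation[methylation$category != "unmethylated", , drop = FALSE]
  similar <- sum(meth$category == "similar")
  diff <- nrow(meth) - similar
  n <- nrow(meth)
  missing <- setdiff(meth$gene_id, expression$gene_id)
  m <- merge(meth, expression, by = "gene_id")
  m$expr_class <- expression_class(m$rpkm_embryo, m$rpkm_endosperm, fold)
  cat_levels <- c("embryo_only", "endosperm_only", "more_in_embryo",
                  "more_in_endosperm", "mixed", "similar")
  tab <- table(factor(m$expr_class,
                      levels = c("higher_endosperm", "higher_embryo",
                                 "similar")),
               factor(m$category, levels = cat_levels))
  list(table = tab,
       summary = list(
         n_methylated = n,
         n_similar = similar,
         n_differential = diff,
         similar_pct = if (n) round_half_up(100 * similar / n) else NA_real_,
         differential_pct = if (n) round_half_up(100 * diff / n)
                            else NA_real_),
       missing_expression = missing)
}
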