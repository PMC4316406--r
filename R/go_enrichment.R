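#' One-sided hypergeometric overrepresentation p-value
#'
#' The probability, under sampling without replacement, of observing at
#' least `count_study` term-annotated genes in a study set of `n_study`
#' genes drawn from a background of `n_pop` genes of which `count_pop` carry
#' the term:
#' p = sum_{j >= count_study} C(count_pop, j) C(n_pop - count_pop,
#' n_study - j) / C(n_pop, n_study).
#'
#' @param count_study term-annotated genes in the study set.
#' @param n_study study-set size.
#' @param count_pop term-annotated genes in the background.
#' @param n_pop background size.
#' @return p-value in \[0, 1\].
#' @export
fisher_overrep <- function(count_study, n_study, count_pop, n_pop) {
  if (any(c(count_study, n_study, count_pop, n_pop) < 0) ||
      n_study > n_pop || count_pop > n_pop ||
      count_study > min(count_pop, n_study))
    stop("inconsistent contingency counts")
  stats::phyper(count_study - 1, count_pop, n_pop - count_pop, n_study,
                lower.tail = FALSE)
}

#' GO-term overrepresentation of DMR-containing genes
#'
#' Tests every GO term annotated to at least one background gene for
#' overrepresentation in the study set (one-sided Fisher's exact /
#' hypergeometric test). No GO-graph ancestor propagation is applied: the
#' input mapping is used as-is. Raw p < `alpha` defines significance;
#' Benjamini-Hochberg adjusted p-values are added when `bh = TRUE` but do
#' not change the `significant` flag.
#'
#' @param study_genes character vector of study gene ids (e.g. genes
#'   containing DMRs); must be a subset of `background_genes`.
#' @param background_genes character vector of background gene ids.
#' @param go_map data.frame `gene_id`, `go_id` and optionally `go_name`.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param bh add a Benjamini-Hochberg `p_adjust` column.
#' @return data.frame `go_id`, `go_name` (when available), `count_study`,
#'   `n_study`, `count_pop`, `n_pop`, `p_value`, `significant`, sorted by
#'   increasing p (ties by go_id).
#' @export
enrich <- function(study_genes, background_genes, go_map, alpha = 0.05,
                   bh = FALSE) {
  study <- unique(study_genes)
  pop <- unique(background_genes)
  stray <- setdiff(study, pop)
  if (length(stray))
    stop("study gene(s) absent from background: ",
         paste(stray, collapse = ", "))
  map <- go_map[go_map$gene_id %in% pop, , drop = FALSE]
  map <- unique(map[, intersect(c("gene_id", "go_id", "go_name"),
                                names(map)), drop = FALSE])
  terms <- sort(unique(map$go_id))
  n_study <- length(study); n_pop <- length(pop)
  res <- lapply(terms, function(tm) {
    genes <- unique(map$gene_id[map$go_id == tm])
    cs <- sum(genes %in% study)
    data.frame(go_id = tm,
               go_name = if ("go_name" %in% names(map))
                 map$go_name[map$go_id == tm][1] else NA_character_,
               count_study = cs, n_study = n_study,
               count_pop = length(genes), n_pop = n_pop,
               p_value = fisher_overrep(cs, n_study, length(genes), n_pop),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(go_id = character(0), go_name = character(0),
                      count_study = integer(0), n_study = integer(0),
                      count_pop = integer(0), n_pop = integer(0),
                      p_value = numeric(0))
  res <- res[order(res$p_value, res$go_id), , drop = FALSE]
  res$significant <- res$p_value < alpha
  if (bh) res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}
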