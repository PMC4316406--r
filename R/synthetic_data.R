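#' Configuration for the synthetic two-tissue methylome
#'
#' Builds and validates the parameter set of the seeded generator. The
#' defaults describe the study conditions the generator emulates: a
#' CpG-depleted background genome at 47% GC carrying CpG-rich islands,
#' non-overlapping genes with 2-kb promoter/TTR flanks, intergenic
#' transposable elements, and a globally hypermethylated "embryo" tissue
#' versus a hypomethylated "endosperm" (element-wise methylation
#' probabilities 0.8 vs 0.35). Planted differentially methylated regions
#' carry an embryo:endosperm expected-depth ratio of `dmr_fold`.
#'
#' @param seed integer RNG seed; the same seed yields byte-identical
#'   outputs.
#' @param n_chroms,chrom_length genome shape.
#' @param background_gc background GC fraction.
#' @param cpg_depletion fraction of background CpG dinucleotides retained
#'   (real genomes are CpG-depleted; 0.2 gives background O/E ~ 0.2 so
#'   island detection is non-trivial).
#' @param n_cgis,cgi_length_range planted CpG islands.
#' @param n_genes,gene_length_range gene models (placed with >= 2-kb
#'   flanks).
#' @param n_tes,te_length_range intergenic transposable elements.
#' @param n_intergenic,intergenic_length_range additional intergenic
#'   methylation elements (planted DMRs are drawn from these).
#' @param frac_methylated_embryo,frac_methylated_endosperm element-wise
#'   methylation probabilities per tissue.
#' @param gene_body_meth_factor multiplier on the methylation probability of
#'   gene-body elements (promoters/TTRs methylate at the full rate, so
#'   metagene profiles show the promoter/TTR excess).
#' @param n_planted_dmrs number of planted fold-change DMRs (must not
#'   exceed `n_intergenic`).
#' @param dmr_fold true embryo:endosperm expected depth ratio in planted
#'   DMRs (> 1; direction alternates).
#' @param mean_depth expected reads per methylated element.
#' @param background_rate background read rate for unmethylated elements,
#'   as a fraction of `mean_depth`.
#' @param read_length read length (bp).
#' @param library_size named vector `c(embryo=, endosperm=)` of nominal
#'   total mapped reads used for normalization.
#' @param promoter_len,ttr_len flank extents (bp).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2,
                       chrom_length = 400000,
                       background_gc = 0.47,
                       cpg_depletion = 0.2,
                       n_cgis = 30,
                       cgi_length_range = c(300, 800),
                       n_genes = 20,
                       gene_length_range = c(1000, 3000),
                       n_tes = 15,
                       te_length_range = c(500, 1500),
                       n_intergenic = 60,
                       intergenic_length_range = c(400, 1000),
                       frac_methylated_embryo = 0.8,
                       frac_methylated_endosperm = 0.35,
                       gene_body_meth_factor = 0.3,
                       n_planted_dmrs = 10,
                       dmr_fold = 8,
                       mean_depth = 40,
                       background_rate = 0.05,
                       read_length = 50,
                       library_size = c(embryo = 1e6, endosperm = 1e6),
                       promoter_len = 2000,
                       ttr_len = 2000) {
  cfg <- as.list(environment())
  fracs <- c(cfg$background_gc, cfg$cpg_depletion,
             cfg$frac_methylated_embryo, cfg$frac_methylated_endosperm,
             cfg$background_rate, cfg$gene_body_meth_factor)
  if (any(fracs < 0) || any(fracs > 1))
    stop("all fractions must lie in [0, 1]")
  if (cfg$dmr_fold <= 1) stop("dmr_fold must be > 1")
  if (cfg$n_planted_dmrs > cfg$n_intergenic)
    stop("n_planted_dmrs cannot exceed n_intergenic")
  if (cfg$mean_depth <= 0 || cfg$chrom_length <= 0 || cfg$n_chroms < 1)
    stop("invalid genome/depth configuration")
  if (!all(c("embryo", "endosperm") %in% names(cfg$library_size)) ||
      any(cfg$library_size <= 0))
    stop("library_size must be a positive named vector (embryo, endosperm)")
  structure(cfg, class = "sim_config")
}

# i.i.d. background at the target GC, then CpG depletion: each CG
# dinucleotide is retained with prob `depletion`; otherwise its G is
# replaced by A/T/C drawn proportionally to the background composition.
random_background <- function(n, gc, depletion) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(names(probs), n, replace = TRUE, prob = probs)
  repl_probs <- probs[c("A", "T", "C")] / sum(probs[c("A", "T", "C")])
  for (pass in 1:2) {
    cg <- which(x[-n] == "C" & x[-1] == "G")
    if (!length(cg)) break
    drop <- cg[stats::runif(length(cg)) > depletion]
    if (length(drop))
      x[drop + 1] <- sample(names(repl_probs), length(drop),
                            replace = TRUE, prob = repl_probs)
  }
  paste(x, collapse = "")
}

# CpG-rich island sequence: token sampling tuned so GC >= 60% and
# O/E >= 1.0 hold by construction (verified, resampled on the rare miss).
random_island <- function(len) {
  tokens <- c("CG", "C", "G", "A", "T")
  probs <- c(0.30, 0.16, 0.16, 0.19, 0.19)
  for (try in 1:50) {
    tk <- sample(tokens, len, replace = TRUE, prob = probs)
    s <- substr(paste(tk, collapse = ""), 1, len)
    st <- cpg_stats(s)
    if (st$gc_pct >= 60 && st$obs_exp >= 1.0) return(s)
  }
  stop("failed to generate a CpG island passing construction thresholds")
}

#' Simulate the synthetic genome, annotation and ground truth
#'
#' Generates chromosome sequences (CpG-depleted background with planted
#' CpG islands), non-overlapping gene models with 2-kb flanks, intergenic
#' TEs and intergenic methylation elements; assigns each element a
#' per-tissue methylation state and expected MeDIP depth; plants fold-change
#' DMRs; and draws a synthetic expression table and gene->GO mapping for the
#' downstream comparisons. Deterministic given `config$seed`.
#'
#' @param config `sim_config` object.
#' @return list of class `sim_genome` with `seqs` (named sequences),
#'   `chrom_lengths`, `models` (`gene_models`), `tes`, `expression`,
#'   `go_map` and `truth` (list: `elements`, `cgis`, `dmrs`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))

  # round-robin element descriptors across chromosomes
  kinds <- c(rep("cgi", config$n_cgis), rep("gene", config$n_genes),
             rep("te", config$n_tes), rep("intergenic", config$n_intergenic))
  kinds <- sample(kinds)
  chrom_of <- rep_len(chroms, length(kinds))

  rint <- function(rng) sample(seq(rng[1], rng[2]), 1)
  gap <- 600
  placed <- list(); cursor <- stats::setNames(rep(500, length(chroms)),
                                              chroms)
  el <- 0L
  for (i in seq_along(kinds)) {
    kind <- kinds[i]; chrom <- chrom_of[i]
    len <- switch(kind,
                  cgi = rint(config$cgi_length_range),
                  gene = rint(config$gene_length_range),
                  te = rint(config$te_length_range),
                  intergenic = rint(config$intergenic_length_range))
    flank <- if (kind == "gene") max(config$promoter_len, config$ttr_len)
             else 0
    start <- cursor[[chrom]] + flank
    end <- start + len
    cursor[[chrom]] <- end + flank + gap
    if (cursor[[chrom]] > config$chrom_length - 500)
      stop("capacity error: requested elements do not fit the genome")
    el <- el + 1L
    placed[[el]] <- data.frame(kind = kind, chrom = chrom, start = start,
                               end = end, stringsAsFactors = FALSE)
  }
  placed <- do.call(rbind, placed)

  # sequences: background then island overwrite
  seqs <- stats::setNames(vapply(chroms, function(ch)
    random_background(config$chrom_length, config$background_gc,
                      config$cpg_depletion), ""), chroms)
  cgis <- placed[placed$kind == "cgi", , drop = FALSE]
  for (i in seq_len(nrow(cgis))) {
    isl <- random_island(cgis$end[i] - cgis$start[i])
    s <- seqs[[cgis$chrom[i]]]
    substr(s, cgis$start[i] + 1, cgis$end[i]) <- isl
    seqs[[cgis$chrom[i]]] <- s
  }

  # gene models: 1-3 exons, UTRs and CDS within first/last exon
  gene_rows <- which(placed$kind == "gene")
  genes <- list(); feats <- list()
  for (j in seq_along(gene_rows)) {
    r <- placed[gene_rows[j], ]
    gid <- sprintf("gene%03d", j)
    strand <- sample(c("+", "-"), 1)
    len <- r$end - r$start
    n_ex <- sample(1:min(3, max(1, len %/% 600)), 1)
    # cut introns of 80-300 bp between exons, exons >= 200 bp
    bounds <- c(0, len)
    ex_start <- 0; ex_end <- len
    if (n_ex > 1) {
      ok <- FALSE
      for (try in 1:20) {
        cuts <- sort(sample(seq(200, len - 200), n_ex - 1))
        ints <- pmin(300, pmax(80, 100 + stats::rpois(n_ex - 1, 50)))
        s0 <- c(0, cuts + ints)
        e0 <- c(cuts, len)
        if (all(e0 - s0 >= 200) && all(s0 < e0) &&
            all(utils::head(e0, -1) <= utils::tail(s0, -1))) {
          ex_start <- s0; ex_end <- e0; ok <- TRUE; break
        }
      }
      if (!ok) { ex_start <- 0; ex_end <- len }
    }
    ex_start <- r$start + ex_start; ex_end <- r$start + ex_end
    fl <- data.frame(gene_id = gid, feature = "exon", chrom = r$chrom,
                     start = ex_start, end = ex_end,
                     stringsAsFactors = FALSE)
    if (length(ex_start) > 1)
      fl <- rbind(fl, data.frame(gene_id = gid, feature = "intron",
                                 chrom = r$chrom,
                                 start = ex_end[-length(ex_end)],
                                 end = ex_start[-1],
                                 stringsAsFactors = FALSE))
    # UTRs: 100 bp at the transcript ends (inside first/last exon)
    u <- 100
    first_ex <- 1; last_ex <- length(ex_start)
    left_utr <- c(ex_start[first_ex], ex_start[first_ex] + u)
    right_utr <- c(ex_end[last_ex] - u, ex_end[last_ex])
    utr5 <- if (strand == "+") left_utr else right_utr
    utr3 <- if (strand == "+") right_utr else left_utr
    cds_start <- ex_start; cds_end <- ex_end
    cds_start[first_ex] <- left_utr[2]
    cds_end[last_ex] <- right_utr[1]
    keep <- cds_start < cds_end
    fl <- rbind(fl,
      data.frame(gene_id = gid, feature = "utr5", chrom = r$chrom,
                 start = utr5[1], end = utr5[2], stringsAsFactors = FALSE),
      data.frame(gene_id = gid, feature = "utr3", chrom = r$chrom,
                 start = utr3[1], end = utr3[2], stringsAsFactors = FALSE),
      data.frame(gene_id = gid, feature = "cds", chrom = r$chrom,
                 start = cds_start[keep], end = cds_end[keep],
                 stringsAsFactors = FALSE))
    genes[[j]] <- data.frame(gene_id = gid, chrom = r$chrom,
                             start = r$start, end = r$end, strand = strand,
                             stringsAsFactors = FALSE)
    feats[[j]] <- fl
  }
  models <- structure(list(
    genes = if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0),
                 strand = character(0)),
    features = if (length(feats)) do.call(rbind, feats) else
      data.frame(gene_id = character(0), feature = character(0),
                 chrom = character(0), start = numeric(0),
                 end = numeric(0))), class = "gene_models")
  rownames(models$genes) <- rownames(models$features) <- NULL

  tes <- placed[placed$kind == "te", c("chrom", "start", "end"),
                drop = FALSE]
  if (nrow(tes)) {
    tes$te_id <- sprintf("te%03d", seq_len(nrow(tes)))
    tes$family <- sample(c("MuDR", "gypsy", "copia", "CACTA", "other"),
                         nrow(tes), replace = TRUE)
  } else {
    tes$te_id <- character(0); tes$family <- character(0)
  }
  rownames(tes) <- NULL

  chrom_lengths <- stats::setNames(rep(config$chrom_length,
                                       length(chroms)), chroms)

  # eligible methylation elements: islands, TEs, intergenic, and per-gene
  # promoter / body / TTR
  elements <- placed
  g <- models$genes
  if (nrow(g)) {
    plus <- g$strand == "+"
    prom <- data.frame(kind = "promoter", chrom = g$chrom,
                       start = ifelse(plus, g$start - config$promoter_len,
                                      g$end),
                       end = ifelse(plus, g$start,
                                    g$end + config$promoter_len),
                       stringsAsFactors = FALSE)
    ttr <- data.frame(kind = "ttr", chrom = g$chrom,
                      start = ifelse(plus, g$end,
                                     g$start - config$ttr_len),
                      end = ifelse(plus, g$end + config$ttr_len, g$start),
                      stringsAsFactors = FALSE)
    body <- data.frame(kind = "gene_body", chrom = g$chrom,
                       start = g$start, end = g$end,
                       stringsAsFactors = FALSE)
    elements <- rbind(elements[elements$kind != "gene", ],
                      prom, body, ttr)
  }
  elements <- elements[order(elements$chrom, elements$start), ,
                       drop = FALSE]
  elements$element_id <- sprintf("el%05d", seq_len(nrow(elements)))

  p_e <- ifelse(elements$kind == "gene_body",
                config$frac_methylated_embryo * config$gene_body_meth_factor,
                config$frac_methylated_embryo)
  p_n <- ifelse(elements$kind == "gene_body",
                config$frac_methylated_endosperm *
                  config$gene_body_meth_factor,
                config$frac_methylated_endosperm)
  elements$meth_embryo <- stats::runif(nrow(elements)) < p_e
  elements$meth_endosperm <- stats::runif(nrow(elements)) < p_n
  elements$planted_dmr <- FALSE
  elements$dmr_direction <- NA_character_
  ig <- which(elements$kind == "intergenic")
  planted <- if (config$n_planted_dmrs > 0)
    sort(sample(ig, config$n_planted_dmrs)) else integer(0)
  if (length(planted)) {
    elements$planted_dmr[planted] <- TRUE
    elements$meth_embryo[planted] <- TRUE
    elements$meth_endosperm[planted] <- TRUE
    elements$dmr_direction[planted] <-
      rep_len(c("up_embryo", "up_endosperm"), length(planted))
  }
  elements$depth_embryo <- ifelse(elements$meth_embryo, config$mean_depth, 0)
  elements$depth_endosperm <- ifelse(elements$meth_endosperm,
                                     config$mean_depth, 0)
  up_e <- elements$planted_dmr &
    elements$dmr_direction == "up_embryo" & !is.na(elements$dmr_direction)
  up_n <- elements$planted_dmr &
    elements$dmr_direction == "up_endosperm" & !is.na(elements$dmr_direction)
  elements$depth_endosperm[up_e] <- config$mean_depth / config$dmr_fold
  elements$depth_embryo[up_n] <- config$mean_depth / config$dmr_fold

  true_dmr <- elements$planted_dmr |
    (elements$meth_embryo != elements$meth_endosperm)
  dmrs <- elements[true_dmr, , drop = FALSE]
  dmrs$dmr_direction[is.na(dmrs$dmr_direction)] <-
    ifelse(dmrs$meth_embryo[is.na(dmrs$dmr_direction)],
           "up_embryo", "up_endosperm")

  # synthetic expression (log-normal RPKM) and gene->GO mapping
  expression <- data.frame(
    gene_id = models$genes$gene_id,
    rpkm_embryo = round(stats::rlnorm(nrow(models$genes), 1, 1), 3),
    rpkm_endosperm = round(stats::rlnorm(nrow(models$genes), 1, 1), 3),
    stringsAsFactors = FALSE)
  terms <- sprintf("GO:%07d", seq_len(max(5, nrow(models$genes) %/% 2)))
  go_map <- do.call(rbind, lapply(models$genes$gene_id, function(gid)
    data.frame(gene_id = gid,
               go_id = sample(terms, sample(1:3, 1)),
               stringsAsFactors = FALSE)))
  if (is.null(go_map))
    go_map <- data.frame(gene_id = character(0), go_id = character(0))

  structure(list(
    seqs = seqs, chrom_lengths = chrom_lengths, models = models,
    tes = tes, expression = expression, go_map = go_map, config = config,
    truth = list(elements = elements,
                 cgis = cgis[, c("chrom", "start", "end")],
                 dmrs = dmrs)), class = "sim_genome")
}

#' Simulate MeDIP peaks and read positions from ground truth
#'
#' Every element methylated in a tissue emits a peak over its span (with
#' diffScore >= 50, so peaks survive the significance filter) and a
#' Poisson(`depth`) number of reads placed uniformly within the element.
#' Unmethylated elements emit sparse background reads
#' (rate `background_rate * mean_depth`) and no peak, so zero-count regions
#' occur naturally. Deterministic given the config seed.
#'
#' @param config `sim_config` object.
#' @param sim `sim_genome` from [simulate_genome()].
#' @return list of class `sim_medip`: `peaks` and `reads`, each a named
#'   list with `embryo` and `endosperm` data.frames.
#' @export
simulate_medip <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"), inherits(sim, "sim_genome"))
  set.seed(config$seed + 1L)
  el <- sim$truth$elements
  out <- list(peaks = list(), reads = list())
  for (tissue in c("embryo", "endosperm")) {
    meth <- el[[paste0("meth_", tissue)]]
    depth <- el[[paste0("depth_", tissue)]]
    lambda <- ifelse(meth, depth, config$background_rate * config$mean_depth)
    k <- stats::rpois(nrow(el), lambda)
    # reads: uniform starts within each element
    idx <- rep(seq_len(nrow(el)), k)
    rl <- config$read_length
    smax <- pmax(el$start, el$end - rl)
    starts <- floor(stats::runif(length(idx), min = el$start[idx],
                                 max = smax[idx] + 1))
    reads <- data.frame(chrom = el$chrom[idx], start = starts,
                        end = pmin(starts + rl, el$end[idx] + rl),
                        stringsAsFactors = FALSE)
    reads <- reads[order(reads$chrom, reads$start), , drop = FALSE]
    rownames(reads) <- NULL
    peaks <- data.frame(chrom = el$chrom[meth], start = el$start[meth],
                        end = el$end[meth], read_count = k[meth],
                        diff_score = round(50 + k[meth] / 4, 1),
                        stringsAsFactors = FALSE)
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL
    out$peaks[[tissue]] <- peaks
    out$reads[[tissue]] <- reads
  }
  structure(out, class = "sim_medip")
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits genome FASTA, gene GFF3, TE BED, per-tissue peak TSVs and read
#' BEDs, plus expression and GO-map TSVs — exactly the formats the readers
#' of the package consume. Writing is deterministic: the same simulation
#' yields byte-identical files.
#'
#' @param sim `sim_genome` object.
#' @param medip `sim_medip` object.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, medip, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    tes = file.path(dir, "tes.bed"),
    peaks_embryo = file.path(dir, "peaks_embryo.tsv"),
    peaks_endosperm = file.path(dir, "peaks_endosperm.tsv"),
    reads_embryo = file.path(dir, "reads_embryo.bed"),
    reads_endosperm = file.path(dir, "reads_endosperm.bed"),
    expression = file.path(dir, "expression.tsv"),
    go_map = file.path(dir, "go_map.tsv"))
  write_fasta(sim$seqs, paths[["genome"]])
  write_gff3_genes(sim$models, paths[["genes"]])
  write_bed(sim$tes[, c("chrom", "start", "end")], paths[["tes"]])
  write_peaks(medip$peaks$embryo, paths[["peaks_embryo"]])
  write_peaks(medip$peaks$endosperm, paths[["peaks_endosperm"]])
  write_bed(medip$reads$embryo, paths[["reads_embryo"]])
  write_bed(medip$reads$endosperm, paths[["reads_endosperm"]])
  write_table_tsv(sim$expression, paths[["expression"]])
  write_table_tsv(sim$go_map, paths[["go_map"]])
  invisible(paths)
}
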