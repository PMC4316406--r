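#' Default run configuration
#'
#' Assembles the full parameter set of an end-to-end run: the simulation
#' config plus every module threshold (CGI thresholds, promoter/TTR
#' extents, HCP/LCP window and cutoffs, DMR alpha, profile window width and
#' metagene bins).
#'
#' @param seed integer seed driving the whole run.
#' @param ... overrides for any top-level key or [sim_config()] argument.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, ...) {
  dots <- list(...)
  sim_args <- dots[names(dots) %in% names(formals(sim_config))]
  cfg <- list(
    seed = seed,
    sim = do.call(sim_config, c(list(seed = seed), sim_args)),
    cgi = list(min_length = 200, min_oe = 0.6, min_gc = 50,
               window = 100, merge_gap = 100, shore_width = 2000),
    peaks = list(min_diff_score = 50, max_p = 1e-5),
    dmr = list(alpha = 0.001),
    promoter = list(promoter_len = 2000, ttr_len = 2000,
                    window = 500, step = 5, r_min = 0.75, g_min = 0.55),
    profile = list(window_width = 10000, bins = c(20, 40, 20)),
    go = list(alpha = 0.05))
  top <- dots[!names(dots) %in% names(formals(sim_config))]
  for (nm in names(top)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], top[[nm]])
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with any subset of the keys of
#'   [default_run_config()].
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1
  sim_args <- y$sim[names(y$sim) %in% names(formals(sim_config))]
  args <- c(list(seed = seed), sim_args,
            y[setdiff(names(y), c("seed", "sim"))])
  do.call(default_run_config, args)
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  a <- cfg$dmr$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1)
    stop("config error: dmr alpha must lie in (0, 1)")
  if (cfg$profile$window_width <= 0)
    stop("config error: profile window_width must be positive")
  if (cfg$cgi$min_length <= 0 || cfg$cgi$min_oe < 0 || cfg$cgi$min_gc < 0 ||
      cfg$cgi$min_gc > 100)
    stop("config error: CGI thresholds out of range")
  invisible(cfg)
}

run_stage <- function(name, expr) {
  message(format(Sys.time(), "%H:%M:%S"), " [", name, "] start")
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(format(Sys.time(), "%H:%M:%S"), " [", name, "] done")
  res
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate -> CGI detection -> region unification -> DMR calling
#' -> feature annotation -> profiling -> imprinting comparison -> GO
#' enrichment in dependency order, writing one TSV per stage plus a JSON
#' run manifest (package version, seed, parameter hash, file checksums)
#' into `out_dir`. A rerun with the same configuration is byte-identical.
#'
#' @param config `run_config` (see [default_run_config()]).
#' @param out_dir output directory.
#' @return named list with the in-memory stage results, invisibly.
#' @export
run_all <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- run_stage("simulate", {
    s <- simulate_genome(config$sim)
    m <- simulate_medip(config$sim, s)
    write_simulation(s, m, file.path(out_dir, "input"))
    list(genome = s, medip = m)
  })
  inp <- file.path(out_dir, "input")
  chrom_lengths <- sim$genome$chrom_lengths
  lib <- config$sim$library_size

  cgi <- run_stage("cgi", {
    seqs <- read_fasta(file.path(inp, "genome.fa"))
    islands <- find_cgis(seqs, config$cgi$min_length, config$cgi$min_oe,
                         config$cgi$min_gc, config$cgi$window,
                         config$cgi$merge_gap)
    shores <- derive_shores(islands, chrom_lengths, config$cgi$shore_width)
    write_table_tsv(islands, file.path(out_dir, "cgis.tsv"))
    write_table_tsv(shores, file.path(out_dir, "shores.tsv"))
    list(seqs = seqs, islands = islands, shores = shores)
  })

  regions <- run_stage("unify", {
    pe <- read_peaks(file.path(inp, "peaks_embryo.tsv"),
                     config$peaks$min_diff_score, config$peaks$max_p)
    pn <- read_peaks(file.path(inp, "peaks_endosperm.tsv"),
                     config$peaks$min_diff_score, config$peaks$max_p)
    reg <- unify(pe, pn, chroms = names(chrom_lengths))
    write_table_tsv(reg, file.path(out_dir, "regions.tsv"))
    list(embryo = pe, endosperm = pn, regions = reg)
  })

  calls <- run_stage("call", {
    cl <- call_dmrs(regions$regions, lib[["embryo"]], lib[["endosperm"]],
                    alpha = config$dmr$alpha)
    write_table_tsv(cl, file.path(out_dir, "dmrs.tsv"))
    cl
  })

  annot <- run_stage("annotate", {
    models <- read_gff3_genes(file.path(inp, "genes.gff3"))
    models <- derive_promoter_ttr(models, chrom_lengths,
                                  config$promoter$promoter_len,
                                  config$promoter$ttr_len)
    tes <- read_reads_bed(file.path(inp, "tes.bed"), chrom_lengths)
    fsets <- list(promoter = feature_intervals(models, "promoter"),
                  ttr = feature_intervals(models, "ttr"),
                  exon = feature_intervals(models, "exon"),
                  intron = feature_intervals(models, "intron"),
                  cds = feature_intervals(models, "cds"),
                  utr5 = feature_intervals(models, "utr5"),
                  utr3 = feature_intervals(models, "utr3"),
                  cgi = cgi$islands, shore = cgi$shores)
    per_tissue <- lapply(list(embryo = regions$embryo,
                              endosperm = regions$endosperm),
                         annotate_overlaps, feature_sets = fsets)
    ann_tab <- do.call(rbind, lapply(names(per_tissue), function(t)
      cbind(tissue = t, per_tissue[[t]]$counts)))
    write_table_tsv(ann_tab, file.path(out_dir, "feature_methylation.tsv"))
    pc <- classify_promoter_cpg(cgi$seqs, fsets$promoter, "promoter",
                                config$promoter$window, config$promoter$step,
                                config$promoter$r_min, config$promoter$g_min)
    tc <- classify_promoter_cpg(cgi$seqs, fsets$ttr, "ttr",
                                config$promoter$window, config$promoter$step,
                                config$promoter$r_min, config$promoter$g_min)
    write_table_tsv(rbind(pc, tc), file.path(out_dir,
                                             "promoter_ttr_classes.tsv"))
    te_ann <- annotate_tes(tes, list(embryo = regions$embryo,
                                     endosperm = regions$endosperm))
    write_table_tsv(te_ann$summary, file.path(out_dir, "te_summary.tsv"))
    dd <- dmr_distribution(calls, fsets)
    write_table_tsv(dd, file.path(out_dir, "dmr_distribution.tsv"))
    list(models = models, feature_sets = fsets, per_tissue = per_tissue,
         promoter_classes = rbind(pc, tc), te = te_ann,
         dmr_distribution = dd)
  })

  profiles <- run_stage("profile", {
    out <- list()
    for (tissue in c("embryo", "endosperm")) {
      reads <- read_reads_bed(file.path(inp, paste0("reads_", tissue,
                                                    ".bed")),
                              chrom_lengths)
      wc <- window_counts(reads, chrom_lengths, config$profile$window_width)
      mg <- metagene(reads, annot$models, chrom_lengths, lib[[tissue]],
                     config$promoter$promoter_len, config$promoter$ttr_len,
                     config$profile$bins)
      wc$tissue <- tissue; mg$tissue <- tissue
      out[[tissue]] <- list(windows = wc, metagene = mg)
    }
    write_table_tsv(rbind(out$embryo$windows, out$endosperm$windows),
                    file.path(out_dir, "window_counts.tsv"))
    write_table_tsv(rbind(out$embryo$metagene, out$endosperm$metagene),
                    file.path(out_dir, "metagene.tsv"))
    out
  })

  imprint <- run_stage("imprinting", {
    meth <- classify_gene_methylation(annot$models, calls)
    expr <- read_expression(file.path(inp, "expression.tsv"))
    ct <- cross_tabulate(meth, expr)
    write_table_tsv(meth, file.path(out_dir, "gene_methylation.tsv"))
    write_table_tsv(as.data.frame(ct$table),
                    file.path(out_dir, "imprinting_crosstab.tsv"))
    list(methylation = meth, crosstab = ct)
  })

  enrichment <- run_stage("enrich", {
    go_map <- read_go_map(file.path(inp, "go_map.tsv"))
    meth <- imprint$methylation
    background <- meth$gene_id[meth$category != "unmethylated"]
    study <- meth$gene_id[meth$category %in%
                            c("embryo_only", "endosperm_only",
                              "more_in_embryo", "more_in_endosperm",
                              "mixed")]
    er <- if (length(background) && length(study))
      enrich(study, background, go_map, alpha = config$go$alpha)
    else data.frame()
    write_table_tsv(er, file.path(out_dir, "go_enrichment.tsv"))
    er
  })

  manifest <- run_stage("manifest", {
    files <- sort(c(list.files(out_dir, pattern = "\\.tsv$",
                               full.names = TRUE),
                    list.files(inp, full.names = TRUE)))
    sums <- as.character(tools::md5sum(files))
    cfg_str <- paste(utils::capture.output(utils::str(unclass(config))),
                     collapse = "\n")
    man <- list(
      package = "medipdmr",
      version = as.character(utils::packageVersion("medipdmr")),
      seed = config$seed,
      parameter_hash = substr(tools::md5sum(
        textConnection_write(cfg_str, out_dir)), 1, 32),
      files = stats::setNames(as.list(sums),
                              sub(paste0(out_dir, "/?"), "", files)))
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  })

  invisible(list(sim = sim, cgi = cgi, regions = regions, calls = calls,
                 annot = annot, profiles = profiles, imprint = imprint,
                 enrichment = enrichment, manifest = manifest))
}

# md5 of a string via a scratch file (tools::md5sum works on files only)
textConnection_write <- function(x, dir) {
  f <- file.path(dir, ".config_hash_tmp")
  writeLines(x, f)
  h <- tools::md5sum(f)
  unlink(f)
  h
}
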