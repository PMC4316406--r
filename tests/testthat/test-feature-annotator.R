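mk_models <- function(start, end, strand, chrom = "c1", gene_id = "g1") {
  structure(list(
    genes = data.frame(gene_id = gene_id, chrom = chrom, start = start,
                       end = end, strand = strand, stringsAsFactors = FALSE),
    features = data.frame(gene_id = gene_id, feature = "exon",
                          chrom = chrom, start = start, end = end,
                          stringsAsFactors = FALSE)),
    class = "gene_models")
}

test_that("promoter/TTR derivation respects strand and chromosome bounds", {
  m <- derive_promoter_ttr(mk_models(1000, 2000, "+"), c(c1 = 1e5))
  prom <- feature_intervals(m, "promoter")
  ttr <- feature_intervals(m, "ttr")
  expect_equal(c(prom$start, prom$end), c(0, 1000))  # clipped at 0
  expect_equal(c(ttr$start, ttr$end), c(2000, 4000))

  m <- derive_promoter_ttr(mk_models(1000, 2000, "-"), c(c1 = 1e5))
  expect_equal(unlist(feature_intervals(m, "promoter")[, c("start", "end")]),
               c(start = 2000, end = 4000))
  expect_equal(unlist(feature_intervals(m, "ttr")[, c("start", "end")]),
               c(start = 0, end = 1000))

  expect_error(derive_promoter_ttr(mk_models(1000, 2000, "*"), c(c1 = 1e5)),
               "unstranded")

  m <- derive_promoter_ttr(mk_models(1000, 2000, "+"), c(c1 = 1e5),
                           promoter_len = 0, ttr_len = 0)
  expect_equal(nrow(feature_intervals(m, "promoter")), 0)
  expect_equal(nrow(feature_intervals(m, "ttr")), 0)
})

test_that("a single shared bp methylates a feature; items count per class", {
  fsets <- list(promoter = iv("c1", 0, 101), exon = iv("c1", 200, 300))
  ann <- annotate_overlaps(iv("c1", 100, 101), fsets)
  expect_equal(ann$counts$n_methylated[ann$counts$class == "promoter"], 1)
  expect_equal(ann$counts$n_methylated[ann$counts$class == "exon"], 0)

  # intergenic peak outside CGIs/shores lands only in "other"
  fsets <- list(cgi = iv("c1", 0, 100), shore = iv("c1", 100, 300),
                exon = iv("c1", 400, 500))
  ann <- annotate_overlaps(iv("c1", 1000, 1100), fsets)
  expect_equal(ann$item_classes$n_items[ann$item_classes$class == "other"], 1)
  expect_equal(sum(ann$item_classes$n_items[ann$item_classes$class !=
                                              "other"]), 0)
})

test_that("adding a peak never un-methylates a feature", {
  set.seed(31)
  fsets <- list(f = iv("c1", seq(0, 9000, 1000), seq(0, 9000, 1000) + 400))
  s <- sample(0:9500, 20)
  peaks <- iv("c1", s, s + 200)
  before <- annotate_overlaps(peaks[1:10, ], fsets)$status$f
  after <- annotate_overlaps(peaks, fsets)$status$f
  expect_true(all(after >= before))
})

test_that("exclusive mode makes CGI/shore/other a partition of the items", {
  set.seed(32)
  cgi <- iv("c1", c(1000, 5000), c(1400, 5300))
  shore <- derive_shores(cgi, c(c1 = 2e4))[, c("chrom", "start", "end")]
  s <- sample(0:19000, 50)
  items <- iv("c1", s, s + 600)  # long items can straddle CGI and shore
  ann <- annotate_overlaps(items, list(cgi = cgi, shore = shore),
                           exclusive = TRUE)
  expect_equal(sum(ann$item_classes$n_items), nrow(items))
})

test_that("CpG-content classes follow the max-window rule", {
  seqs <- c(c1 = paste0(strrep("CG", 1000), strrep("AT", 1000)))
  pc <- classify_promoter_cpg(seqs, iv("c1", 0, 2000), "promoter")
  expect_equal(pc$label, "HCP")
  expect_equal(pc$cpg_ratio, 2)
  expect_equal(pc$gc_frac, 1)

  # zero CpG dinucleotides -> LCP even at 100% GC
  seqs <- c(c1 = strrep("C", 2000))
  pc <- classify_promoter_cpg(seqs, iv("c1", 0, 2000), "promoter")
  expect_equal(pc$label, "LCP")
  expect_equal(pc$cpg_ratio, 0)

  # TTR kind uses the TTR label pair
  tc <- classify_promoter_cpg(c(c1 = strrep("CG", 300)), iv("c1", 0, 600),
                              "ttr")
  expect_equal(tc$label, "HCTTR")
})

test_that("CpG-depleted 47%-GC promoters classify as LCP", {
  set.seed(33)
  for (i in 1:100) {
    s <- random_seq(2000, gc = 0.47, cpg_keep = 0.2)
    pc <- classify_promoter_cpg(c(c1 = s), iv("c1", 0, 2000), "promoter")
    expect_equal(pc$label, "LCP")
  }
})

test_that("class labels are invariant under reverse complement", {
  revcomp <- function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(34)
  for (i in 1:10) {
    s <- random_seq(1500, gc = 0.6)
    a <- classify_promoter_cpg(c(c1 = s), iv("c1", 200, 1300), "promoter")
    b <- classify_promoter_cpg(c(c1 = revcomp(s)),
                               iv("c1", 1500 - 1300, 1500 - 200),
                               "promoter")
    expect_equal(a$label, b$label)
  }
})

test_that("TE methylation fractions reproduce printed-tally arithmetic", {
  n_te <- 184
  starts <- seq(0, by = 2000, length.out = n_te)
  tes <- iv("c1", starts, starts + 800)
  # all but 2 methylated in embryo; all but 64 in endosperm
  pk <- function(unmeth) peak_df("c1", starts[-(1:unmeth)] + 100,
                                 starts[-(1:unmeth)] + 300)
  ann <- annotate_tes(tes, list(embryo = pk(2), endosperm = pk(64)))
  s <- ann$summary
  expect_equal(s$pct_methylated[s$tissue == "embryo"], 98.9)
  expect_equal(round(s$pct_methylated[s$tissue == "embryo"]), 99)
  expect_equal(s$pct_unmethylated[s$tissue == "endosperm"], 34.8)
  # no peaks at all -> 0% methylated
  none <- annotate_tes(tes, list(embryo = peak_df("c1", numeric(0),
                                                  numeric(0))))
  expect_equal(none$summary$pct_methylated, 0)
})

test_that("DMR distribution counts each hit class once per DMR", {
  calls <- data.frame(chrom = "c1", start = c(100, 500), end = c(300, 700),
                      k_embryo = c(40, 2), k_endosperm = c(2, 40),
                      status = c("up_embryo", "up_endosperm"))
  fsets <- list(promoter = iv("c1", 0, 250), shore = iv("c1", 200, 400),
                exon = iv("c1", 900, 1000))
  dd <- dmr_distribution(calls, fsets)
  expect_equal(dd$up_embryo[dd$class == "promoter"], 1)
  expect_equal(dd$up_embryo[dd$class == "shore"], 1)   # same DMR, both classes
  expect_equal(dd$up_embryo[dd$class == "exon"], 0)
  expect_equal(sum(dd$up_endosperm), 0)
})
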