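# Gene spanning [1000,2000); helper builds calls whose regions lie inside.
gene_fixture <- function() {
  structure(list(
    genes = data.frame(gene_id = "g1", chrom = "c1", start = 1000,
                       end = 2000, strand = "+", stringsAsFactors = FALSE),
    features = data.frame(gene_id = character(0), feature = character(0),
                          chrom = character(0), start = numeric(0),
                          end = numeric(0))), class = "gene_models")
}

calls_fixture <- function(origins, statuses) {
  n <- length(origins)
  data.frame(chrom = rep_len("c1", n),
             start = 1000 + (seq_len(n) - 1) * 100,
             end = 1050 + (seq_len(n) - 1) * 100,
             origin = origins, status = statuses,
             k_embryo = rep_len(1, n), k_endosperm = rep_len(1, n),
             stringsAsFactors = FALSE)
}

test_that("origin of overlapping regions drives tissue methylation status", {
  m <- classify_gene_methylation(gene_fixture(),
                                 calls_fixture(character(0), character(0)))
  expect_equal(m$category, "unmethylated")

  m <- classify_gene_methylation(gene_fixture(),
                                 calls_fixture("embryo_only",
                                               "not_differential"))
  expect_equal(m$category, "embryo_only")
  expect_true(m$methylated_embryo)
  expect_false(m$methylated_endosperm)
})

test_that("classification matches the exhaustive rule-table oracle", {
  # all multisets of overlapping-region DMR statuses up to size 3, for a
  # gene with regions of origin "both" (methylated in both tissues)
  statuses <- c("up_embryo", "up_endosperm", "not_differential")
  oracle <- function(st) {
    ue <- sum(st == "up_embryo"); un <- sum(st == "up_endosperm")
    if (ue > 0 && un == 0) "more_in_embryo"
    else if (un > 0 && ue == 0) "more_in_endosperm"
    else if (ue == 0 && un == 0) "similar"
    else "mixed"
  }
  for (size in 1:3) {
    combos <- do.call(expand.grid,
                      rep(list(statuses), size))
    for (r in seq_len(nrow(combos))) {
      st <- as.character(unlist(combos[r, ]))
      m <- classify_gene_methylation(
        gene_fixture(), calls_fixture(rep("both", size), st))
      expect_equal(m$category, oracle(st),
                   info = paste(st, collapse = ","))
    }
  }
  # a non-DMR region alongside an up_embryo DMR still gives more_in_embryo
  m <- classify_gene_methylation(
    gene_fixture(), calls_fixture(c("both", "both"),
                                  c("up_embryo", "not_differential")))
  expect_equal(m$category, "more_in_embryo")
})

test_that("promoter and TTR overlap count toward gene methylation", {
  models <- derive_promoter_ttr(gene_fixture(), c(c1 = 1e5))
  # region only over the promoter flank [0,1000)
  calls <- data.frame(chrom = "c1", start = 100, end = 300,
                      origin = "embryo_only", status = "not_differential",
                      k_embryo = 10, k_endosperm = 0)
  m <- classify_gene_methylation(models, calls)
  expect_equal(m$category, "embryo_only")
})

test_that("expression ratio classes follow the 1.5-fold rule", {
  expect_equal(expression_class(c(1, 10, 4, 0, 0, 3),
                                c(2, 2, 5, 7, 0, 4.5)),
               c("higher_endosperm", "higher_embryo", "similar",
                 "higher_endosperm", "similar", "similar"))
})

test_that("the printed imprinting tallies give the 41.5/58.5 split", {
  # 25 genes higher in endosperm: 17 more/only-embryo, 4 more/only-endosperm,
  # 4 similar; 15 higher in embryo: 1 + 6 + 8; 25 similar expression: 10 + 15
  cats <- c(rep("more_in_embryo", 10), rep("embryo_only", 7),
            rep("more_in_endosperm", 2), rep("endosperm_only", 2),
            rep("similar", 4),
            rep("more_in_endosperm", 1), rep("more_in_embryo", 6),
            rep("similar", 8),
            rep("more_in_embryo", 10), rep("similar", 15))
  expr_class <- c(rep("higher_endosperm", 25), rep("higher_embryo", 15),
                  rep("similar", 25))
  rpkm <- list(higher_endosperm = c(1, 2), higher_embryo = c(2, 1),
               similar = c(1, 1))
  meth <- data.frame(gene_id = sprintf("g%02d", 1:65),
                     methylated_embryo = TRUE, methylated_endosperm = TRUE,
                     n_dmr_up_embryo = 0L, n_dmr_up_endosperm = 0L,
                     category = cats, stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = meth$gene_id,
                     rpkm_embryo = vapply(expr_class,
                                          function(x) rpkm[[x]][1], 1),
                     rpkm_endosperm = vapply(expr_class,
                                             function(x) rpkm[[x]][2], 1),
                     stringsAsFactors = FALSE)
  ct <- cross_tabulate(meth, expr)
  expect_equal(ct$summary$n_methylated, 65)
  expect_equal(ct$summary$n_differential, 38)
  expect_equal(ct$summary$similar_pct, 41.5)
  expect_equal(ct$summary$differential_pct, 58.5)
  tab <- ct$table
  expect_equal(sum(tab["higher_endosperm", ]), 25)
  expect_equal(sum(tab["higher_embryo", ]), 15)
  expect_equal(sum(tab["similar", ]), 25)
  expect_equal(unname(tab["higher_endosperm", "similar"]), 4)

  expect_error(cross_tabulate(rbind(meth, meth[1, ]), expr), "duplicate")
})

test_that("percentages always reconcile with direct counting", {
  set.seed(51)
  cats <- sample(c("embryo_only", "endosperm_only", "more_in_embryo",
                   "more_in_endosperm", "similar", "mixed"), 200,
                 replace = TRUE)
  meth <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     methylated_embryo = TRUE,
                     methylated_endosperm = TRUE,
                     n_dmr_up_embryo = 0L, n_dmr_up_endosperm = 0L,
                     category = cats, stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = meth$gene_id,
                     rpkm_embryo = runif(200, 0, 5),
                     rpkm_endosperm = runif(200, 0, 5))
  ct <- cross_tabulate(meth, expr)
  expect_equal(ct$summary$n_similar, sum(cats == "similar"))
  expect_equal(ct$summary$n_similar + ct$summary$n_differential, 200)
  expect_equal(ct$summary$similar_pct + ct$summary$differential_pct, 100,
               tolerance = 0.11)  # each side rounded to 1 decimal
})
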