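test_that("config validation rejects impossible settings", {
  expect_error(sim_config(background_gc = 1.2), "fractions")
  expect_error(sim_config(dmr_fold = 1), "dmr_fold")
  expect_error(sim_config(n_planted_dmrs = 100, n_intergenic = 10),
               "n_planted_dmrs")
  expect_error(sim_config(library_size = c(embryo = 0, endosperm = 1)),
               "library_size")
  # capacity: too many elements for the genome
  cfg <- sim_config(chrom_length = 20000, n_genes = 50)
  expect_error(simulate_genome(cfg), "capacity")
})

test_that("the same seed yields byte-identical simulated files", {
  cfg <- sim_config(seed = 42, n_cgis = 10, n_genes = 8, n_tes = 5,
                    n_intergenic = 20, n_planted_dmrs = 5,
                    chrom_length = 200000)
  d1 <- file.path(tempdir(), "simdet1"); d2 <- file.path(tempdir(),
                                                         "simdet2")
  s1 <- simulate_genome(cfg); write_simulation(s1, simulate_medip(cfg, s1),
                                               d1)
  s2 <- simulate_genome(cfg); write_simulation(s2, simulate_medip(cfg, s2),
                                               d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the genome
  cfg3 <- sim_config(seed = 43, n_cgis = 10, n_genes = 8, n_tes = 5,
                     n_intergenic = 20, n_planted_dmrs = 5,
                     chrom_length = 200000)
  s3 <- simulate_genome(cfg3)
  expect_false(identical(s1$seqs, s3$seqs))
})

test_that("planted structure is internally consistent", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_genome(cfg)
  el <- sim$truth$elements
  # every planted DMR is methylated in at least one tissue
  expect_true(all(el$meth_embryo[el$planted_dmr] |
                    el$meth_endosperm[el$planted_dmr]))
  # planted fold-DMRs carry the configured depth ratio
  up_e <- el$planted_dmr & el$dmr_direction == "up_embryo"
  expect_true(all(el$depth_embryo[up_e] / el$depth_endosperm[up_e] ==
                    cfg$dmr_fold))
  # elements never overlap (regions will match elements one-to-one)
  for (ch in unique(el$chrom)) {
    e <- el[el$chrom == ch, ]
    e <- e[order(e$start), ]
    expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
})

test_that("hypermethylated embryo emits more peaks than endosperm", {
  cfg <- sim_config(seed = 11)
  sim <- simulate_genome(cfg)
  medip <- simulate_medip(cfg, sim)
  expect_gt(nrow(medip$peaks$embryo), nrow(medip$peaks$endosperm))
  # elements methylated in neither tissue emit no peak in either
  el <- sim$truth$elements
  silent <- el[!el$meth_embryo & !el$meth_endosperm, ]
  for (tissue in c("embryo", "endosperm")) {
    hits <- overlaps_any(silent[, c("chrom", "start", "end")],
                         medip$peaks[[tissue]])
    expect_false(any(hits))
  }
})

test_that("background-only sequence yields almost no islands", {
  cfg <- sim_config(seed = 3, n_cgis = 0, n_genes = 0, n_tes = 0,
                    n_intergenic = 1, n_planted_dmrs = 0, n_chroms = 1,
                    chrom_length = 1000000)
  sim <- simulate_genome(cfg)
  expect_lte(nrow(find_cgis(sim$seqs)), 2)  # <= 2 per Mb
})

test_that("planted islands are recovered with reciprocal overlap", {
  cfg <- sim_config(seed = 19, n_cgis = 50, cgi_length_range = c(300, 700),
                    n_genes = 0, n_tes = 0, n_intergenic = 1,
                    n_planted_dmrs = 0, n_chroms = 2, chrom_length = 300000)
  sim <- simulate_genome(cfg)
  found <- find_cgis(sim$seqs)
  truth <- sim$truth$cgis
  recovered <- 0
  for (i in seq_len(nrow(truth))) {
    f <- found[found$chrom == truth$chrom[i], ]
    ov <- pmin(f$end, truth$end[i]) - pmax(f$start, truth$start[i])
    rec <- ov >= 0.5 * (truth$end[i] - truth$start[i]) &
      ov >= 0.5 * (f$end - f$start)
    if (any(rec)) recovered <- recovered + 1
  }
  expect_gte(recovered, 45)
})

test_that("a fold-free simulation produces almost no differential calls", {
  # all elements methylated in both tissues at equal depth; the only
  # planted fold-DMRs are excluded from the false-positive count
  cfg <- sim_config(seed = 23, n_chroms = 2, chrom_length = 400000,
                    n_cgis = 0, n_genes = 0, n_tes = 0, n_intergenic = 300,
                    n_planted_dmrs = 0, frac_methylated_embryo = 1,
                    frac_methylated_endosperm = 1)
  sim <- simulate_genome(cfg)
  medip <- simulate_medip(cfg, sim)
  reg <- unify(medip$peaks$embryo, medip$peaks$endosperm)
  calls <- call_dmrs(reg, cfg$library_size[["embryo"]],
                     cfg$library_size[["endosperm"]])
  expect_equal(nrow(calls), 300)
  expect_lte(summarize_dmr_calls(calls)$differential, 3)
})

test_that("planted fold-change DMRs are recovered with correct direction", {
  cfg <- sim_config(seed = 29, n_chroms = 2, chrom_length = 400000,
                    n_cgis = 0, n_genes = 0, n_tes = 0, n_intergenic = 200,
                    n_planted_dmrs = 30, dmr_fold = 8, mean_depth = 40,
                    frac_methylated_embryo = 1, frac_methylated_endosperm = 1)
  sim <- simulate_genome(cfg)
  medip <- simulate_medip(cfg, sim)
  reg <- unify(medip$peaks$embryo, medip$peaks$endosperm)
  calls <- call_dmrs(reg, cfg$library_size[["embryo"]],
                     cfg$library_size[["endosperm"]])
  el <- sim$truth$elements
  planted <- el[el$planted_dmr, ]
  key <- paste(calls$chrom, calls$start)
  hit <- match(paste(planted$chrom, planted$start), key)
  expect_false(any(is.na(hit)))
  ok <- calls$status[hit] == planted$dmr_direction
  expect_gte(sum(ok), 27)  # >= 90%
})
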