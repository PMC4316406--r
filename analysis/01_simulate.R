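#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-tissue methylome with planted ground
# truth and write every downstream input format (FASTA, GFF3, BED, peak
# TSVs, read BEDs, expression and GO tables).

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
a <- parse_analysis_args()
p <- paths_for(a$results)

cfg <- sim_config(seed = a$seed)
sim <- simulate_genome(cfg)
medip <- simulate_medip(cfg, sim)
write_simulation(sim, medip, p$input)

write_table_tsv(sim$truth$elements, file.path(p$results,
                                              "truth_elements.tsv"))
yaml::write_yaml(list(seed = a$seed,
                      library_size = as.list(cfg$library_size),
                      alpha = 0.001,
                      promoter_len = cfg$promoter_len,
                      ttr_len = cfg$ttr_len), p$params)

el <- sim$truth$elements
message("genome: ", cfg$n_chroms, " chromosomes x ",
        format(cfg$chrom_length, big.mark = ",", scientific = FALSE),
        " bp; ", nrow(el), " methylation-eligible elements")
message("methylated in embryo: ", sum(el$meth_embryo),
        "; in endosperm: ", sum(el$meth_endosperm),
        " (embryo hypermethylation planted)")
message("planted fold-", cfg$dmr_fold, " DMRs: ", sum(el$planted_dmr))
message("peaks written: embryo ", nrow(medip$peaks$embryo),
        ", endosperm ", nrow(medip$peaks$endosperm))
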