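#!/usr/bin/env Rscript
# Stage 2: detect CpG islands (200 bp / O/E 0.6 / GC 50%) on the genome
# sequence and derive their 2-kb shores.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
a <- parse_analysis_args()
p <- paths_for(a$results)

seqs <- read_fasta(p$genome)
islands <- find_cgis(seqs)
shores <- derive_shores(islands, setNames(nchar(seqs), names(seqs)))
write_table_tsv(islands, file.path(p$results, "cgis.tsv"))
write_table_tsv(shores, file.path(p$results, "shores.tsv"))

message(nrow(islands), " CpG islands (mean length ",
        round(mean(islands$length)), " bp, mean O/E ",
        round(mean(islands$obs_exp), 2), "), ", nrow(shores), " shores")
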