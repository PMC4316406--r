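#!/usr/bin/env Rscript
# Stage 5: 10-kb windowed chromosome read profiles and the
# promoter/gene-body/TTR metagene methylation-level curve per tissue.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
a <- parse_analysis_args()
p <- paths_for(a$results)
prm <- read_params(p)

chrom_lengths <- chrom_lengths_from_fasta(p$genome)
models <- read_gff3_genes(p$genes)

win <- list(); mg <- list()
for (tissue in c("embryo", "endosperm")) {
  reads <- read_reads_bed(p[[paste0("reads_", tissue)]], chrom_lengths)
  w <- window_counts(reads, chrom_lengths)
  m <- metagene(reads, models, chrom_lengths,
                prm$library_size[[tissue]],
                prm$promoter_len, prm$ttr_len)
  w$tissue <- tissue; m$tissue <- tissue
  win[[tissue]] <- w; mg[[tissue]] <- m
  seg <- tapply(m$level, m$segment, mean)
  message(tissue, ": total reads ", sum(w$count),
          "; metagene mean level promoter ", round(seg[["promoter"]], 2),
          ", body ", round(seg[["body"]], 2),
          ", TTR ", round(seg[["ttr"]], 2))
}
write_table_tsv(do.call(rbind, win),
                file.path(p$results, "window_counts.tsv"))
write_table_tsv(do.call(rbind, mg), file.path(p$results, "metagene.tsv"))
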