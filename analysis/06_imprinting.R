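#!/usr/bin/env Rscript
# Stage 6: classify each gene's methylation pattern across tissues and
# cross-tabulate against the 1.5-fold expression-ratio classes.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
a <- parse_analysis_args()
p <- paths_for(a$results)
prm <- read_params(p)

chrom_lengths <- chrom_lengths_from_fasta(p$genome)
models <- derive_promoter_ttr(read_gff3_genes(p$genes), chrom_lengths,
                              prm$promoter_len, prm$ttr_len)
calls <- utils::read.delim(file.path(p$results, "dmrs.tsv"))
meth <- classify_gene_methylation(models, calls)
expr <- read_expression(p$expression)
ct <- cross_tabulate(meth, expr)

write_table_tsv(meth, file.path(p$results, "gene_methylation.tsv"))
write_table_tsv(as.data.frame(ct$table),
                file.path(p$results, "imprinting_crosstab.tsv"))

message(ct$summary$n_methylated, " methylated genes: ",
        ct$summary$similar_pct, "% similarly methylated, ",
        ct$summary$differential_pct, "% differentially methylated")
print(ct$table)
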