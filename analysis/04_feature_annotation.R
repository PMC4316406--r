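#!/usr/bin/env Rscript
# Stage 4: overlap peaks and DMRs with gene features, CpG islands/shores
# and TEs; classify promoters/TTRs by CpG content (HCP/LCP, HCTTR/LCTTR).

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
a <- parse_analysis_args()
p <- paths_for(a$results)
prm <- read_params(p)

seqs <- read_fasta(p$genome)
chrom_lengths <- setNames(nchar(seqs), names(seqs))
models <- derive_promoter_ttr(read_gff3_genes(p$genes), chrom_lengths,
                              prm$promoter_len, prm$ttr_len)
islands <- utils::read.delim(file.path(p$results, "cgis.tsv"))
shores <- utils::read.delim(file.path(p$results, "shores.tsv"))
calls <- utils::read.delim(file.path(p$results, "dmrs.tsv"))
tes <- read_reads_bed(p$tes, chrom_lengths)

fsets <- list(promoter = feature_intervals(models, "promoter"),
              ttr = feature_intervals(models, "ttr"),
              exon = feature_intervals(models, "exon"),
              intron = feature_intervals(models, "intron"),
              cds = feature_intervals(models, "cds"),
              utr5 = feature_intervals(models, "utr5"),
              utr3 = feature_intervals(models, "utr3"),
              cgi = islands, shore = shores)

tissues <- list(embryo = read_peaks(p$peaks_embryo),
                endosperm = read_peaks(p$peaks_endosperm))
ann <- do.call(rbind, lapply(names(tissues), function(t)
  cbind(tissue = t, annotate_overlaps(tissues[[t]], fsets)$counts)))
write_table_tsv(ann, file.path(p$results, "feature_methylation.tsv"))

pc <- classify_promoter_cpg(seqs, fsets$promoter, "promoter")
tc <- classify_promoter_cpg(seqs, fsets$ttr, "ttr")
write_table_tsv(rbind(pc, tc),
                file.path(p$results, "promoter_ttr_classes.tsv"))

te_ann <- annotate_tes(tes, tissues)
write_table_tsv(te_ann$summary, file.path(p$results, "te_summary.tsv"))
dd <- dmr_distribution(calls, fsets)
write_table_tsv(dd, file.path(p$results, "dmr_distribution.tsv"))

for (t in names(tissues)) {
  at <- ann[ann$tissue == t, ]
  message(t, ": methylated promoters ",
          at$n_methylated[at$class == "promoter"], "/",
          at$n_features[at$class == "promoter"], ", TTRs ",
          at$n_methylated[at$class == "ttr"], ", CGIs ",
          at$n_methylated[at$class == "cgi"], ", shores ",
          at$n_methylated[at$class == "shore"])
}
message("promoter classes: ", sum(pc$label == "HCP"), " HCP / ",
        sum(pc$label == "LCP"), " LCP; TE methylated: embryo ",
        te_ann$summary$pct_methylated[te_ann$summary$tissue == "embryo"],
        "%, endosperm ",
        te_ann$summary$pct_methylated[te_ann$summary$tissue ==
                                        "endosperm"], "%")
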