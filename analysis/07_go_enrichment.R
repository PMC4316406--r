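#!/usr/bin/env Rscript
# Stage 7: test GO-term overrepresentation of DMR-containing genes against
# the background of all methylated genes (one-sided Fisher, p < 0.05).

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
a <- parse_analysis_args()
p <- paths_for(a$results)

meth <- utils::read.delim(file.path(p$results, "gene_methylation.tsv"))
go_map <- read_go_map(p$go_map)
background <- meth$gene_id[meth$category != "unmethylated"]
study <- meth$gene_id[meth$category %in%
                        c("embryo_only", "endosperm_only",
                          "more_in_embryo", "more_in_endosperm", "mixed")]

if (length(study) == 0 || length(background) == 0) {
  message("no differentially methylated genes; nothing to test")
  quit(status = 0)
}
res <- enrich(study, background, go_map)
write_table_tsv(res, file.path(p$results, "go_enrichment.tsv"))
message(nrow(res), " GO terms tested over ", length(study),
        " DMR genes vs ", length(background), " methylated genes; ",
        sum(res$significant), " significant at p < 0.05")
if (nrow(res)) message("top term: ", res$go_id[1], " (p = ",
                       signif(res$p_value[1], 3), ")")
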