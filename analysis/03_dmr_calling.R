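#!/usr/bin/env Rscript
# Stage 3: unify the two tissues' significant peaks (diffScore >= 50) into
# methylation regions and call differential methylation with the exact
# conditional binomial test at p < 0.001.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
a <- parse_analysis_args()
p <- paths_for(a$results)
prm <- read_params(p)

pe <- read_peaks(p$peaks_embryo)
pn <- read_peaks(p$peaks_endosperm)
regions <- unify(pe, pn,
                 chroms = names(chrom_lengths_from_fasta(p$genome)))
calls <- call_dmrs(regions, prm$library_size$embryo,
                   prm$library_size$endosperm, alpha = prm$alpha)
write_table_tsv(regions, file.path(p$results, "regions.tsv"))
write_table_tsv(calls, file.path(p$results, "dmrs.tsv"))

s <- summarize_dmr_calls(calls)
message(nrow(pe), " embryo and ", nrow(pn),
        " endosperm peaks -> ", s$n_regions, " methylation regions")
message(s$differential, " differential (", s$up_embryo,
        " up in embryo, ", s$up_endosperm, " up in endosperm), ",
        s$not_differential, " not differential")
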