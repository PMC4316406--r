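# Shared plumbing for the numbered analysis scripts: argument parsing and
# the layout of the results directory. Each script is a thin driver over
# the medipdmr package; all computation lives in the package.

suppressMessages(library(medipdmr))

parse_analysis_args <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  get <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  list(seed = as.integer(get("--seed", "1")),
       results = get("--results", "results/analysis"))
}

paths_for <- function(results) {
  inp <- file.path(results, "input")
  list(results = results, input = inp,
       params = file.path(results, "params.yaml"),
       genome = file.path(inp, "genome.fa"),
       genes = file.path(inp, "genes.gff3"),
       tes = file.path(inp, "tes.bed"),
       peaks_embryo = file.path(inp, "peaks_embryo.tsv"),
       peaks_endosperm = file.path(inp, "peaks_endosperm.tsv"),
       reads_embryo = file.path(inp, "reads_embryo.bed"),
       reads_endosperm = file.path(inp, "reads_endosperm.bed"),
       expression = file.path(inp, "expression.tsv"),
       go_map = file.path(inp, "go_map.tsv"))
}

read_params <- function(p) yaml::read_yaml(p$params)

chrom_lengths_from_fasta <- function(path) {
  seqs <- read_fasta(path)
  stats::setNames(nchar(seqs), names(seqs))
}
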