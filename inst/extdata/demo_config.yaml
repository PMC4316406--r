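# Demo configuration for a small end-to-end run (see ?run_all).
seed: 7
sim:
  n_chroms: 2
  chrom_length: 150000
  n_cgis: 8
  n_genes: 8
  n_tes: 6
  n_intergenic: 20
  n_planted_dmrs: 5
dmr:
  alpha: 0.001
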