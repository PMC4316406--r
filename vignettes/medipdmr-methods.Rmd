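---
title: "Methods: comparative MeDIP-seq methylome analysis in medipdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative MeDIP-seq methylome analysis in medipdmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`medipdmr` implements a comparative MeDIP-seq analysis between two
tissues, with the maize seed (hypermethylated embryo vs hypomethylated
endosperm) as the motivating design. MeDIP-seq enriches methylated DNA
fragments, so local read depth proxies methylation level; the analysis
therefore works entirely on intervals and counts. Peak calling itself is
upstream of the package: peaks arrive as a 5-column table (chrom, start,
end, read count, diffScore), and only peaks with diffScore =
−10·log10(p) ≥ 50 — equivalently p ≤ 1e-5 — enter the analysis.

All coordinates are internally 0-based half-open (the BED convention),
converted at the format boundary: GFF3 is shifted on read and restored on
write. This makes interval length always `end − start` and removes
off-by-one ambiguity between modules.

## CpG islands and shores

Islands are detected with the classical thresholds: minimum length 200 bp,
observed/expected CpG ratio ≥ 0.6 and GC ≥ 50%, with O/E defined as
(#CpG × L)/(#C × #G) and set to 0 when #C·#G = 0 (so a C-less or G-less
window can never pass). The windowed algorithm is fixed as this package's
normative definition because the original island-report tools do not
document their internals at the level needed for oracle testing:

1. a 100-bp window slides by 1 bp; a window passes when both thresholds
   hold at window level;
2. overlapping/adjacent passing windows merge into candidates;
3. candidate ends are trimmed inward to the outermost CpG dinucleotide;
4. candidates separated by < 100 bp merge;
5. the interval is kept only if island-level length, O/E and GC all pass.

Window width, step and merge gap are exposed as parameters; the reported
O/E and GC are island-level values. N bases count toward length but not
toward C/G/CpG tallies, so long ambiguous stretches dilute rather than
poison an island. A subtlety found during property testing: the island
*count* is not monotone in the thresholds — a stricter threshold can split
one gap-merged island into two — while total island bases and island
territory are monotone; the test suite asserts the latter two.

Shores are the ≤ 2,000-bp flanks on either side of an island, clipped at
chromosome ends. When two islands lie closer than 4,000 bp the gap is
split at its midpoint between the facing shores, so islands, shores and
"other" sequence tile the chromosome without overlap. The midpoint rule is
a package design choice for the otherwise-undefined nearby-island case.

## Methylation regions and DMR calling

The two tissues' peak sets are pooled; each connected component of the
overlap graph (≥ 1 shared bp; book-ended peaks do not connect, as they
share zero bases) becomes one methylation region reported as the covering
span, with per-tissue summed read counts and an origin label (both /
embryo-only / endosperm-only). Transitive chaining makes the regions a
well-defined partition of the peaks even when one peak overlaps several
from the other tissue. When raw read positions are available, per-region
counts can instead be re-counted by read midpoint, which assigns every
read to exactly one region.

Differential methylation uses two ingredients:

* the normalized log2 ratio `M = log2((k1/n1)/(k2/n2))`, where n1, n2 are
  total mapped reads per library (library-size normalization, not
  per-region sums);
* a conditional count test: under the null of equal methylation,
  k1 | (k1 + k2 = K) ~ Binomial(K, p0) with p0 = n1/(n1 + n2). The
  two-sided p-value is the minimal-likelihood sum — the total probability
  of all outcomes whose point probability is at most that of the observed
  k1, ties included (a relative tolerance of 1e-7 guards ties against
  floating-point noise).

A region is up-methylated in embryo iff (M > 0, or k2 = 0 with k1 > 0)
and p < α, with α = 0.001 and a strict inequality (p = α is not
differential); symmetrically for endosperm. No multiple-testing correction
is applied — each region is judged on its own evidence. K = 0 yields p = 1.

For K ≤ 10,000 the p-value is computed by full summation over 0..K. Above
that the same quantity is computed as two binomial tails, locating the
likelihood-matched cutoff on the opposite flank by binary search over the
unimodal pmf (O(log K)). An earlier candidate — the symmetric normal
approximation with continuity correction — was measured against full
summation and rejected: because the minimal-likelihood region is
asymmetric whenever p0 ≠ 0.5, the normal approximation deviates by up to
~0.056 even at K = 200 with p0 = 0.505, far outside the intended 0.01
agreement band, while the two-tail method agrees to ~4e-15.

The conditional binomial assumes per-region counts are (approximately)
Poisson with tissue-proportional rates; it conditions away the absolute
rate, so only the library-size ratio matters under the null.

## Annotation

Gene models come from GFF3, one model per gene from its longest transcript
(largest summed exon length; the format is silent on a canonical choice).
Introns are the gaps between sorted exons. Promoters are the 2,000 bp
upstream of the TSS and TTRs the 2,000 bp downstream of the TES, oriented
by strand and clipped at chromosome bounds; 2 kb matches the shore scale,
in the absence of an organism-specific promoter definition.

A feature is methylated iff it shares ≥ 1 bp with ≥ 1 peak/region/DMR. An
item counts in every feature class it hits (the per-class tallies are not
a partition); an exclusive mode with precedence CGI > shore > other is
available where a partition is needed. Promoters and TTRs are classified
high/low CpG-content (HCP/LCP, HCTTR/LCTTR) by the 500-bp window (step
5 bp) maximizing the CpG O/E ratio: high iff that window has O/E ≥ 0.75
and GC fraction ≥ 0.55. These are the conventional two-class thresholds;
both are configuration keys. Exactly two classes per region kind are used
because the downstream tallies distinguish only high and low.

## Profiles

Windowed chromosome profiles count reads per fixed-width window (default
10 kb) by read midpoint, so counts conserve the per-chromosome total
exactly. The metagene curve averages per-base read depth over genes in a
20/40/20-bin promoter/body/TTR layout: flanks are binned directly, the
body is length-rescaled, minus-strand genes are flipped so the x-axis runs
5'→3', and depth is normalized per 10 million library reads to make
tissues comparable. The bin layout and the depth (rather than
peak-density) y-axis are package choices; both are configurable.

## Imprinting comparison and GO enrichment

A gene is methylated in tissue T when any part of its extent (body plus
derived promoter/TTR) overlaps a region containing at least one tissue-T
peak — background read counts alone never methylate a gene. Genes
methylated in both tissues are sub-classified by the DMR calls of their
overlapping regions: all DMRs up in one tissue (≥ 1 DMR) → "more in" that
tissue; no DMRs → similar; both directions → mixed, reported and counted
as differential (a rare case, kept so the categories stay a partition).
Expression classes use the 1.5-fold RPKM ratio rule, with
zero-denominator cases mapped to the corresponding
"higher" label and 0/0 to similar. Percentages are rounded half-up to one
decimal. The overall similar/differential split depends only on
methylation, so genes lacking expression records are excluded from the
cross-table but not from the split.

GO overrepresentation is the one-sided hypergeometric tail of the study
count given the background margins. The gene→term mapping is used as-is,
without GO-graph ancestor propagation, mirroring annotation-export tables;
the background is an explicit required input because the choice (all
genes vs all methylated genes) materially changes the test. Raw p < 0.05
defines significance; Benjamini–Hochberg adjustment is available behind a
flag but off by default.

## The synthetic methylome

The generator plants everything the pipeline later measures, so each stage
has ground truth. Defaults define the emulated study conditions:

* **Genome.** 2 chromosomes × 400 kb at 47% GC. Background bases are drawn
  i.i.d. and then CpG-depleted (20% of CpG dinucleotides retained, the
  depleted G replaced by A/T/C proportionally). Real genomes are
  CpG-depleted — that is why CpG islands are a meaningful signal — and an
  undepleted i.i.d. background has O/E ≈ 1, which would make the O/E ≥ 0.6
  filter vacuous and island detection trivial everywhere.
* **Islands.** 30 planted islands of 300–800 bp built from CpG-rich token
  sampling, with GC ≥ 60% and O/E ≥ 1.0 enforced by construction.
* **Genes and TEs.** 20 genes (1–3 exons, UTRs/CDS, strands random) placed
  non-overlapping with ≥ 2-kb flanks; 15 intergenic TEs; 60 additional
  intergenic methylation elements.
* **Methylation.** Each eligible element (island, TE, intergenic element,
  promoter, gene body, TTR) is methylated independently per tissue with
  probability 0.8 (embryo) vs 0.35 (endosperm), emulating global embryo
  hypermethylation; gene bodies methylate at 0.3× those rates so the
  metagene promoter/TTR excess is part of the emulated biology.
* **Reads and peaks.** A methylated element emits Poisson(40) reads placed
  uniformly within it and one peak over its span with diffScore ≥ 50;
  unmethylated elements emit background reads at rate 0.05 × 40 and no
  peak, so zero-count regions occur naturally. Planted DMRs (10 by
  default, drawn from intergenic elements, directions alternating) carry
  an 8-fold expected depth ratio. Nominal library sizes are equal
  (10⁶ per tissue), so normalization is neutral by construction and
  planted fold changes are the only true signal.

Poisson (not negative-binomial) counts keep the power analysis of the
conditional test analytic; with 40 vs 5 expected reads the per-region
detection probability at α = 0.001 exceeds 0.99, so the ≥ 90% recovery
bound used in testing is conservative. The generator does not emulate
realistic maize sequence composition, per-cytosine methylation states,
fragment-length effects, or overdispersed counts — passing tests
demonstrate the pipeline's correctness on its stated model, not
performance on real libraries with biological replication or
overdispersion.

Determinism is bitwise: the same seed yields byte-identical FASTA, GFF3,
BED and TSV outputs, which the orchestrated run (`run_all()`) records in a
JSON manifest of file checksums.

## Problem sizes and numerical choices

The test-suite and acceptance computations use deliberately compact
conditions: island-finder oracle equivalence on 200 random sequences of up
to 5 kb; DMR-test exactness on grids up to K = 2,000 with enumeration
oracles to K = 500; null calibration on 10,000 simulated count pairs;
planted-DMR recovery on 100 fold-8 DMRs among 1,000 equally methylated
regions over a 4 × 600 kb genome; and the full demo pipeline on the
default 2 × 400 kb genome. These sizes were chosen so every oracle can be
exhaustive while the statistical assertions (recovery ≥ 90%, false calls
≤ 5/1000, null rejection ≤ 0.005 at α = 0.001) retain enough replication
to be meaningful.

Tie handling, degenerate inputs and tie-breaks are fixed as follows:
minimal-likelihood ties are included in the p-value; O/E with zero C or G
is 0; sequences shorter than the window yield no islands (not an error);
empty shores at chromosome ends are dropped; book-ended intervals never
merge or overlap; the max-CpG window of a promoter resolves ties to the
leftmost window; and percentage rounding is half-up to one decimal.

## Known limitations

* Counts are modeled without overdispersion; on real data with biological
  replicates a dispersion-aware test would be less anticonservative.
* The DMR p-value is not corrected for multiple testing (by design,
  a deliberate convention of this procedure); interpret genome-wide calls
  accordingly.
* Single-transcript gene models discard isoform structure beyond the
  longest transcript.
* The imprinting comparison classifies methylation patterns; it does not
  model parental alleles, so it cannot by itself establish imprinting.
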