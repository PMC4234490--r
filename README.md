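# uplift

Toolkit for upgrading a draft genome assembly into chromosome-scale
pseudomolecules, written for assembly curators who hold a scaffold-level
WGS assembly plus long-range evidence: a high-density genetic map from a
biparental mapping population (e.g. GBS genotyping of a RIL population)
and map-placement records of scaffolds on a chromosome coordinate system
(the usual abstraction of optical-map alignments). It also covers the
release bookkeeping that follows an upgrade: liftOver chains, gene
identifier carry-over, annotation consolidation, and synteny-based
whole-genome-duplication (WGD) analysis.

## What it does

- **Genetic map construction.** Genotype calling from allele depths
  (call `A`/`B` when one allele has ≥ 3 supporting reads, `-` for
  heterozygous or low-depth sites), marker filtering (minor-allele
  frequency ≥ 0.1 among non-missing calls, ≤ 25 % missing data),
  SNP + SSR map integration, and pairwise LD as
  r² = (p_AB − p_A·p_B)² / (p_A(1−p_A)·p_B(1−p_B)) over complete pairs.
- **Chimeric scaffold splitting.** Adjacent markers whose segregation
  patterns differ in more than 10 % of individuals (14 of 139) flag a
  genetic-map breakpoint; scaffolds placed on two chromosomes flag a
  placement breakpoint; only *consensus* breakpoints — supported by
  both — are split, preferring an N-gap midpoint as the cut point.
- **Anchoring.** Scaffolds are ordered and oriented along chromosomes
  from placements; legacy-assembly segments are recruited into layout
  gaps; leftover scaffolds are anchored when supported by **both** ≥ 1
  co-segregating marker (r² ≥ 0.8) and ≥ 1 clone-end link, iterated in
  rounds.
- **Gap patching.** 2 kb flanks of every N-gap are aligned to the
  legacy assembly (exact seeds of ≥ 100 bp, ≥ 99 % identity); a gap is
  closed iff both flanks hit the same record, same orientation, within
  200 kb, and the patch has strictly fewer N's than the gap. Finished
  BAC-quality segments can replace whole assembly regions located by
  their 5 kb end flankers.
- **Edit log, AGP and liftOver chains.** Every split/anchor/insert/
  replace is logged; replaying the log reproduces the output assembly
  byte-for-byte and generates AGP v2.0 plus UCSC chain files so old
  coordinates lift onto the new assembly.
- **Gene identifiers.** `Medtr<chrom>g<6 digits>` identifiers are
  carried over by structure correspondence (unchanged / minor / merge /
  split / moved / novel / retired), merge conflicts resolved by global
  protein alignment, and new identifiers minted inside reserved ranges
  with strides of 10, 5, 3 or 2 — falling back to the `4`-prefixed
  overflow series (`Medtr1g409010, Medtr1g409020, …`) when the range
  is too tight.
- **Annotation consolidation.** Source-precedence merging (EVM first,
  non-intersecting MAKER models added, community/SPADA models
  override), isoform deduplication by identical CDS chains, a 50 aa
  length filter with SPADA exemption, and HC/LC/unsupported/TE
  confidence binning with configurable evidence floors.
- **Synteny & WGD.** Anchor hits are chained in gene-rank space
  (gap ≤ 20 genes, ≥ 5 pairs per block), filtered to 1:1 syntenic
  depth by exact maximum-score selection of non-overlapping blocks,
  and summarized with Ks histograms (0.05 bins) to locate duplication
  peaks.
- **Synthetic data.** A first-class generator produces a truth genome
  and derives *every* pipeline input from it (scaffolds with injected
  chimeras, RIL genotypes with segregation distortion and a Poisson
  read-depth model, placements, clone links, a variant-bearing legacy
  assembly, anchor hits with planted Ks mixtures), so each stage is
  testable against known truth.

## Worked example

```r
library(uplift)
p <- simulation_params(n_chromosomes = 4, chrom_length = 300000,
                       markers_per_chrom = 40, scaffolds_per_chrom = 5,
                       chimera_rate = 0.25, seed = 7)
truth <- simulate_truth(p)
fr <- fragment_into_scaffolds(truth, p)
g  <- simulate_ril_genotypes(truth, p, fr$layout)
gm <- filter_markers(call_genotypes(g$ref_depth, g$alt_depth, g$markers))$kept
gm
#> GenotypeMatrix: 160 markers x 139 individuals on 16 scaffold(s)
discordance_threshold(length(gm$individuals))
#> [1] 14
ev   <- derive_evidence(truth, fr$layout, p)
gbs  <- gbs_breakpoints(gm)
plc  <- placement_breakpoints(ev$placements)
cons <- consensus_breakpoints(gbs, plc)
head(cons, 3)
#>    scaffold_id start   end    source                      support
#> 1 scaffold0001 57992 58092 consensus gbs=53;placement=chr01|chr04
#> 2 scaffold0002 60148 60248 consensus gbs=60;placement=chr02|chr03
#> 3 scaffold0003 62595 62695 consensus gbs=55;placement=chr03|chr02
```

Sixteen scaffolds were simulated, four of them chimeric. Four
genetic-map breakpoints (up to 60 of 139 individuals discordant at the
junction, far above the flag threshold of 14) coincide with the four
two-chromosome placements, so exactly the four injected chimeras reach
consensus and are split; single-evidence flags never are.
`split_scaffolds()`, `tile_by_placements()` and
`build_pseudomolecules()` then assemble pseudomolecules, an AGP and an
edit log from which `emit_chain()` writes the liftOver chain.

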