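---
title: "Methods: map-guided assembly upgrade, identifier tracking and WGD detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: map-guided assembly upgrade, identifier tracking and WGD detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uplift)
```

# The problem

A draft whole-genome-shotgun assembly arrives as thousands of gapped
scaffolds. Two independent long-range data types can turn it into
chromosome-scale pseudomolecules: a high-density genetic map from a
biparental mapping population, and placements of scaffolds on a
chromosome coordinate system (in practice produced by optical-map
alignment; this package consumes the resulting placement records, not
raw optical data). The same upgrade must preserve continuity for users
of the previous release: coordinates need a liftOver chain, and gene
identifiers need to survive wherever the underlying locus did.

This vignette records the models, parameter choices and numerical
decisions behind each stage, and what the synthetic-data tests do and
do not demonstrate.

# Genetic map

## Genotype calling model

The mapping population is assumed (essentially) homozygous, as in a
recombinant inbred line: each individual is a mosaic of the two
parental haplotypes. A site is called `A` (reference parent) or `B`
(alternative parent) only when a single allele is observed with at
least `depth_min = 3` reads; observing both alleles is treated as
residual heterozygosity and collapsed to missing (`-`), as is
insufficient depth. Negative depths are rejected.

## Marker filters

A marker is *segregating* when its minor-allele frequency is at least
`maf_min = 0.1`. The MAF denominator is the non-missing calls only,
while the missingness filter (`missing_max = 0.25`) is computed over
all individuals: using a missing-inclusive denominator for MAF would
conflate the two filters, and the low 0.1 threshold deliberately keeps
markers from regions under strong segregation distortion, where one
parental allele is systematically underrepresented. Filtering is
idempotent and the kept + rejected counts always conserve the input.

No de novo marker ordering is implemented: markers are ordered by
scaffold coordinates and scaffolds by map evidence. This mirrors the
workflow the package supports, in which the genetic map validates and
anchors an existing assembly rather than re-estimating marker order.

## Linkage disequilibrium

Pairwise r² uses the haplotype-frequency formula
$r^2 = (p_{AB} - p_A p_B)^2 / (p_A(1-p_A)\,p_B(1-p_B))$ over
individuals with non-missing calls at both markers. Pairs with fewer
than two complete individuals, or monomorphic among them, are reported
as missing with a flag rather than as zero.

# Chimera detection and splitting

Two scaffolds joined in error produce two signatures: adjacent markers
whose segregation patterns disagree wildly, and placements on two
different chromosomes.

- **Genetic signal.** For each adjacent marker pair on a scaffold,
  discordance is the number of individuals with non-missing, unequal
  calls at both markers (missing calls carry no phase information). A
  pair is flagged when discordance strictly exceeds
  `ceiling(0.10 * n)` individuals — 14 for a population of 139. Runs
  of flagged pairs merge into one breakpoint interval.
- **Placement signal.** Every change-point between
  scaffold-coordinate-sorted placements of different chromosomes is a
  breakpoint whose interval is the unplaced region between them.
- **Consensus.** Only breakpoints supported by both signals are acted
  on. Intervals on the same scaffold are paired greedily by distance;
  overlap is required, with a configurable tolerance
  (`consensus_tol = 50` kb, a declared choice — no sharing distance is
  prescribed by the workflow this reimplements) admitting near-misses,
  in which case the consensus interval is the hull spanning the gap.
- **Cut point.** The junction's exact base is unknowable from either
  signal, so the split prefers the midpoint of an N-gap inside the
  consensus interval (dropping the whole gap, so no junction base is
  fabricated) and falls back to the interval midpoint. Splitting
  conserves non-N sequence exactly, up to gaps dropped at the cut.

# Anchoring and pseudomolecule construction

Placed scaffolds are tiled in placement order; inter-part gaps are
estimated from placement coordinates and floored at `join_gap_min =
100` N when materialized. Placements overlapping by more than half the
shorter placement are a hard tiling conflict (they indicate an unsplit
chimera or inconsistent evidence).

Legacy-assembly segments are recruited only into genuine inter-part
gaps (overlap with flanking parts tolerated up to 10 kb); segments
spanning a layout part are skipped with a logged reason.

Unplaced scaffolds are anchored by *dual* evidence: at least
`min_snp_links = 1` marker co-segregating with a placed marker and at
least `min_clone_links = 1` clone-end link to a placed part of the
same chromosome, both required. Co-segregation is operationalized as
r² ≥ 0.8 — a declared threshold, since "linked" is not otherwise
quantified. Evidence is evaluated against the layout as of the round
start and the procedure iterates until no scaffold moves, so a
scaffold whose only link partner was itself anchored in the previous
round is recovered in the next. The anchored position is the midpoint
of the link-implied interval; orientation is accepted when the clone
end separation fits the library model (mean ± 3 sd), otherwise `+`
with a low-confidence tag. Conflicting chromosome assignments between
the two evidence types leave the scaffold unplaced, with the conflict
logged.

AGP conventions: evidence-derived gaps are written as type `N` with
their estimated length; gaps with no distance evidence as type `U`
with the conventional 100 bp. Internal coordinates are 0-based
half-open everywhere; AGP and GFF3 convert at the I/O boundary. Both
choices are declared conventions, not inferences.

# Gap patching and region replacement

For every N-gap of at least `min_gap_len = 10` bases, up to 2 kb of
ungapped flank is taken from each side (flanks are trimmed back at
neighbouring gaps; under 100 bp of clean flank the side is reported
unmatchable). Flanks are aligned with the seeded aligner: exact seed
tiles of `word_size = 100` on both strands, co-linear seeds merged
within a 20 bp diagonal band, single-diagonal clusters scored by
column comparison and multi-diagonal clusters re-aligned globally.
Matches must reach `min_identity = 0.99`. The best match is the
highest identity, then longest alignment, then lowest target
coordinate — a total order, for determinism.

A gap closes iff both flanks hit the same legacy record in the same
orientation, the *inner-edge* distance between the two matches is at
most `span_max = 200` kb (the patch itself is the intervening
sequence, so its span is the natural measurand of "mapped within"),
and the patch carries strictly fewer N's than the gap. Each examined
gap receives exactly one reason code (`closed`, `no-left-match`,
`no-right-match`, `different-records`, `orientation-mismatch`,
`span-exceeded`, `not-fewer-Ns`), so reports always reconcile:
examined = closed + Σ reasons. Patching never increases a sequence's
N count and is idempotent.

High-quality legacy segments (finished BAC-grade) are applied after
gap closure: their 5 kb end flankers are located in the assembly and
the enclosed range replaced when the flankers agree on sequence,
orientation and order. Longer segments are applied first; a segment
whose range overlaps an earlier replacement is skipped.

# Edit log and liftOver chains

Every sequence-changing operation appends rows to an ordered edit log
(`split`, `anchor`, `insert`, `replace`) whose coordinates refer to
the working state at application time. Replaying the log against the
inputs reproduces the output byte-for-byte — tested directly — and a
segment-level provenance map tracked during replay yields the UCSC
chain file: target side old assembly, query side new, one chain per
maximal colinear run, minus-strand queries expressed on the reversed
strand as the format requires. Every surviving old base maps to
exactly one new coordinate (injectivity is asserted in tests by
lifting coordinates and matching their 21-mer sequence context).

# Gene identifiers

Identifiers have the form `Medtr<chrom>g<6 digits>`; the number
encodes chromosomal order. Rules, in precedence order: a locus that
moved over in whole or in part keeps its `Medtr` identifier; legacy
contig-style identifiers (`contig999_1`) are never retained; retired
identifiers are never reused; no identifier is assigned twice (a
registry asserts global uniqueness after every batch).

Structure correspondence is computed by lifting old loci through the
chain and classifying connected components of the same-strand overlap
graph: 1:1 with identical (lifted) CDS boundaries → `unchanged`, 1:1
otherwise → `minor`, k:1 → `merge`, 1:k → `split`; unliftable →
`moved`; unmatched old/new → `retired`/`novel`. Components that are
k:m with both k,m ≥ 2 are recorded as `merge` — the relation
vocabulary is closed and the dominant interpretation of such tangles
is a merged region; the full pair list is retained so no information
is lost. When several legacy identifiers compete, the retained one
maximizes (identity, coverage) of a global protein alignment
(Needleman–Wunsch via Biostrings; identity = matching columns /
alignment columns, coverage = matching columns / new protein length),
ties to the numerically smaller (older) identifier. The same rule
gives the retained identifier of a split to the best-matching
fragment.

New identifiers are minted between their flanking neighbours with the
largest stride s ∈ {10, 5, 3, 2} such that `n_new · s` fits strictly
inside the reserved range, leaving room for future insertions. When no
stride fits, the overflow series inserts `4` as the first digit and
runs `400000 + left + 10k`, skipping identifiers already in the
registry. The overflow series is bounded only by the 6-digit space,
not by the right flank: the scheme's own worked behaviour (20
insertions after `…009000` reaching `…409200`) requires crossing the
right flank's 4-image, and collisions with a neighbouring gap's
overflow are resolved by skipping to the next free multiple of ten.

# Annotation consolidation

Precedence merging takes all primary (EVM) models, adds secondary
(MAKER) models with **zero** same-strand CDS base overlap against the
kept set (the strictest reading of "did not intersect", preventing
duplicated loci), then lets manual sets (community, SPADA) override
overlapping computed models. Isoforms sharing an identical ordered CDS
chain are collapsed to the longest transcript (ties: first in input
order; a transcript without CDS is its own group, with a warning).
Models under `min_protein_aa = 50` are dropped unless their source is
exempt (SPADA peptides are legitimately short); the boundary is
strict, so a 50 aa model survives.

Confidence classes use evidence floors that are configuration, not
claims: HC requires a transcript alignment at ≥ 90 % coverage and
≥ 95 % identity, or a protein alignment at ≥ 70 % coverage and ≥ 60 %
identity; any lesser evidence is LC; none is unsupported; a supplied
transposable-element flag overrides (repeat classification itself is a
separate pipeline). The exact published thresholds for such binning
are not recoverable from the workflow description, which is why they
are exposed as parameters with a sensitivity-friendly interface, and
the class counts always partition the gene set.

# Synteny and WGD

Anchor hits live in gene-rank space. Chaining is greedy in rank order
with per-axis gap cutoff `chain_gap_genes = 20` (the per-axis reading
of the distance cutoff is a declared choice) and a direction fixed by
each chain's second hit; both axes stay strictly monotonic, inverted
(antiparallel) blocks are first-class. Blocks need
`min_block_pairs = 5` pairs; the block score is its pair count.

The 1:1 quota filter selects the maximum-total-score subset of blocks
with no two selected blocks overlapping on either genome axis. The
conflict graph is solved exactly by branch-and-bound per connected
component up to 30 blocks; larger components fall back to greedy with
the result flagged approximate. Tests verify exactness against full
subset enumeration.

Ks values are inputs on anchor hits (codon-level estimation is out of
scope); histograms use half-open bins of `ks_bin = 0.05`, report
proportions over non-missing values, and a local-maxima scan locates
mixture components such as a speciation peak near 0.28 and a WGD peak
near 0.64.

# The synthetic-data generator

The generator emulates the study conditions end to end: 139 mapping
individuals; Poisson read depth with mean 8 (making the 3-read and
multi-allele rules genuinely exercisable); a Markov crossover process
with 1 Morgan per chromosome (a generic choice — the emulated workflow
used real data and states no simulation model); residual
heterozygosity 0.5 %; segregation distortion on the left arm of
chromosome 1 implemented as selection (individuals carrying the
alternative allele there are resampled with probability 0.7), which
skews allele frequency smoothly without fabricating spurious
recombination; a 35 kb ± 7 kb clone-link library; chimeras formed by
joining segments of two chromosomes across an N-gap; sequencing gaps
masked in place so scaffold coordinates stay aligned to truth; a
legacy assembly that is truth with point substitutions at rate 0.001;
and planted duplication blocks whose gene pairs draw Ks from
N(mode, 0.06), placed in non-overlapping rank windows.

Desk-scale defaults (10 × 1 Mb chromosomes, 100 markers and 10
scaffolds per chromosome) keep full-pipeline tests in tens of seconds;
the heaviest property suite — chimera recovery on 20 injected
chimeras — runs on exactly these defaults.

What passing tests show: the detection, splitting, anchoring,
patching, chaining and identifier machinery is correct against known
truth under a faithful if clean evidence model. What they do not show:
robustness to alignment noise absent from the generator — misplaced
optical alignments, paralog-collapsed scaffolds, reference-bias in
genotyping, indel divergence between releases (the legacy model is
substitution-only, which the seeded aligner's banded merging handles
but real structural divergence would stress harder).

# Known limitations

- The seeded aligner is exact-seed based; diverged regions without a
  100 bp exact match are invisible to gap patching, as with the
  word-size-100 search it mirrors.
- Only inter-chromosome chimeras are detected; within-chromosome
  misassemblies (inversions, transpositions) are out of scope.
- Link-anchored scaffolds get a point position (median of link-implied
  coordinates); the true offset within a gap is not estimated.
- Genetic distances (cM) are never estimated; LD decay is used
  qualitatively only.
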