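---
title: "Reference-assisted diploid assembly from linked reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-assisted diploid assembly from linked reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`diploidlr` reconstructs a diploid personal genome from barcoded
linked-read data by leaning on a reference sequence: reads are phased into
their two parental haplotypes first, each haplotype is assembled locally in
small chunks, the chunk assemblies are stitched back together at
high-confidence partitioning points, and variants are then read off
pairwise contig-to-reference alignments. This vignette explains the model
behind each stage, the tunable parameters and their defaults, what the
bundled simulator does and does not emulate, and the numerical and design
choices a maintainer should know about.

## The data model

Linked-read libraries tag short reads with a barcode identifying the long
DNA molecule (tens to hundreds of kb) they came from. Three coverage
quantities describe such a library:

* `C_F` — physical (fragment) coverage: total molecule length divided by
  genome length; typically hundreds-fold.
* `C_R` — read coverage *within* a molecule: aligned read bases divided by
  total molecule length; typically sparse (0.05-0.4x).
* `C = C_F * C_R` — raw read coverage.

Because `C_R` is sparse, a single molecule samples only a fraction of the
heterozygous SNPs it spans, but `C_F` is high enough that neighbouring
SNPs are jointly covered by many molecules. That redundancy is what the
haplotyping stage exploits.

## Molecule reconstruction

Reads are grouped by barcode and chromosome; a new molecule starts
whenever the gap between the end of one read and the start of the next
exceeds `split_gap` (default 50 kb). The gap is measured end-to-start, not
start-to-start, matching the idea of "distance between successive reads".
Reads below a MAPQ floor (default 20) are excluded: partitioning decisions
downstream rely on uniquely mapped reads. Unsorted input is an error
rather than being silently re-sorted — molecule reconstruction is a
streaming operation and silent re-sorts hide broken upstream pipelines.

Per-molecule allele calls at het SNP sites keep one call per covered site;
a site where reads of the same molecule disagree is dropped from that
molecule only (the molecule itself is kept). Each call carries
`p_correct = 1 - 10^(-Q/10)`, clamped to `[0.51, 0.9999]` so no call is
ever treated as certain or as worse than a coin flip.

Multiple libraries reuse the same barcode whitelist, so they cannot be
pooled as raw reads; after per-library molecule reconstruction barcodes
are no longer needed and molecule sets simply concatenate
(`merge_libraries()`), re-keyed by a library prefix.

## Variant pruning

Haplotyping is only as good as the het callset it starts from. Before
phasing, variants must pass: alternate-allele fraction `>= 0.25`, variant
quality `>= 13`, and per-variant depth inside a two-tailed band. The
depth band is implemented as the 10th-90th *percentile* of the observed
per-variant depth distribution; a literal 0.10x-0.90x-of-mean band (which
would reject most variants at typical coverage, since mean-depth variants
sit near 1.0x of the mean) is available via
`prune_config(percentile = FALSE)`. All comparisons are
boundary-inclusive.

## The parity model

For a pair of neighbouring het SNPs the two true haplotypes form
complementary two-site keys: `00/11` (even parity) or `01/10` (odd).
With per-variant call-correctness probabilities `p1`, `p2`, a molecule
shows a key of the *correct* parity with probability
`p_c = p1 p2 + (1-p1)(1-p2)` (both calls right, or both wrong). Observing
`k` even keys out of `N` molecules, the two-hypothesis posterior with a
flat prior is

```
P(even | k of N) = p_c^k (1-p_c)^(N-k) /
                   [ p_c^k (1-p_c)^(N-k) + (1-p_c)^k p_c^(N-k) ]
```

— the binomial coefficients cancel, so this is `plogis((2k - N) *
logit(p_c))`, numerically stable for any `N`. Parity is accepted when the
posterior exceeds `alpha = 0.99`; otherwise the pair is UNDETERMINED and
contributes no clustering evidence. A textbook-Bayes variant with a flat
`P(A) = choose(N,k)/2^N` denominator and `P(B) = 1` is kept behind
`literal = TRUE` for comparison; it is not a normalised probability (it
exceeds 1 for strongly supported pairs) and is not used for decisions.

`p1`, `p2` default to the per-variant mean `p_correct` over molecule
calls, floored at 0.95: base qualities vary little within a run, and the
floor keeps single noisy molecules from inflating confidence in sparse
pairs.

## Recursive clustering and phase blocks

Each parity-determined pair seeds a pair of complementary molecule
clusters; molecules whose key has the rejected parity are excluded as
sequencing error *for that pair only* — they keep contributing at their
other sites. Cluster pairs merge when the number of distinct molecules
supporting the same haplotype in both reaches `merge_support = 3` while
the opposite orientation stays below it (merging error is then at most
`((1-p1)(1-p2))^3` per pair). Merging uses a union-find with an
orientation parity bit, complementary clusters merge in lockstep, clusters
are re-sorted by genomic position each round, and rounds repeat to a fixed
point. A molecule is counted once per cluster pair regardless of how many
variant pairs it supports.

A variant is phased into its block only when *every* assigned molecule
covering it agrees (per haplotype); one contradicting molecule excludes
the variant from further steps. Blocks then extend by merging any two
blocks sharing at least `overlap_support = 5` variants with a consistent
relative orientation (spurious-merge probability at most `p^5` for
per-site error `p`). Internally blocks are keyed by a cluster id; the
user-visible `block_id` is the leftmost phased position (the `PS` value).
Before extension converges, distinct overlapping blocks can legitimately
share variants — exclusivity is enforced only after extension, where a
variant still phased in several blocks keeps its best-supported copy and a
block whose variants are all phased elsewhere disappears. (Enforcing
exclusivity at block construction would leave the extension step with no
shared variants to merge on.)

Finally every molecule with at least two het calls is assigned to the
block and side maximising `L(M|H) - L(M|H_c)` where
`L(M|H) = prod_i [theta(H_i,M_i) p_i + (1-theta(H_i,M_i))(1-p_i)]`.
Likelihoods are tiny but only their difference matters; a margin below
`1e-12` is a tie and the molecule stays UNASSIGNED — its reads later go
to *both* haplotypes, which keeps diploid coverage in het-poor regions.

## Partitioning points and chunking

Phase blocks can reach chromosome-arm length; handing all their reads to
an assembler would defeat the purpose of reference-assisted local
assembly. Blocks longer than `block_threshold = 200 kb` are cut into
chunks of about `chunk_len = 100 kb` at *high-confidence partitioning
points*: positions where read coverage and fragment coverage both exceed
0.8x their covered-region averages and the reference 100-mer starting
there is unique (both strands considered). Cut sites snap to the
qualifying point nearest each ideal multiple of `chunk_len` within
+-20 kb (so chunks stay within 20% of target); if no point qualifies the
boundary is skipped and the chunk runs long. Each block's assembly span is
the union of its assigned molecules, so assembly reaches past the
outermost phased SNPs.

## Local assembly and stitching

Reads are partitioned per (block, haplotype, chunk): an assigned
molecule's reads go to chunks of its own block and haplotype; UNASSIGNED
molecules' reads go to both haplotypes of every chunk they overlap. Reads
are kept if they overlap the chunk padded by `chunk_pad = 500 bp`, so
minicontigs reach far enough past each partitioning point to contain the
stitch anchor.

The built-in assembler is a greedy de Bruijn graph: count k-mers
(`k = 31`, 2-bit encoded, single-stranded since simulated alignments are
already in genome orientation), drop k-mers below `min_count = 2`, and
emit maximal unambiguous paths. One extra greedy move matters: at any
graph fork, edges whose coverage is outweighed `purge_ratio = 3`-fold by
the strongest sibling are removed first. Duplicating UNASSIGNED molecules'
reads to both haplotypes plants minority-coverage allelic bubbles at het
sites; a production assembler pops such bubbles, and without this purge
the unambiguous-path walk would fragment at every het site. An external
assembler can be plugged in per chunk via `backend = "external"`.

Minicontigs from neighbouring chunks are stitched at their shared
partitioning point: the reference 100-mer starting at the point (unique by
construction) is located near the right end of the left minicontig and the
left end of the right one (`search_margin = 2000 bp`); the splice keeps
the left prefix up to the anchor and the right minicontig from the anchor
on, and proceeds left-to-right so each concatenation feeds the next. If
the anchor is missing or ambiguous on either side, no splice happens and
both pieces are emitted — stitching never guesses.

Contig headers follow
`"<n>_PS<start>:<end>_hp<k>[_merge<a>:<b>_hp<k>-...]"`; `hp1`/`hp2` are
arbitrary per block. All raw contigs are written, including those under
1 kb; the length filter applies at variant calling, not at output.

## Variant calling and phasing

Contigs align to the reference through a pluggable backend. The built-in
aligner finds k-mers (k = 21) unique in both contig and reference window,
collapses same-diagonal anchor runs (breaking a run when the anchor gap
exceeds k — a larger gap can hide a substitution), chains runs by longest
increasing subsequence, trims overlaps caused by breakpoint
micro-homology, and aligns the inter-anchor segments with an affine-gap
global alignment (equal-length segments are compared positionwise).
Alternatively, PAF with cs difference strings from a minimap2-style
aligner parses into the identical edit-operation table, so the downstream
code path is shared.

Candidates come from contigs over 1 kb at MAPQ >= 20; indels are
VCF-anchored and left-aligned so calls from the two haplotypes are
comparable. Zygosity: a SNP with the same alternate allele on both
haploid assemblies is homozygous; on one haplotype with the other
covering the reference allele, heterozygous (a low-confidence flag marks
sites the other haplotype does not cover). Deletions from opposite
haplotypes are the same event when their reference intervals overlap;
insertions when their breakpoints are within 20 bp; matched events with
different alleles (compound events) split into two het records. Variants
of 50 bp and over are classed as SVs.

Assembly SNPs merge with the read-based callset (union of sites); on a
genotype conflict the read-based genotype wins and the assembly call is
kept as an annotation — mapping-based genotyping of SNPs is the more
reliable of the two. Phase is then inferred for *all* het variants: per
(block, contig-haplotype) a majority vote over assembly SNPs matching
scaffold-phased SNPs fixes the orientation, and every het variant on that
haplotype is placed accordingly with `PS` = block id; tied votes leave
variants unphased. Homozygous records are written `1/1` without phase.

## The simulator

`sim_config()` / `simulate_truth()` / `simulate_reads()` generate a
diploid genome with planted het/hom SNPs (defaults 1e-3 and 5e-4 per bp),
small indels (1e-4 per bp, geometric sizes with a mild 2-bp periodicity as
in real indel spectra), and a configurable set of SVs (defaults span the
Alu-typical 60-500 bp range). Molecules draw exponential lengths (mean
50 kb, truncated to [1 kb, 5x mean]); 2000 barcodes x 2 molecules give
`C_F ~ 190x`, and 1.5 read pairs per molecule-kb give `C_R = 0.3x`, i.e.
`C ~ 57x` — a desk-scale version of a realistic library design. Reads are
emitted as truth-placed alignments (barcode, MAPQ 60, known position), so
no external mapper is needed; a FASTQ path exists for end-to-end runs with
a real mapper.

Two generator choices deserve a note:

* Molecules sharing a barcode are placed half a genome apart by default so
  the 50 kb split rule is unambiguous; requesting a spacing below 50 kb
  switches to a stress layout that places them as close as possible, to
  exercise mis-splitting.
* Molecules may overhang the sequence ends and are clamped. This keeps
  per-base physical coverage flat right up to the ends — like an interior
  window of a real chromosome — rather than ramping from zero over a
  molecule length, a desk-scale artifact that real 3 Gb data does not
  show and that would otherwise fragment the terminal chunks.

What the simulator does **not** emulate: sequencing-instrument error
profiles (errors are uniform substitutions, Q30 bases with Q10 at error
positions), GC bias, chimeric molecules, barcode collisions or whitelist
errors, and mapping ambiguity (alignments are truth-placed). Passing
tests on simulated data therefore demonstrate the correctness of the
algorithms under clean conditions, not robustness to real-data artifacts.

## Problem sizes and expected results

The bundled evaluation runs on a 1 Mb genome at the library design above;
the full pipeline (simulation through phased VCF) takes a few minutes on
one core, which makes it practical as a routine regression check. Under
these error-free conditions the package phases with zero long-switch and
zero mismatch errors, covers >= 99% of the genome with exactly one contig
per haplotype, recovers planted SNPs/indels/SVs inside chunk interiors
with F1 = 1.0 and exact genotypes, and stitched contigs equal truth
haplotype substrings exactly. `scripts/acceptance.R` recomputes all of
these from scratch.

## Numerical choices and edge cases

* Ties: a 50/50 parity split is UNDETERMINED; a zero likelihood margin
  leaves a molecule UNASSIGNED; a tied phasing vote leaves variants
  unphased. Nothing is ever broken arbitrarily.
* Coordinates are 0-based half-open internally; VCF emission is 1-based.
* Degenerate inputs: empty read sets assemble to empty output; an empty
  variant table prunes to empty; a genome shorter than the uniqueness
  k-mer yields an empty track; overlapping requested SVs are rejected
  with a report.
* `evaluate_variants()` left-aligns both callsets before matching when
  given the reference, so representation differences in repeat context do
  not count as errors.
* Evaluation of phasing chooses each block's orientation by majority
  (haplotype labels are arbitrary per block); an isolated one-variant
  disagreement run counts as a mismatch error, a run of two or more as a
  long switch.

## Known limitations

* The built-in aligner assumes near-reference contigs with unique anchor
  k-mers; highly repetitive or strongly diverged sequence needs the
  external aligner backend.
* Variants spanning a partitioning point can be split across chunks;
  evaluation therefore reports chunk-interior metrics separately.
* The toy assembler does not canonicalise reverse complements and is only
  suitable for the truth-placed simulator output or similarly oriented
  read sets.
* Ancestral-state inference trusts the provided flank alignments; flanks
  on different outgroup chromosomes, disagreeing outgroups, or gaps
  outside both decision windows are left unresolved rather than guessed.
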