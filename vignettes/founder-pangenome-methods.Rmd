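---
title: "Founder reconstruction, kernel indexing and ad hoc references: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder reconstruction, kernel indexing and ad hoc references: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderpan)
```

This vignette documents the models and algorithms `founderpan` implements,
the parameters that matter, the numerical and representational choices made
where the design was genuinely open, and what the packaged tests do and do
not establish.

## The variant graph and the reference-guided MSA

A phased VCF encodes, per sample chromosome copy, a pairwise alignment
against the reference. We build, per chromosome, a directed acyclic graph
whose nodes are the unique variant start and end coordinates plus the
boundary nodes `1` and `R + 1` (`R` the reference length). Consecutive
nodes are joined by *reference edges* labeled with the intervening
reference substring; every alternative allele contributes one edge from its
start node to its end node (start plus REF-allele length), and duplicate
alternative edges are merged. A haplotype is a source-to-sink path; its
sequence is the concatenation of edge labels.

The *aligned position* of a node — its column in the reference-guided
multiple alignment — is one plus the length of the longest label-length
path reaching it, computed by a linear-time DP in node order. A row is
emitted by walking a path and appending, after each edge label, enough `-`
characters to reach the target node's aligned position; all rows therefore
have identical width. Because the columns are pinned by the pairwise
alignments only, this MSA is *consistent*, not optimal: it makes no claim
about homology inside re-aligned variant regions, which is exactly what the
downstream steps need and nothing more.

Coordinates are 1-based and inclusive throughout; segments are half-open on
node coordinates. Unphased `/` separators are an error by default (a
`strict_phasing = FALSE` escape hatch accepts them with a warning, since
haploid simulated data carries no ambiguity). Two overlapping variants
chosen by one haplotype have no defined concatenation, so they are an error
naming the records; `drop_conflicts = TRUE` keeps the earlier-starting one.
Records sharing a start position are ordered by (start, end, alternative
string) to make all downstream tie-breaking reproducible.

## Founder reconstruction

Aligning reads against every haplotype is wasteful because most of the rows
agree almost everywhere. A *bridge* is a reference edge shared by every
source-to-sink path (equivalently: no alternative edge spans it); its
endpoints are the only cut points at which every haplotype can be split
without cutting through a variant. Given cuts, each segment has a set of
distinct restriction subsequences with occurrence counts, the reference
counting as one haplotype with weight 1. The number of *founder* rows
needed to represent all of them is the maximum per-segment distinct count,
so the segmentation objective is

\[
D(r) = \min_{\substack{q \in Q,\; r - q \ge L,\; q - 1 \ge L}}
\max\{D(q),\, d(q, r)\},
\]

where `Q` is the bridge-node set, `d(q, r)` the number of distinct
restriction subsequences on `[q, r)`, and `L` the user-chosen minimum
segment size in reference positions. Two choices here are not forced by the
recurrence and are made explicit:

* **Base case.** `D(r)` also competes against the no-cut option `d(1, r)`,
  so a single segment is always feasible and the DP cannot fail for large
  `L`.
* **Tie rule.** Among equal-valued options the rightmost (most recently
  cut) last cut wins, applied recursively. On the packaged worked example
  (`table1_fixture()`, `L = 4`) the candidate segmentations with cuts
  `{7}`, `{12}` and `{7, 12}` all attain `D = 4`; the tie rule selects
  `{7, 12}`, segments of 6, 5 and 7 reference positions.

`d` counts distinct *restrictions of the input haplotypes*, not all
combinatorial paths through the segment's subgraph — the worked example's
first segment has three distinct haplotype restrictions but six graph
paths, and founders exist to cover observed haplotypes, not the
combinatorial closure.

**Greedy joining.** Consecutive segments are joined left to right through a
bipartite graph with `f` slots per side (`f ≥ max d`, the default being
equality). Distinct subsequences of the concatenated two-segment window are
visited in descending occurrence order (ties broken lexicographically by
the window string); each window connects its two slots if both are free,
reroutes to an available slot if one side is taken, and is skipped
otherwise; leftover slots pair in ascending index. The effect is that
locally frequent haplotype contexts stay contiguous in some founder, which
is the property read alignment needs: every haplotype substring contained
within one segment occurs in at least one founder.

**Leftover slots.** When a segment has fewer distinct subsequences than
`f`, the spare slots are filled by duplicating subsequences cyclically in
descending count order (default), or left as `N` runs spanning the
segment's columns (`fill = "N"`). Duplication is the default because a
duplicated frequent subsequence is still alignable sequence, whereas `N`
runs shrink the usable index; both behaviors are provided because either
can be argued for and neither affects the coverage guarantee.

## Kernel construction

The founders still repeat each other heavily. A greedy LZ77-compatible
parse factorizes their concatenation left to right: at each position the
longest substring with an occurrence starting strictly earlier becomes a
*copying phrase*; positions with no earlier occurrence become literals,
merged into literal runs. Two dialect choices, made for verifiability:
copy sources must end at or before their target (no self-overlap) and
neither end of a match may cross a sequence boundary. The contract that
matters downstream is not the dialect but the *P-mer coverage property*:
with read length `P`, every length-≤P substring of every founder must
survive in the kernel. Copying phrases of length greater than `2P`
therefore keep only their first and last `P` characters — a read
overlapping the excised middle also occurs at the phrase's source — and a
phrase whose source is not fully intact in the retained text (an earlier
excision cut through it) is conservatively kept whole. The property is
enforced by construction and re-checked exhaustively in the tests on
randomized inputs (sequences up to a few hundred bases, `P ≤ 20`).

The kernel is emitted as multi-record FASTA, one record per detached piece
with provenance (`founder`, `start`, `length`) encoded in the id, rather
than one concatenated string with separators: equivalent for aligners, and
it cannot produce spurious matches across piece boundaries. Reads are
treated as single-ended against the kernel; alignment itself is external to
the package.

## Support matrix and the heaviest path

Given one best alignment per read — highest aligner score (`AS`), then
mapping quality, then file order — spanning founder positions `p..q` on row
`i`, the matrix cells `M[i, col(p)..col(q)]` are incremented, including gap
columns interior to the span. Alignments to kernel pieces are lifted to
founder coordinates through the provenance map first.

The ad hoc reference takes, per MSA column, the character of the argmax
row, skipping gaps. Ties break to the lowest row index, and the original
reference is required to be row 1: at zero coverage the ad hoc reference
*is* the original reference, an exact identity the tests assert. The
per-column rule realizes founder deletions (gap chosen, base dropped) and
founder insertions (non-gap chosen in an insertion column); indels inside
individual read alignments are not re-examined. Memory is `m × n` integers,
fine at the scale the package targets; the accumulation interface takes
plain range increments, so a streamed column-wise variant could be
substituted without changing callers.

## Projection and embedded variants

A record called at ad hoc positions `p..p+|REF|-1` maps through the column
table to an MSA column interval; the projected REF is the original
reference's non-gap characters across those columns and the projected POS
the first reference position in the span. A record falling entirely inside
an ad hoc insertion has no reference image and is anchored on the preceding
reference base, VCF-style, and flagged. All projected and embedded records
are trimmed and left-aligned (the usual VCF normalization); the underlying
workflow convention is silent on normalization, so the package picks the
canonical form.

Differences between the ad hoc reference and the original reference are
reported as *embedded* variants: aligned substitution columns one SNP per
column, gap runs as single anchored indel records. (A maximal-run walker
that merges adjacent difference columns would fuse neighboring SNPs into
MNVs; the decomposition is a lossless re-representation that keeps embedded
output comparable with SNP-level truth sets.) Genotypes follow ploidy
arithmetic: with no overlapping caller record, every chromosome copy is
non-reference; where a caller record overlaps, its non-zero genotype values
are counted, subtracted from the ploidy, and the embedded record receives
that many non-zero values — per sample. A partially overlapping embedded
indel and caller SNP are both emitted rather than merged.

## The simulators

`simulate_generations()` emulates bacterial mutation accumulation: one
genome equal to the reference, population doubling per generation (32
genomes at generation 5, 128 at generation 7), and per-child, per-locus
Bernoulli(`mutation_rate`) substitutions, the new base uniform over the
three alternatives of the *current* base. A locus may mutate repeatedly
along a lineage; the final base is reported, and a reversion drops out of
the emitted haploid multi-sample VCF. `simulate_reads()` draws fragments
uniformly with normal insert sizes (defaults 300 ± 25), 100 bp mates and a
1% substitution error rate by default, writing FASTQ plus a truth SAM with
proper-pair flags so support accumulation can be exercised without an
external aligner. Every stochastic function takes a mandatory seed; there
is no hidden global RNG state, and fixed seeds give byte-identical outputs.

What the simulator does *not* emulate: indel or structural mutations,
platform-specific error and quality profiles, GC or coverage bias, and
mapping ambiguity from genuine repeats. Tests passing on this synthetic
data therefore establish algorithmic correctness (coordinate bookkeeping,
coverage guarantees, round-trip identities) — not calling accuracy on real
sequencing data, which additionally depends on the external aligner and
caller the workflow wraps.

## Problem sizes and numerical choices

The test and acceptance workloads run at desk scale by design: references
of a few hundred bases, panels of 16–128 genomes, reads of 8–100 bp, LZ
inputs up to a few hundred bases per sequence, exhaustive oracles on graphs
with ≤ 10 variants and ≤ 12 bridge nodes. The segmentation DP memoizes
`d(q, r)` per boundary pair; its cost is quadratic in the bridge count
times the restriction cost, ample headroom at these sizes. The LZ scan and
the edit-distance DP are the only compiled components — the two places
where a quadratic character loop in R would dominate runtime.

Degenerate inputs are defined, not special-cased away: an empty VCF yields
a single-edge graph whose MSA is the reference row; `L` larger than the
reference yields the single uncut segment; zero coverage yields the
reference as ad hoc output; an empty caller VCF yields embedded records
only.

## Known limitations

* One graph, one chromosome: multi-chromosome inputs are processed per
  chromosome.
* Symbolic alleles (`<DEL>`, breakends) and `*` overlapping-deletion
  alleles are rejected rather than approximated.
* The greedy LZ dialect is a declared substitute for whatever parse an
  external hybrid indexer would use; the P-mer coverage contract, not the
  phrase list, is the interface.
* Per-chromosome-copy ad hoc references and structural-variant support are
  out of scope.
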