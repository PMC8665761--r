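# founderpan

Founder sequences, kernel indexing and ad hoc references for pangenomic
variant calling.

Single-reference variant calling is biased toward the alleles that happen to
sit in the reference genome. One remedy is to align reads against *many*
reference haplotypes at once — but indexing hundreds of near-identical
sequences is wasteful, and downstream callers expect a single linear
reference. `founderpan` implements the computational core of a workflow that
threads this needle:

1. **VCF → variant graph → reference-guided MSA.** Phased variants of one
   chromosome become a directed acyclic graph with nodes at every variant
   start/end coordinate (plus 1 and R+1), reference edges carrying the
   intervening reference substrings, and one labeled edge per alternative
   allele. The *aligned position* of a node is one plus the longest
   label-length path reaching it, so gap columns fall out of a linear-time
   DP and every haplotype can be written as an equal-width gapped row.
2. **Founder reconstruction.** A *bridge* is a reference edge on every
   source-to-sink path; bridge nodes are the legal cut points. The
   segmentation DP
   `D(r) = min over q in Q, r−q ≥ L, q−1 ≥ L of max(D(q), d(q,r))`
   (with the single uncut segment as fallback) minimizes the maximum
   per-segment number of distinct haplotype subsequences `d`, under a
   minimum segment size `L`; ties prefer the most recently cut final
   segment. Per-segment subsequences are then joined across segment
   boundaries by a greedy bipartite matching in descending occurrence
   order, yielding `f ≥ max d` founder rows that jointly contain every
   observed local subsequence.
3. **Kernel sequence.** The founders are factorized by a greedy
   LZ77-compatible parse; copying phrases longer than `2P` (P = read
   length) keep only their first and last `P` characters, because any read
   overlapping the excised middle also matches the phrase's earlier source.
   The kernel plus its provenance map is what a general-purpose read
   aligner indexes.
4. **Ad hoc reference.** Best read alignments (lifted from kernel pieces
   back to founders when needed) increment an `m × n` support matrix `M`
   over founder rows × MSA columns. Per column, the argmax row's character
   (ties to the lowest row, with the original reference as row 1) is
   appended unless it is a gap — a heaviest path that mimics
   recombination. With zero coverage the ad hoc reference *is* the
   original reference.
5. **Projection.** Variants called against the ad hoc reference are
   rewritten to original-reference POS/REF through the column map, and
   differences embedded in the ad hoc reference itself are reported with
   genotypes set in every chromosome copy not already claimed by an
   overlapping caller record (ploidy subtraction).

A generational mutation simulator (population doubles each generation,
per-locus Bernoulli substitutions), a paired-end read simulator with truth
alignments, and a unit-cost edit distance make the whole pipeline testable
with no external aligners or data.

## Worked example

The running example is a five-record artificial variant table over the
18 bp reference `TTCTGGGAGGCAGTTACC` with five haploid samples, packaged as
`table1_fixture()` (and as plain files under `inst/extdata/`):

```r
library(founderpan)
fx <- table1_fixture()
g  <- build_variant_graph(fx$reference, fx$variants)
emit_msa(g)
#> ref_msa: 6 row(s) x 23 column(s)
#>   REF        T--TCTG-G--GAGGCAGTTACC
#>   s1         T--TCAAAAAAGAGGCAGTTACC
#>   s2         T--TCAAAAAAGAGGCAGTTT-C
#>   s3         TAATCTCCG--GAGGCAGTTA-C
#>   s4         TAATCTCCG--GAGGCT----CC
#>   s5         T--TCAAAAAAGAGGCT----CC

paths <- haplotype_paths(g)
(seg <- optimal_segmentation(g, paths, L = 4))
#> segmentation: L = 4, D = 4, cuts at {7, 12}
#>   start end size d
#> 1     1   7    6 3
#> 2     7  12    5 1
#> 3    12  19    7 4
```

With minimum segment size `L = 4` the optimal cuts are the bridge nodes 7
and 12, giving segments of 6, 5 and 7 reference positions and at most
`D = 4` distinct subsequences per segment. Four founders therefore suffice;
the first segment has only three distinct subsequences, so one is
duplicated:

```r
fs <- greedy_join(g, paths, seg, f = 4)
ungap(emit_founders(fs, g)$rows)
#>                founder1                founder2                founder3
#> "TTCAAAAAAGAGGCAGTTACC"     "TAATCTCCGGAGGCTCC"     "TTCTGGGAGGCAGTTAC"
#>                founder4
#>  "TTCAAAAAAGAGGCAGTTTC"
```

Every haplotype's subsequence in every segment occurs in some founder, so
reads from any sample still find their local context. Downstream, reads
aligned to the founders (or to the kernel built from them with
`build_kernel(lz_parse(founders), P)`) drive `accumulate_support()` /
`heaviest_path()`, and `project_vcf()` maps calls back to the original
reference.

A thin command-line front end over these functions ships as
`inst/cli/founderpan.R` (`vcf2msa`, `founders`, `kernel`, `adhoc`,
`project`, `simulate`).

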