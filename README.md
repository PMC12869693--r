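# pantag — tag-array indexing for pangenome graphs

Pangenome graphs embed many haplotypes as walks through a shared sequence
graph. An FM-index over the haplotype sequences answers "where does this
pattern occur?" — but it reports one hit per haplotype, even when all those
hits sit at the same place in the graph. `pantag` implements a lossless,
haplotype-aware index that merges equivalent hits: a **tag array** aligned
with the Burrows–Wheeler transform, whose entry *i* is the graph position
`(v, o, b)` (node, 0-based offset, orientation) where the suffix `SA[i]`
starts. Because a pangenome graph aligns similar sequences, equal tags
cluster into long runs, and the array compresses run-length just like the
BWT itself.

The package is aimed at people building sequence-to-graph search tools:
it indexes a GFA1 graph (S/L lines plus P or W walks), and answers

* **find + distinct tags** — the lexicographic interval `[A, B]` of a
  pattern, and the deduplicated set of graph positions annotating it
  (two rank queries on the run-start bitvector, never a scan of the rows);
* **MEM finding** — maximal exact matches of a read against the index
  (FMD layout: every haplotype plus its reverse complement is indexed, so
  both strands match), each annotated with its distinct tags;
* **one-to-all coordinate translation** — an interval on one haplotype
  mapped to every haplotype that traverses the same node starts, via a
  sampled tag array holding only runs with offset `o = 0`.

## The construction algorithm

The tag array is built in three stages over a mutable **run-length B+
tree** (runs of `(start, tag)` with implicit lengths, four merge conditions
on insert, borrow-then-merge rebalancing on the underflows that
bidirectional merges cause):

1. **Unique k-mer anchoring.** A k-mer with exactly one starting graph
   position pins its whole BWT interval `[A, B]` to that position: one run
   of length `B + 1 − A`.
2. **Graph-based backward extension.** If `U` is graph-unique and its
   position has a single predecessor with base `c`, then `cU` is also
   unique; the extended interval is one LF-step away. At variation,
   predecessors are grouped by their last base and extension continues
   through each base contributed by exactly one predecessor.
3. **Haplotype traversal.** Every sequence is walked backwards with
   LF-mapping from its end-marker row; rows no unique context reached get
   the walk's own graph position. This stage alone would build the array —
   the first two stages exist so it touches few rows.

Large graphs are handled per weakly connected component (a chromosome
proxy), and the per-component arrays are interleaved into the whole-genome
array using the sequence-number mapping of the r-index — the merged array
equals the whole-text build row for row.

## Worked example

```r
library(pantag)
g <- toy_graph()            # bundled 8-node, 3-haplotype graph
idx <- pantag_build(g, k = 3)
idx
#> pangenome graph: 8 nodes (22 bp), 18 oriented edges, 3 haplotypes, 1 component(s)
#> multi-string BWT index: N = 122 rows, 6 sequences, 44 runs (n/r = 2.8)
#> tag array: N = 122 rows in 53 runs (mean run length 2.30)
#> sampled tag array: 17 node-start runs over 122 rows (16 distinct tags)

iv <- backward_search(idx$index, "AGGA")
iv                          # rows 20..22: three occurrences, one per haplotype
#> [1] 20 22
distinct_tags(idx$tags, iv) # ...but a single graph position
#>   v o b
#> 1 4 0 0
```

All three haplotypes traverse node 4 (`AGGA`), so the FM-index reports
three row hits while the tag array collapses them to the one position
`(v = 4, o = 0, b = 0)` — the lossless merge that motivates the structure.

Translation maps an interval of haplotype 0 (sequence ids are 0-based;
even ids are forward strands, odd ids their reverse complements) to every
haplotype sharing its node starts:

```r
translate_coords(idx$index, idx$sampled, sid = 0, p = 5, q = 12)
#>   offset v o b sid2 offset2 other strand
#> 1      0 2 0 0    0       5 FALSE      +
#> 2      0 2 0 0    4       5  TRUE      +
#> 3      1 4 0 0    0       6 FALSE      +
#> 4      1 4 0 0    2       6  TRUE      +
#> 5      1 4 0 0    4       6  TRUE      +
#> 6      5 5 0 0    0      10 FALSE      +
```

Haplotype 2 (sid 4) shares nodes 2, 4 and 5 with the query; haplotype 1
(sid 2) only joins at node 4 — it took the other side of the first bubble.

A shell front-end wraps the same functions:

```sh
exec/pantag synth --nodes 30 --haps 4 --mut 0.05 --seed 1 --components 2 --out g.gfa
exec/pantag build --gfa g.gfa --k 8 --per-component --out idx
exec/pantag query --index idx --pattern ACGTACGT
exec/pantag mems --index idx --fasta reads.fa --lmin 31 --tags
exec/pantag translate --index idx --seq c1h1 --start 0 --end 50
```

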