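---
title: "Tag arrays: lossless haplotype-aware indexing of pangenome graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag arrays: lossless haplotype-aware indexing of pangenome graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pantag)
```

## The model

A pangenome graph stores DNA on nodes and embeds haplotypes as walks.
`pantag` indexes the *haplotype text*: for each walk, its spelled sequence
followed by its reverse complement (the FMD convention, so sequence `sid`
and its partner `sid XOR 1` always pair), each terminated by an
end-marker. End-markers are distinct and ordered by sequence index during
suffix sorting but collapse to a single `$` symbol in the BWT, giving the
standard multi-string BWT: rows `0..m-1` are the end-marker rows, in
sequence order.

The tag array `Tag[0..N-1]` annotates row `i` with the graph position
`(v, o, b)` where suffix `SA[i]` starts: node id, 0-based offset, and
orientation. Offsets are counted along the traversal direction on either
strand — a convention this package fixes package-wide, since only the
triplet itself is forced by the model. End-marker rows carry a reserved
END tag (`v = 0, o = 1`) so the array is total; queries filter reserved
tags out. Internally a position is packed into one double,
`((v * 2^20) + o) * 2 + b`, which bounds node length below ~1 Mbp and node
count below 2^30 — ample at the scales this implementation targets — and
makes packed numeric order equal lexicographic `(v, o, b)` order.

Searching is classic FM-index machinery: `lf_char` implements
`C[c] + rank(c, i)`, `backward_search` narrows inclusive row intervals,
and a bidirectional (`bi_extend_forward` / `bi_extend_backward`) interval
pair supports extension in both directions with the cumulative-width rule
over the six-symbol alphabet `{$, A, C, G, N, T}` (complement fixes `$`
and `N`). Locate is r-index style: suffix-array samples are stored at run
boundaries and at every `$` row (where LF over the merged alphabet is not
the text-predecessor map, so those rows must be their own anchors), a
toehold for an arbitrary row is found by LF-walking to the nearest sample,
and neighbouring values are derived with the phi function — a predecessor
lookup over the sampled values, linear within a run.

## Construction

The mutable structure during construction is a run-length B+ tree: entries
`(start, tag)` with lengths implicit from successive starts, a sentinel
entry at `N`, and unassigned regions materialised as runs with a reserved
GAP tag so that "is this row assigned?" and length-by-difference stay
coherent over a total partition of `[0, N)`. Insertion applies four merge
conditions (no merge, forward, backward, bidirectional); the entry
removals caused by merges can underflow a leaf, repaired by
borrow-then-merge rebalancing that propagates upward. Three further
choices are deliberate:

* **Atomic conflict checking.** An insert that would overwrite a
  differently-tagged assigned row raises *before* mutating anything. The
  construction stages are designed never to conflict, so a conflict is a
  bug signal, and a half-applied insert would corrupt the very state one
  wants to inspect.
* **Idempotent equal-tag overlap.** Stages 1 and 2 can re-derive the same
  run; absorbing equal-tag overlap keeps them freely composable.
* **Cost accounting.** Every descent counts node visits, so the
  logarithmic cost contract is a testable property, not a promise.

Stage 1 anchors every unique k-mer — uniqueness is decided over the
*indexed* text (all walks plus reverse complements), since substrings the
haplotypes never realise cannot occur in the BWT either. Stage 2 extends
anchors backward breadth-first: a single predecessor always extends; at
variation, predecessor nodes are grouped by their final base and each base
contributed by exactly one predecessor extends through that branch (five
predecessors ending `A,A,A,T,C` extend through `T` and `C` only).
Extended branches re-enter the worklist, so extension recurses through
consecutive unambiguous junctions; intervals already seen (deduplicated by
interval start) are not re-expanded, which prevents re-work on shared
prefixes. A depth cap (`max_rounds`, default 256) bounds worst-case unary
chains. Stage 3 walks each sequence backward with LF from its end-marker
row and fills whatever is still GAP, then tags the end-marker rows; a
disagreement between an existing tag and the traversal tag raises an
integrity error, because stages 1–2 must only ever write correct tags.

Per-component construction restricts the *walks* to one weakly connected
component while keeping node identities, so tags are unchanged; the
whole-graph index then determines, per global BWT row, the owning
sequence and hence component, and per-component cursors interleave the
part arrays. Relative sequence order within a component is preserved by
construction, which is exactly what makes the interleave equal the
whole-text build row for row (a property the tests check bit-exactly).

## Queries

The frozen tag array keeps a sparse monotone vector of run starts plus one
tag per run — the Elias–Fano contract (space proportional to runs,
logarithmic rank) realised here as a sorted numeric vector with counted
binary search, which is the appropriate engineering point for an R
implementation. `distinct_tags` does two rank queries, slices the
overlapping runs, sorts and deduplicates; an access counter records every
element touched so the output-sensitive bound is asserted in tests rather
than assumed.

Coordinate translation samples only runs whose tag has `o = 0` — node
starts, on either strand; sampling both orientations is this package's
choice, since strand handling is otherwise unconstrained and the reverse
strand is first-class in an FMD text. Phase 1 LF-walks the query interval
and collects sampled tags with their offsets; phase 2 enumerates, per tag,
the sampled runs carrying it (a hash from tag to run ids, space
proportional to sampled runs) and locates their intervals. The library
returns raw `(sid', offset')` pairs including the query's own hits — a
useful consistency handle — with reverse-complement hits collapsible onto
forward coordinates (`collapse_rc`, the CLI default). An interval crossing
no node start yields an empty report: sub-node resolution is offset
arithmetic for the caller, not a lookup.

MEM finding uses the bidirectional index: from each query start, forward
extension to failure gives the unique right-maximal match, kept when left
extension fails too. `N` never matches, consistent with anchoring. The
enumeration contract (equality with a quadratic brute force) is the
normative surface; the traversal order is not.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 31 | anchor k-mer length (bases). 31 is the conventional seed length in pangenome indexing; desk-scale test graphs use 3–8 so anchors exist at all. |
| `degree` | 64 | runs per B+ node; higher trades pointer overhead for wider scans. |
| `max_rounds` | 256 | extension depth cap (bases prepended per anchor branch). |
| `Lmin` | 31 | minimum MEM length (bases). |

## The synthetic generator

`random_pangenome()` emulates the structure that matters to this method:
a backbone of nodes with substitution bubbles (equal-length alternative
nodes), node deletions (skip edges) and small insertions, at a 5% event
rate per interior node by default, with four haplotypes choosing variants
independently and the first haplotype pinned to the backbone so every
reference node is traversed. Variation acts at node granularity, so
multi-predecessor junctions — including same-last-base predecessors, the
edge case of the grouped extension rule — are explicit graph structure.
It does **not** emulate realistic human variation: no mutation-rate
heterogeneity, no structural variants beyond single-node events, no
sequencing error, no cycles, and all walks are forward-oriented
(reverse-orientation steps are exercised by hand-built fixtures instead).
Passing tests therefore demonstrate algorithmic correctness on
graph-shaped inputs, not calibrated performance on real pangenomes.

## Numerical and degenerate-input choices

* Intervals on the BWT are inclusive `[A, B]`, empty iff `B < A`;
  CLI-facing sequence intervals are 0-based half-open. Rank counts
  strictly below its argument.
* Suffix sorting uses vectorised prefix doubling on integer codes with
  distinct ordered sentinels; ties cannot survive, so termination is
  structural.
* The empty pattern maps to the full interval; an absent pattern is an
  empty interval, not an error. A k larger than every haplotype yields an
  empty anchor set, not an error; stage 3 still completes the array.
* A component containing nodes but no walks is an error (its text would
  be empty and untaggable); unknown segments, non-ACGTN bases and empty
  walks are format errors naming the offender.
* Serialization is a single-file container with a magic string and
  version, refusing to load on mismatch; content round-trips exactly.

## Problem sizes and limitations

The oracle suites run at sizes chosen for exhaustive verification: ~200
random texts up to 2 kbp against a naive suffix sort; 50 random pangenomes
(≤ 50 nodes, ≤ 8 haplotypes) against the permute-by-suffix-array gold
construction; 10,000 random inserts against a flat-array reference with
structural audits; exhaustive interval and translation enumeration on
graphs small enough to enumerate. These sizes are a verification choice:
every structure here is O(log)-shaped, but the implementation is pure R
and desk-scale by design — indexing consortium-scale graphs needs the
external-memory BWT construction and compressed rank/select machinery
this package deliberately leaves out of scope. Other known limitations:
anchoring ignores k-mers containing N; the depth cap can leave long unary
chains to stage 3; and translation reports node starts only.
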