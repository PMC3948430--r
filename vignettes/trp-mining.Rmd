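---
title: "Mining and scoring transcriptional regulatory pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and scoring transcriptional regulatory pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpmine)
```

## The model

Two high-throughput assays inform TF–gene regulation and they disagree on
purpose. TF perturbation experiments (TFPEs) give **TFR evidence**: deleting
or overexpressing a TF changes a target's expression. They capture direct
*and* indirect regulation. Chromatin immunoprecipitation gives **TFB
evidence**: the TF binds the target's promoter. Their overlap — pairs with
both kinds of evidence — defines **direct regulatory pairs**; the large
remainder of TFR-only pairs must act through intermediate TFs, along a
**transcriptional regulatory pathway (TRP)**: a directed path
TF → TF → … → gene whose every step is an edge of an underlying network.

`trpmine` operationalizes this as two condition-specific digraphs built
from evidence tables:

* the **binding network**: an edge per condition-matching TFB pair;
* the **direct-regulatory network**: an edge per (tf, target) key passing
  the condition filter in *both* the TFB and the TFR table. Its edge set is
  by construction a subset of the binding network's, much sparser and much
  better supported.

The intersection is keyed on (tf, target) only: a pair is direct even when
its binding and regulation evidence come from different publications,
because directness is a property of the pair, not of any one study.

## Mining procedures

Enumerating all simple paths between two nodes is NP-complete in dense
graphs, so the two networks get two different procedures.

**All pathways (direct-regulatory network).** A divide-and-conquer
two-step: (1) extract the subgraph spanned by all source→target paths as
the intersection of the forward-reachable set of the source and the
backward-reachable set of the target (two breadth-first sweeps) with its
induced edges — any node in the intersection lies on a source→target walk
and any simple path uses only such nodes, so the simple-path set of the
subgraph equals that of the full network; (2) depth-first enumeration with
a visited set on the extracted subgraph. The sparsity of the
direct-regulatory network makes the extracted subgraph small in practice,
which is what makes step (2) affordable.

**All shortest pathways (binding network).** The binding network is too
dense for full enumeration, so the goal narrows to all *shortest*
pathways, which is polynomial per reported path: (1) breadth-first
distance labeling (Dijkstra degenerates to BFS on a unit-weight digraph)
gives the shortest length L and, run backwards from the target, a
lower-bound label dist(v → target) for every node; (2) a depth-first
branch-and-bound search prunes any branch with depth + dist(v → target)
> L, so it never leaves the union of shortest paths.

Three semantic decisions the mining rests on:

* **Paths are simple** (no node revisited). Regulatory circuits are full of
  feedback loops — the nitrogen GATA circuit among them — and with
  revisits allowed "all pathways" is not a finite set. Simplicity is the
  only reading under which complete enumeration terminates; it also drops
  self-loop edges (autoregulation) from pathways while keeping them in the
  networks.
* **The length-1 pathway counts.** When the queried pair is itself a
  direct edge, the single-edge pathway is returned: the detail report must
  answer "direct or indirect?", and the length-1 pathway is the "direct"
  answer. For the same reason the shortest-pathway miner reports the direct
  binding edge when one exists.
* **Either miner runs on either network.** The pairing above (all ↔
  direct, shortest ↔ binding) is the default at the query surface, but the
  functions do not enforce it — cross-running them is how the equivalence
  tests work.

Mining runs under an explicit `mining_budget()` (defaults: 5 000 subgraph
nodes, 100 000 pathways, unlimited length). Exceeding a limit raises a
classed error naming the limit and the partial count; budgets never
silently truncate, because a truncated "all pathways" answer is worse than
no answer.

## Scoring and curation

A pathway with L edges implies an ordered regulation claim for every
(upstream, downstream) node pair along its direction — L(L+1)/2 claims.
The **confidence score** is the fraction of those pairs carrying TFR
evidence in the index built with the same condition filter as the mined
network (a global index is available by passing `condition = "any"`). The
score is monotone under evidence addition and equals 1 exactly when every
along-path pair is supported.

**Known vs putative.** A pathway is *known* when at least one abstract in
the user-supplied corpus mentions every member symbol, matched
case-insensitively as whole words with boundaries at non-alphanumerics —
`GAT1` never matches `GAT12`, while `Gzf3` and `GZF3` both match. Substring
matching was rejected precisely for the `GAT1`/`GAT12` ambiguity; alias or
systematic-name resolution is out of scope, so a corpus using only
systematic names will under-classify.

## Conditions and symbols

Condition labels live in a configurable vocabulary seeded with the nine
standard experimental-condition classes (stress, nitrogen source
quality/availability, …). Tags are matched case-insensitively; unmatched
tags map to `"unclassified"` with a warning rather than an error, because
real exports carry idiosyncratic spellings. The reserved label `"any"`
means "no filter". Because the evidence tables carry condition tags per
pair, the condition filter has two policies: `"any"` (default — the
queried label is among the pair's tags) and `"all"` (every tag is the
queried label); the strict policy exists because upstream databases do not
document whether their grouping is at pair or publication level.

TF and gene symbols are upper-cased on ingestion: yeast protein names
(Gln3) are capitalization variants of gene names (*GLN3*), and one
canonical key prevents silent query misses.

## The synthetic generator

`generate_tables()` emulates the regime the engine targets: an
Erdős–Rényi digraph restricted to TF sources (default 15 TFs, 30 genes,
edge probability 0.08 — a few dozen edges, the sparse direct-regulatory
regime), every edge with TFR evidence, and a `tfb_given_edge` fraction
(default 0.5, emulating the scarcity of binding support among
perturbation-identified pairs) with TFB evidence too. Planted pathways
(default 3, lengths 2–4) get both evidence kinds on every edge and TFR
evidence on every along-direction ordered pair, so each is guaranteed to
appear in the direct-regulatory network and to score exactly 1 — the
generator's correctness contract, checked across seeds in the tests.

What the generator does *not* emulate: scale-free degree distributions,
per-publication condition tags, realistic publication multiplicity, or
database-scale table sizes. Tests passing on synthetic tables therefore
certify the algorithms and contracts, not performance or biological
realism at corpus scale.

`gln3_fixture()` reproduces the nitrogen GATA circuit worked example
(Gln3, Gat1, Dal80, Gzf3): four doubly-evidenced edges, TFR-only evidence
for GLN3→GZF3 and DAL80→GZF3, all tagged
`"nitrogen source quality/availability"`. The fixture grants TFR evidence
to all six ordered pairs along the longer pathway so that both enumerated
pathways score 100%, consistent with Dal80's documented indirect
regulation of *GZF3*. Its publication ids and one-abstract corpus are
synthetic stand-ins (`SYN:*`).

## Numerical and ordering choices

* Pathway output is sorted by (length, element-wise lexicographic node
  sequence) using radix (C-locale) ordering; all table outputs are sorted
  on explicit keys; DOT, TSV and report writers are byte-deterministic.
* Unreachable pairs yield `Inf` from `shortest_trp_length()` and an empty
  pathway set — not an error. A missing endpoint is flagged with an
  `absent_nodes` attribute so batch queries keep going; only a
  source = target query errors.
* Empty inputs are legal where a scientist would expect them (an empty
  evidence table builds an empty network; an empty corpus classifies
  everything putative); malformed input (missing columns, unknown evidence
  kinds, empty tables) raises classed format errors.
* Ties in the known/putative rule do not exist by construction: any number
  of matching abstracts > 0 means known, and all matches are reported.

## Verification strategy and problem sizes

The test suite checks the miners against a naive recursive
all-simple-paths oracle that shares no code with the implementation and
runs on the *full* graph — so one comparison certifies both the
enumerator and the path-set-preservation of subgraph extraction — across
200 seeded random digraphs of up to 12 nodes, cyclic and acyclic, plus an
igraph cross-check on a handful of cases. The shortest-pathway miner is
checked against the min-length filter of the oracle's output on the same
suite. Closed-form cases (2^(n−2) paths in a complete DAG, single cycles)
pin the combinatorics. Scoring laws, the direct ⊆ binding edge law (50
synthetic table pairs), planted-pathway recovery (50 seeds) and
byte-determinism of all writers round out the suite. These sizes keep the
whole suite under a minute while exercising every contract; the budgets,
not the tests, are what guard production-scale runs.

## Known limitations

* No alias/synonym resolution in curation; abstracts must use the symbols
  the tables use.
* Condition filtering is pair-level; publication-level condition
  attribution cannot be expressed in the input schema.
* Edges are unsigned — activation/repression calls need condition-specific
  expression data and are out of scope.
* The confidence score is descriptive, not probabilistic: it counts
  evidence, it does not model it.
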