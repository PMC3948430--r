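# trpmine

Mining transcriptional regulatory pathways (TRPs) from TF–gene evidence
tables.

## The problem

TF perturbation experiments (TFPEs — deleting or overexpressing a
transcription factor and profiling genome-wide expression) identify the
*regulatory* targets of a TF, but most of those targets are indirect: the
TF does not bind their promoters, and the regulation runs through
intermediate TFs. Chromatin immunoprecipitation (ChIP) identifies the
*binding* targets. A TF–gene pair supported by both evidence kinds is a
**direct regulatory pair**; a pair with regulation (TFR) evidence but no
binding (TFB) evidence needs a mechanistic explanation — a **TRP**, a
directed path of regulation steps

TF → intermediate TF → … → gene

through direct edges. `trpmine` builds the two condition-specific networks
the field uses for this, enumerates the pathways, scores them, and checks
them against the literature:

* **direct-regulatory network** — edge TF→gene iff the pair has both TFB
  and TFR evidence under the queried experimental condition; sparse, high
  support. All simple pathways are enumerated here (subgraph extraction by
  forward/backward reachability, then depth-first enumeration).
* **binding network** — edge per TFB pair; dense, so only all *shortest*
  pathways are enumerated (breadth-first shortest length, then depth-first
  branch-and-bound).
* **confidence score** of a pathway with L edges: the fraction of its
  L(L+1)/2 ordered along-path pairs (every upstream node against every
  downstream node) that carry TFR evidence. 100% means every implied
  perturbation effect is documented.
* **known vs putative**: a pathway is *known* if at least one literature
  abstract mentions all of its member TFs/genes (whole-word,
  case-insensitive), else *putative*.

Intended users: yeast systems biologists with YEASTRACT-style evidence
exports who want mechanistic hypotheses for indirect TF–gene pairs; the
algorithms are organism-agnostic.

## Worked example: the nitrogen GATA circuit

Nitrogen catabolic gene expression in *S. cerevisiae* is controlled by the
GATA factors Gln3, Gat1, Dal80 and Gzf3. Perturbing Gln3 changes *GZF3*
expression, but Gln3 does not bind the *GZF3* promoter — how does the
regulation work? The bundled fixture carries the relevant evidence:

```r
library(trpmine)
fx  <- gln3_fixture()
net <- build_direct_regulatory_network(fx$tfb, fx$tfr, condition = fx$condition)
net
#> <trp_network: direct_regulatory | condition: nitrogen source quality/availability>
#>   4 nodes, 4 edges, 3 TFs (nodes with out-edges)

paths <- enumerate_all_trps(net, "GLN3", "GZF3")
paths$path
#> [1] "GLN3 -> GAT1 -> GZF3"          "GLN3 -> DAL80 -> GAT1 -> GZF3"

idx <- evidence_index(fx$tfr, "TFR", condition = fx$condition)
annotate_trps(paths, idx, evidence_index(fx$tfb, "TFB", fx$condition),
              corpus = fx$corpus)[, c("path", "length", "confidence", "status")]
#> # A tibble: 2 × 4
#>   path                          length confidence status
#>   <chr>                          <int>      <dbl> <chr>
#> 1 GLN3 -> GAT1 -> GZF3               2          1 known
#> 2 GLN3 -> DAL80 -> GAT1 -> GZF3      3          1 putative
```

Both candidate mechanisms are fully supported (confidence 1 = 100%: every
ordered pair along each pathway has TFR evidence), and the shorter one is
additionally backed by an abstract naming all three members. The four-part
detail report assembles the same answer for humans:

```r
build_detail_report(fx$tfb, fx$tfr, "GLN3", "GZF3",
                    condition = fx$condition, corpus = fx$corpus)
#> ==== Part 1: queried TF-gene regulatory pair ====
#> TF: GLN3
#> Gene: GZF3
#> ...
#> TFB evidence: 0 publication(s) -- the pair is not a direct edge; regulation must be indirect
#>
#> ==== Part 2: enumerated TRPs and confidence scores ====
#> TRP 1 (length 2): GLN3 -> GAT1 -> GZF3
#>   confidence: 100.0%  status: known  support: SYN:ABSTRACT:1
#> TRP 2 (length 3): GLN3 -> DAL80 -> GAT1 -> GZF3
#>   confidence: 100.0%  status: putative
#> ...
```

`search_trps()` / `browse_trps()` answer list-shaped queries,
`write_dot()` emits Graphviz figures with `(TFR, TFB)` evidence-count edge
labels, `generate_tables()` produces seeded synthetic evidence tables with
planted, fully supported pathways, and `exec/trpmine` exposes the verbs
`build`, `search`, `browse`, `detail`, `synth` and `stats` from a shell.

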