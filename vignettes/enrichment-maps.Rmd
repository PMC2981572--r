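---
title: "Enrichment maps: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrichment maps: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichmapr)
```

## The model

An enrichment map re-expresses a gene-set enrichment result as a weighted
network. The units are gene-sets — named collections of gene identifiers
from GO, pathway databases or any GMT file — and the experiment contributes
one enrichment record per set: a nominal p-value, an FDR q-value, and a
direction (+1 / −1 for the two classes of a two-class design, 0 for a
one-class analysis). The map is built in three steps.

**Node selection.** Sets are first restricted by size (default: keep
10–500 genes, inclusive on both ends; very large sets are biologically
vague, very small ones statistically fragile) and then by significance.
Significance filtering is strict on both thresholds: a record is kept when
`p < p_max` and, if a q-value exists, `q < q_max` (defaults 0.001 and
0.05). Records without q-values are filtered on p alone. With two datasets
the node set is the *union* of sets significant in either — this is what
makes a two-condition comparison informative, since a set significant at
one time point but not the other must still appear, with the
non-significant slot rendered white.

**Edges.** For every pair of included sets the similarity is either the
Jaccard coefficient JC = |A∩B| / |A∪B| or the overlap coefficient
OC = |A∩B| / min(|A|,|B|). An edge exists when the coefficient is **at or
above** the cutoff (default 0.5). The threshold is deliberately inclusive:
OC equals exactly 1 for any subset pair, so with an inclusive test every
significant parent–child pair of a hierarchical vocabulary is connected at
any cutoff up to and including 1. JC penalises size mismatch
(JC = |child|/|parent| for nested sets), which is why OC is the default for
GO-like collections and JC the alternative for flatter ones. For all pairs
OC ≥ JC, with equality exactly when the sets have equal size or a void
intersection.

**Attributes and layout.** Node colour is `direction × (1 − p)`, clipped to
0 for non-significant slots, giving a bounded score in [−1, 1] mapped onto a
blue/white/red diverging gradient. Node display size is an affine map of the
gene-set size onto a display range; edge width an affine map of the
coefficient from [cutoff, 1]. Coordinates come from a Fruchterman–Reingold
force-directed layout in weighted mode, with the coefficient as edge weight,
so tightly overlapping sets cluster spatially.

The post-analysis mode attaches an external query gene list to the map:
each node's set is tested for overlap with the query by the one-tailed
Fisher's exact test (hypergeometric upper tail,
`p = P(X ≥ k)` for universe N, set n, query m, overlap k), and edges with
nominal p below `alpha` (default 10⁻⁴, uncorrected by convention for this
screen) are drawn with width −log₁₀(p). The same hypergeometric test doubles
as a stand-alone enrichment mode for discrete gene lists, there with
Benjamini–Hochberg q-values attached since that mode produces a full result
table rather than a thresholded screen.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_size`, `max_size` | 10, 500 | genes | routine pre-processing bounds; inclusive |
| `p_max`, `q_max` | 0.001, 0.05 | probability | conservative display thresholds; strict inequalities |
| `metric` | `"overlap"` | — | guarantees parent–child edges in hierarchical collections |
| `cutoff` | 0.5 | coefficient | usual operating point; inclusive comparison |
| `alpha` (post-analysis) | 1e-4 | probability | nominal, uncorrected; per-query |
| `log_base` (signature width) | 10 | — | width = −log₁₀(p); natural log available |
| `seed`, `iterations` (layout) | 42, 100 | — | recorded in metadata; reruns are identical |
| `var_floor` (t scoring) | 1e-8 | variance | keeps constant genes finite, t = 0 when means agree |

## Numerical and design choices

Where the design was genuinely open we chose once and documented:

- **Colour intensity is linear (1 − p), not −log p.** The gradient needs a
  bounded score to be well defined; `-log10` is available behind the
  `intensity` flag of `color_score()` for viewers that rescale.
- **Inclusive similarity threshold.** `coefficient >= cutoff` so the OC = 1
  subset guarantee holds at cutoff 1; exclusive thresholds would silently
  drop exactly the hierarchical edges the overlap metric exists for.
- **Union semantics for two datasets**, with the *unfiltered* record kept in
  a non-significant slot (tables and tooltips can show the raw p) while its
  colour score is forced to 0.
- **Fisher universe default** for post-analysis is the union of genes across
  the collection backing the map; overridable (e.g. to a platform's measured
  gene list). Query genes outside the universe are dropped with a warning.
- **Welch t by default** for gene scoring, pooled variance behind a flag;
  the per-class variance floor (1e-8) makes constant genes score 0 rather
  than NaN. Ratio-of-means scoring divides means on the scale given — log2
  input is *not* re-exponentiated unless asked, matching the convention of
  applying the statistic verbatim.
- **Ties and determinism.** Gene rankings break ties by gene id (stable);
  edge pairs are canonicalised lexicographically and sorted, so edge lists
  are invariant to collection row order; GMT and GCT writers emit sorted
  genes / full-precision (`%.17g`) numbers so repeated writes are
  byte-identical and round trips exact; layout components are placed
  largest-first with singleton nodes on a peripheral grid, and the RNG seed
  is restored after use.
- **Degenerate inputs.** A single-node map lays out at the origin; an
  all-equal size range maps every node to one display size; a map with zero
  significant sets is an explanatory error rather than an empty file; blank
  GSEA p-value cells parse as 0 because GSEA prints an empty cell when the
  permutation p falls below its resolution, and such records must pass any
  filter.
- **Direction labels** in generic tables map first-seen label → +1:
  deterministic without configuration.

## What the synthetic generator emulates

`synth_spec()` + `make_collection()` / `make_enrichment()` /
`make_expression()` produce fixtures with *known planted structure*:

- clusters of gene-sets sharing a core (within-cluster OC ≥
  core/(core+peripheral), default 20/25 = 0.8) with **gene-disjoint**
  clusters (between-cluster OC exactly 0), plus one parent/child pair per
  cluster (OC exactly 1). Disjoint cores make cluster recovery an exact,
  not statistical, property: at cutoff 0.5 the map's connected components
  must equal the planted clusters.
- enrichment records drawn with margins around the thresholds
  (significant: p ~ U(0, 0.0005), q ~ U(0, 0.04); null: p ~ U(0.01, 1),
  q ~ U(0.06, 1)), so threshold-boundary flakiness cannot occur; a second
  dataset flips each planted call with probability `perturb_fraction`,
  emulating a two-time-point contrast.
- expression matrices with Normal(7, `noise_sd`) baselines on a log2-rma-like
  scale, defaults of 3 samples per class and a +`effect_size` shift in case
  samples for genes of chosen sets — mirroring a small two-class cell-line
  microarray design.

What it does **not** emulate: a realistic GO DAG topology (real collections
overlap *between* themes too, so real maps have inter-cluster edges and
recovery is not exact); correlated genes within samples; heavy-tailed or
heteroscedastic expression noise; GSEA's permutation distribution. Passing
the planted-recovery tests therefore demonstrates the pipeline's
correctness, not that real enrichment results will split into clean
components.

A note on null t statistics: with 3 + 3 samples the Welch statistic has ~4
degrees of freedom and visibly heavy tails (P(|t| > 6) ≈ 4·10⁻³), so a few
hundred null genes are expected to produce a handful of |t| > 6 values; the
test suite bounds that tail count rather than asserting it is empty.

## Problem sizes

The test suite and examples run at deliberately small scale: collections of
tens of sets over universes of a few hundred to 2000 genes, 1000 random
pairs for the coefficient cross-checks, exhaustive hypergeometric
enumeration up to universe size 25, ten seeds per planted-cluster
configuration, and 3 + 3-sample expression matrices of up to a few hundred
genes. These sizes exercise every code path; nothing in the implementation
is specific to them, and maps of a few thousand sets are handled by the
same inverted-index edge enumeration.

## Known limitations

- At most two datasets per map; multi-condition comparison needs a
  different encoding.
- Similarity is computed on gene-set *definitions* (after size/universe
  filtering), not on leading-edge subsets or co-expression.
- The layout is deterministic but not canonical: different seeds give
  different (equally valid) embeddings.
- Cluster identification is visual/topological; the package does not label
  or circle clusters automatically.
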