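---
title: "HippoConnect: models, parameters and design choices"
author: "HippoConnect maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HippoConnect: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HippoConnect)
```

# The scientific question

In the developing *Drosophila* ovary, the Hippo kinase Hpo restrains the
transcriptional coactivator Yki post-translationally, yet in the larval
germ line a knockdown of *hpo* also lowers *yki* transcript — a
regulatory direction the canonical pathway does not provide. HippoConnect
packages the computational route from cell-type-resolved knockdown
RNA-seq to a mechanistic candidate: quantify how similarly germ and soma
respond to *hpo* versus *yki* knockdown, tie knockdown-responsive genes
to putative direct Yki targets from ChIP peaks, and ask a heterogeneous
regulatory network which gene could carry a signal from Hpo to the *yki*
promoter in the fewest steps. On the emulated inputs the answer is the
BTB-zinc-finger factor Chinmo, the sole two-step connector.

Because the deposited datasets and versioned interaction databases are
not desk-reproducible, every stage is exercised against a synthetic-data
generator with planted ground truth; the package's guarantees are about
recovering what was planted, plus the handful of worked statistics that
are computable from printed marginal counts alone.

# The count model and the DE engine

Counts are simulated and tested under the standard bulk RNA-seq model:

$$ y_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \qquad
   \mu_{gj} = q_g \, s_j \, 2^{\sum_k x_{jk}\beta_{gk}}, \qquad
   \mathrm{Var}(y) = \mu + \alpha \mu^2, $$

with gene baseline $q_g$, sample size factor $s_j$, planted log2
fold-changes $\beta$ and gene-wise dispersion $\alpha_g$ ($\alpha = 0$
reduces to Poisson; verified in the tests by Monte-Carlo).

`waldDE()` fits, per gene, an NB log-link regression of counts on the
contrast factor (plus optional covariates such as stage), with
$\log s_j$ offsets, by iteratively reweighted least squares at fixed
gene-wise dispersion. The contrast coefficient over $\log 2$ is the
log2 fold-change; a two-sided Wald test with Benjamini–Hochberg
adjustment gives the significance call at `padj < deAlpha` (default
0.05). This is a deliberately simplified engine: no trended shrinkage of
fold-changes, no outlier-count filtering, no independent filtering. Its
claims are correspondingly property-based — type-I control on all-null
simulations and recovery of planted effects — not bit-agreement with any
specific published tool.

Supporting estimates:

* **Size factors** (`computeSizeFactors()`): median-of-ratios against a
  geometric-mean pseudo-reference, restricted to genes positive in every
  sample. When no such gene exists the function errors and points to the
  documented `allowPseudoReference` fallback (geometric means over
  positive entries only). The method assumes a predominantly null gene
  set; strongly one-sided differential expression inflates the perturbed
  group's factors and shrinks estimated fold-changes (see *Numerical
  choices* below).
* **Dispersion** (`estimateDispersion()`): within-group method of
  moments on normalised counts, $\hat\alpha = (s^2 - \bar m)/\bar m^2$
  pooled across groups with $n_k - 1$ weights and floored at zero, then
  shrunk 50/50 toward a parametric trend $\alpha(m) = a_0 + a_1/m$ fit
  across genes. With no replicated group at all the gene-wise component
  is undefined and a default trend ($a_0 = 0.01$, $a_1 = 1$) is returned
  with a warning. The 50/50 weight is a simple compromise between the
  noisy 3-replicate gene-wise estimate and the stable trend; planted
  dispersions of 0.2 are recovered with median inside [0.1, 0.3] at 10
  replicates per group.
* **VST stand-in** (`vstTransform()`): `log2(count / sizeFactor + 1)`,
  a strictly monotone variance-flattening surrogate sufficient for
  PCA and clustering of simulated libraries; it is not a
  mean-dispersion-calibrated VST and is not used for testing.

# Outlier control flagging

One control library in the emulated study showed anomalously low marker
(*yki*) expression and was removed after visual inspection of
VST-normalised counts. `flagOutlierControls()` encodes that decision as
a reproducible rule: within each cell type, a control sample is flagged
when its marker expression on the `log2(normalised + 1)` scale deviates
from the median of its peer controls (across stages) by more than
`k = outlierMadK` (default 3) scaled median absolute deviations. The
log scale is the scale on which the original call was made, and it turns
the planted 10-fold suppression into a fixed ≈3.3-log2 deviation
regardless of the marker's baseline, whereas on the raw normalised scale
the same rule is baseline-dependent and unstable at bulk dispersions.
With only nine peer controls a 3-MAD rule has a nonzero false-positive
rate; the pipeline therefore reports every flagged sample rather than
silently dropping the non-planted ones.

# PCA and concordance statistics

`pcaExpression()` performs PCA on per-gene-centred, unscaled transformed
values (the standard expression-PCA convention); component signs are
fixed by forcing the largest-magnitude loading positive, and variance
fractions sum to one. `factorVarianceAttribution()` reports, per
component, the one-way $R^2$ of a sample factor —
$SS_{between}/SS_{total}$ of the scores — so "PC1 is cell type" becomes
a number.

`classifyDEOverlap()` partitions the union of two significant gene sets
into five disjoint classes (shared up, shared down, opposite-direction,
exclusive to either contrast). Two reported statistics follow:

* `sharedFraction()`: $100\,|shared| / |sig_A \cup sig_B|$. Genes
  significant in both contrasts with discordant signs are counted as
  shared by default — they are significant in both, matching the Venn
  semantics of a "common to both" region — with `includeOpposite =
  FALSE` available; on the printed germ-line marginals (1582 and 1720
  significant genes, 869 + 245 shared same-direction, 1 opposite) both
  conventions round to 51%.
* `updownExcess()`: $100\,(n_{up} - n_{down})/n_{down}$, one decimal.

Reported percentages are rounded half-away-from-zero (base `round()`
rounds half to even, which would misreport printed-precision
percentages).

# Over-representation

`hypergeomEnrich()` is a self-contained hypergeometric over-representation
test over flat, named gene sets: population = declared universe,
successes = set within the universe, draws = query within the universe,
one-sided tail $P(X \ge k)$, BH across the retained sets. The filters
mirror the workflow's GO-style analysis: terms with fewer than
`goMinSetSize = 30` genes in the universe are dropped before testing,
enrichment is called at BH-adjusted $p <$ `goPadjCutoff = 0.01`
(KEGG-style analyses use 0.05). A separate q-value estimate alongside BH
is deliberately not computed: q-value estimation is estimator-dependent,
so the 0.01 cutoff applies to the BH-adjusted p. Term hierarchies are out
of scope; collections are flat TSV (`term_id`, `gene_id`).

# Promoter windows and target sets

The promoter is "the 1,500 bp flanking the TSS". That phrase does not
disambiguate symmetric versus upstream-only; `assignPromoter()` defaults
to the symmetric window TSS ± `promoterFlank` (3,001 bases including
the TSS base, `flankMode = "upstream"` available). A peak is in a
promoter when its interval shares at least one base with any window
(no minimum-overlap fraction); among overlapped genes the assignment
goes to the TSS nearest the peak midpoint, ties to the lexicographically
smallest gene ID so results are order-independent. "Putative target"
means promoter-overlap by default; `fallbackNearest` additionally maps
non-promoter peaks to the nearest TSS, reflecting the ambiguity between
promoter-containment and closest-gene phrasing in ChIP annotation
practice. `targetSetsIntersection()` then counts genes unique to one
dataset, common to all, and common to at least two — for any input,
unique + common-to-≥2 equals the union.

Coordinates live in `GRanges` (1-based, closed) throughout; BED is the
only 0-based surface and GTF the only other on-disk convention, both
converted at the single read/write site in the I/O layer.

# The regulatory network and connector search

`buildNetwork()` merges directed TF→gene edges, undirected PPI edges and
ChIP-derived target lists (added as TF→gene edges carrying their own
provenance) into one typed edge set: TFs regulate targets and not vice
versa, so `tfgene` edges are traversable one way, while PPI edges are
stored once per canonical unordered pair and expanded to two arcs at
traversal time. Duplicate `(source, target, type)` triples are dropped;
a `tfgene` and a `ppi` edge between the same pair are distinct semantics
and both kept, but they collapse to a single traversal arc so path
counts are not inflated. Self-loops are kept in storage, flagged in the
build summary, and ignored during search.

`shortestRegulatoryPath()` runs breadth-first search on the directed
expansion and enumerates **all** shortest node sequences from the
predecessor DAG (cap `maxPaths = 1000`, truncation flagged,
lexicographic ordering). `enumerateConnectors()` reports the interior
nodes of those paths; the `unique` flag asserts the headline condition —
exactly one connector at length exactly two. A direct src→dst edge is
reported as length 1 with an empty connector set rather than skipped.
Both functions are validated against an exhaustive DFS enumeration of
simple paths on hundreds of small random typed graphs.

# What the synthetic generator emulates — and what it does not

`designSpec()` defaults to the emulated study's 48-library layout: 27
soma libraries (3 stages × 3 genotypes × 3 replicates), 9 germ controls
(3 stages × 3), and 12 germ knockdowns at mid/late stages only. The
composition of the 48 libraries is not itemised in the source material;
this map is one consistent reconstruction. The two single-replicate
early-germ knockdown libraries are generable (`includeEarlyGermKD`) and
conventionally excluded from DE, since single replicates support no
within-group variance.

`makeTruth()` plants the qualitative structure the analysis must
recover, with values chosen once as realistic for bulk knockdown data:

* a dominant cell-type effect (30% of genes, |log2FC| 2–4) so PC1 is
  cell type;
* a stage effect confined to the soma (10% of genes, mid effects 0.8–1.6
  and larger late effects), so soma — but not germ — varies with
  development;
* germ knockdown responses mostly **shared** between *hpo* and *yki*
  contrasts (12% of genes, 70% of them downregulated, |log2FC| 1.5–3),
  small exclusive classes (2% each), and exactly one opposite-direction
  gene; soma responses mostly **exclusive** (3% *hpo*, 1.5% *yki*, a
  small shared class) with four opposite-direction genes — so germ
  shared fractions exceed soma shared fractions and the opposite counts
  echo the emulated Venn structure;
* marker genes `hpo`, `yki`, `chinmo` carrying their own signatures:
  strong *hpo* self-knockdown (−4.1), *yki* self-knockdown (−2), the
  weak *yki* reduction under *hpo* RNAi in the germ line (−0.8), and
  *chinmo* upregulation under *yki* knockdown in the germ line;
* gene-wise dispersion 0.05 and lognormal baselines scaled to the
  expected library size (default 5 × 10^5 in the examples and tests;
  counts scale linearly and no conclusion depends on depth);
* one germ-line mid-stage control whose marker mean is multiplied by
  0.1 (the planted anomalous control).

`makePeaks()` draws each peak's promoter status independently
(Bernoulli at `promoterFraction`, default 0.72 — inside the emulated
69–75% range), places promoter peaks overlapping a random TSS window and
non-promoter peaks outside every window by rejection, so the measured
fraction is exactly Binomial(n, fraction) and recovery can be tested
against the exact binomial interval.

`makeNetwork()` plants the motif `ppi(hpo–chinmo)`,
`tfgene(chinmo→yki)`, `tfgene(chinmo→hpo)`, `tfgene(yki→chinmo)` inside
a random TF-gene/PPI background sampled without replacement (so edge
counts survive deduplication exactly). The no-shortcut guarantee is by
construction: `hpo` and `yki` are never random TF sources and random PPI
edges avoid `hpo`, so `hpo`'s only outgoing arc is the planted
interaction with `chinmo`; a post-generation validation errors if the
guarantee is ever violated. Across 100 seeds the connector set is
exactly `{chinmo}`.

Not emulated: read-level artefacts (GC, length, mappability, lane
effects), correlated gene-gene noise, batch structure, chained
cell-type × stage × genotype interactions beyond the planted sums, two
genome assemblies (no liftOver), and the scale of real interaction
databases. Passing tests therefore demonstrate the correctness of the
computations and their ability to recover planted structure under NB
noise — not robustness to every artefact of real libraries.

# Numerical choices and degenerate inputs

* IRLS: working response on the log link, weights $\mu/(1+\alpha\mu)$,
  ridge $10^{-8}$ on the normal equations, linear predictor clamped to
  ±30, convergence at $10^{-8}$ max coefficient change, 50 iterations.
  Genes all-zero across the contrast get `NA` p-values and are excluded
  from the BH family.
* Swapping contrast levels negates log2FC exactly; p-values agree to
  solver tolerance (~10⁻⁶ relative), since the reparameterised IRLS
  converges to the same optimum only numerically.
* Rescaling one sample's counts by $c$ multiplies its size factor by
  $c$ relative to every other sample (the geometric-mean reference
  absorbs a common $c^{1/m}$). The per-gene fit is stable but not
  bit-identical under this perturbation — the sample's likelihood
  contribution carries the raw counts — so stability is asserted at the
  0.02 level with identical significance calls.
* Recovery benchmark: 250 planted log2FC = 2 genes are embedded in a
  2,000-gene majority-null background. With a 25% one-directional DE
  fraction instead, median-of-ratios normalisation absorbs part of the
  planted signal (measured ≈0.25 log2 units); this contamination bias
  is inherent to ratio-based normalisation, and the benchmark follows
  its stated assumption.
* PCA on a constant matrix, empty queries/universes, zero-length peak
  sets, unknown nodes, confounded designs and impossible gene packing
  all raise explicit errors (or flagged empty results where the spec of
  the operation defines one, e.g. the `empty` flag for a zero-peak
  assignment).
* Problem sizes in tests and the acceptance script (48-library designs
  at 250–2,000 genes, 2,000 peaks, 200-graph oracle sweeps) were chosen
  so the full suite exercises every stage at bulk-realistic scale while
  remaining quick to run on one CPU.

# The pipeline

`runPipeline()` chains the stages under one `PipelineConfig` — every
threshold lives there and is echoed into the summary for audit — and one
seed, fanned out to fixed per-stage child seeds so stages are
independently reproducible and the whole bundle is byte-identical under
the same seed. Stage outputs (counts, metadata, per-contrast DE tables,
enrichment, peak assignments, network edges) are written as TSV next to
a machine-readable `summary.json`. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`; the exported functions are the intended
interface for everything else.

# Known limitations

* The DE engine is a simplified NB Wald engine; it will not reproduce
  shrunken fold-changes or outlier-robust p-values of full production
  DE tools, and its guarantees are calibration and recovery properties.
* The MAD outlier rule needs ≥3 peer controls and has a nonzero
  false-positive rate at `k = 3` with nine peers.
* Enrichment ignores term hierarchies and treats collections as flat.
* The connector search reports shortest paths only; longer redundant
  routes are invisible to the headline uniqueness claim by design.
* Printed real-data headline counts that depend on deposited accessions
  and database versions (absolute DE counts, enriched-term lists, ChIP
  target totals, network sizes) are out of scope and are not asserted
  anywhere in the package.
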