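---
title: "Methods: context-stratified clustering of non-CpG methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-stratified clustering of non-CpG methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noncpg)
```

## Scope and model

`noncpg` analyses per-cytosine bisulfite methylation calls across a study of
several tissues from several individuals, and asks a single structured
question: when samples are clustered on their methylation fractions, does the
dendrogram organise them by tissue or by individual — and how does the answer
depend on the trinucleotide context of the cytosines used?

The analysis path is: context annotation → site filtering → per-context
matrices → hierarchical clustering → dendrogram composition scoring. Each
stage is an exported function; `run_pipeline()` chains them.

### Coordinates and contexts

Internally everything is 0-based, half-open. Cytosine reports are 1-based on
disk (the Bismark convention) and shifted on load; bedGraph coverage files
are 0-based half-open and taken as-is. The coverage bedGraph dialect carries
no strand column, so such calls load with strand `*` and the annotator
infers strand from the genome (plus-strand base C → `+`, G → `-`); after
annotation both dialects yield identical records.

A cytosine's context is the three bases starting at the C, read 5'→3' on its
own strand: plus-strand bases `[pos, pos+2]`, or the reverse complement of
`[pos−2, pos]` for a minus-strand cytosine. Sixteen contexts are defined
(4 CpG + 12 non-CpG); a window that leaves the chromosome or touches an `N`
is `UNDEFINED` and excluded from all context-stratified analyses — there is
no defensible imputation for a partial window. The on-disk context column is
deliberately ignored and recomputed from the genome: the genome is the
source of truth, and recomputation catches genome/calls mismatches (a
`trust_file_context` flag restores the file's values when wanted). Plus- and
minus-strand cytosines are distinct sites throughout; CHH contexts are
inherently asymmetric, and no merge rule for symmetric CpG pairs is assumed.

### Site retention

Two filters, applied in a fixed, logged order:

1. **Depth**: a site is retained for a sample iff total reads ≥ `min_depth`.
   The threshold is *inclusive* and defaults to 30×. The depth rule is
   exposed as a knob because both strict (`> 30`) and inclusive readings
   circulate; the "minimum read-depth of 30×" phrasing is taken as
   definitive here.
2. **Commonly methylated** (non-CpG only by default): among sites retained
   in *every* sample, keep those with ≥ 1 methylated read in every sample
   (equivalently, fraction > 0 everywhere). No smoothing or imputation.

Both filters are monotone (raising the threshold or adding a sample never
adds sites), and `assemble_matrix()` reports the site count after each stage
for audit.

### Clustering

Distances are plain Euclidean over methylation fractions — no
standardisation, since none is standard for this analysis (a per-site
centering flag exists). Agglomeration is implemented from scratch with the
Lance–Williams recurrences: complete (maximum), average/UPGMA
(size-weighted mean) and WPGMA (simple mean of the merged pair). All three
are monotone linkages, so merge heights are non-decreasing.

Numerical conventions:

* the minimum-distance pair merges at each step; ties (measure-zero on real
  data) break deterministically by the lexicographically smallest pair of
  cluster indices, a cluster's index being the smallest original leaf index
  it contains;
* within each merge the child containing the lowest original leaf index is
  recorded first, which fixes the leaf order;
* distances are doubles; oracle agreement is asserted to 1e-9 in the test
  suite (against both a direct-definition agglomerator and `stats::hclust`);
* a 1-leaf tree is legal (no merges); NaN distances and asymmetric inputs
  are rejected.

Dendrograms store merge heights, not branch lengths; Newick export derives
branch lengths as parent height − child height and refuses height
inversions.

### Composition scoring

The package formalizes narrative dendrogram descriptions ("samples grouped
by individual", "clustered by tissue") as an exact-node assignment. Each
leaf is assigned once, greedily:

1. **triads** — nodes whose leaf set is *exactly* all `k_tissues` samples of
   one individual;
2. **pairs** — among remaining leaves, nodes that are exactly two samples of
   one individual;
3. **tissue-pure clusters** — among remaining leaves, *maximal* nodes whose
   leaves share one tissue and span ≥ 2 individuals (the ≥ 2 rule prevents a
   single individual's same-tissue duplicates from counting as a tissue
   cluster, which matters for duplicate-based validation designs);
4. **outliers** — whatever is left.

The categories partition the samples, so the counts always sum to the leaf
count. The exact-node reading is the strictest computable interpretation of
"clustered together"; looser readings (e.g., adjacency in the leaf order)
would give higher counts. Triads take precedence over pairs, mirroring how
such dendrograms are described (full individuals first, pairs among the
rest). The score is invariant to swapping children anywhere in the tree.

### Summaries

Duplicate concordance is the fraction of shared sites with
|Δ methylation| ≤ 10 percentage points, inclusive, read as absolute points
(not relative). Per-sample summaries report median and 5th/95th percentiles
using linear interpolation (type-7 quantiles), stated explicitly because no
percentile convention is otherwise implied. Promoters are strand-aware TSS
windows — `[TSS−2000, TSS+500)` on the plus strand and its mirror image
`[TSS−499, TSS+2001)` on the minus strand, clamped at chromosome bounds;
introns are the transcript span minus exons; a transcript without exon rows
is warned about and treated as single-exon. Overlaps resolve by a fixed,
configurable precedence (promoter > exon > intron > intergenic), and a site
in any transcript's promoter is a promoter site.

## The synthetic generator

No public per-cytosine data accompany the analysis this package
operationalises, so the generator is a first-class module: it encodes the
minimal statistical structure needed to make the tissue-versus-individual
contrast reproducible and falsifiable, and every structural claim in the
test suite runs against it.

For site $s$ with context $c$, tissue $t$, individual $i$:

$$p_{s,t,i} = \mathrm{logit}^{-1}\!\left(\mathrm{logit}(b_s) +
  \frac{L_{s,\ell(t)} + r_{s,t} + u_{s,i}}{g_0}\right)$$

* $b_s$: per-site baseline. Non-CpG sites draw from Beta(0.5, 7) — a
  low-methylation regime whose latent per-sample medians sit in the 3–8%
  band. CpG sites draw from an equal mixture of Beta(8, 2) and Beta(0.5, 10),
  the familiar bimodal CpG landscape.
* $L_{s,\ell(t)}$: tissue-lineage effect, drawn per (site, lineage) with a
  context-specific sd. Cord blood and peripheral blood share the "blood"
  lineage — the haematopoietic relationship is built in because the
  tissue-driven contexts show exactly that pairing.
* $r_{s,t}$: small within-lineage residual per (site, tissue), default sd
  0.005, so the two blood tissues are similar but not identical.
* $u_{s,i}$: individual effect per (site, individual), shared across that
  individual's tissues. Genetic and stable environmental causes are not
  distinguishable in this design, so a single term represents both.
* Reads: total ~ 1 + Poisson(depth − 1) (default mean 50×), methylated ~
  Binomial(total, p). Replicates get no extra noise beyond binomial
  sampling.

**Effect scale.** Effect sds are specified in methylation-fraction units.
They are applied on the logit scale — which keeps probabilities inside
(0, 1) without hard truncation doing the work — after division by
$g_0 = E[b(1-b)]$, the analytic mean logistic derivative of the baseline
distribution (0.0549 for Beta(0.5, 7)). With this scaling a lineage contrast
of sd $\tau$ moves fractions by about $\tau$ at a typically methylated site
and proportionally less at weakly methylated sites, and the delta-method
identity $E|\Delta f| \approx 2\tau/\sqrt{\pi}$ holds (asserted in the test
suite within 25%). The alternative — dividing by the *per-site* derivative
$b_s(1-b_s)$ — was rejected: it explodes effects at low-baseline sites
through the logit's tails and breaks that identity several-fold.

Default per-context regimes (`default_context_effects()`): CAC 0.05/0.01
(tissue/individual), CTC 0.03/0.01, CAT 0.005/0.04, other non-CpG contexts
0.02/0.02, CpG contexts 0.05/0.01. Units are methylation-fraction sds;
tissue-driven contexts get lineage effects an order of magnitude above their
individual effects and vice versa.

**What the generator does not emulate.** Sites are i.i.d. — no genomic
autocorrelation, no CpG islands, no sequence-driven effects; depth is
homogeneous rather than capture-biased; there is no bisulfite
conversion-failure model and no read-level simulation. Passing tests
therefore demonstrate that the pipeline recovers the structure the generator
encodes, not that real tissues behave this way; conversely, any claimed
pipeline property that fails on data this clean would certainly fail on real
data.

A consequence of the low Beta(0.5, 7) baseline worth knowing: the
depth + non-zero cascade preferentially retains higher-methylation sites, so
medians computed on *filtered* matrices sit well above the raw 3–8% band.
The generator's level regime is asserted on the latent truth and the raw
fractions, where it belongs. Observed raw medians also sit a few tenths of a
point below the latent medians because the sample median of a
Binomial(50, p)/50 fraction is discrete.

## Study designs and problem sizes

Two built-in designs mirror the motivating study shapes: a discovery design
(20 individuals × umbilical cord, cord blood, peripheral blood; 60 samples)
and a validation design (4 individuals × duplicate muscle + one pooled
cord-blood sample as two duplicate pairs; 12 samples, 5 individual labels).

`run_context_recovery()` packages the recovery experiment used by the
acceptance script: simulate one context under a chosen regime, filter,
truncate the filtered sub-matrix to a stated size in deterministic
(chrom, pos, strand) order, cluster with complete linkage, and score. The
stated site counts (2000 for CAC/CAT-like runs, 700 for CTC-like) are the
number of sites *entering the clustering*, i.e. post-filter — matching how
per-context site counts are conventionally reported — and the simulated
genome is sized with a surplus of raw sites so the filtered matrix reaches
that size. The recovery experiments sweep 20 seeds in the acceptance script
and 8 seeds in the test suite; oracle-equivalence tests use 200 random
distance matrices with up to 10 leaves; enumeration oracles run on 10 kb
genomes. These sizes were chosen so the full suite exercises every claim in
well under typical laptop patience while leaving the statistical conclusions
unambiguous.

## Known limitations

* The exact-node reading of "clustered together" is a choice; scores are not
  comparable to analyses that count adjacency or allow slop.
* Ties in linkage are broken by a documented but arbitrary index rule; other
  implementations' unstated tie rules may order tied merges differently
  (heights are unaffected).
* The non-zero rule at depth ~50× couples site retention to methylation
  level; comparisons of filtered-set summaries across depth regimes are
  confounded by that coupling.
* No statistical significance is attached to composition scores; a
  label-permutation null is exercised in the tests (structured trees score
  near zero under permuted individual labels) but no p-value machinery is
  provided.
* Only complete, UPGMA and WPGMA linkage are implemented; Ward, single and
  centroid methods are out of scope, as are bootstrap support values.
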