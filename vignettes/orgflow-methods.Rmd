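---
title: "Methods: multi-sample TMM normalization and organ comparison with orgflow"
author: "orgflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sample TMM normalization and organ comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgflow)
```

# The problem

Comparing transcriptomes of different organs (petal stages, sepal, leaf)
sampled once each — no biological replicates — from a de novo assembly
poses two difficulties: scaffolds differ in length and samples differ in
sequencing depth, and each organ expresses a private minority of
transcripts that would bias any global scaling.  `orgflow` implements a
complete desk workflow for this setting: abundance estimation, an
n-sample trimmed-mean normalization against a synthetic reference built
from the commonly expressed genes, subcellular partitioning of scaffolds,
organ-comparison statistics, and fold-class annotation of metabolic
pathway topologies.

# Abundance model

Raw input is a scaffold-by-sample table of paired-end read counts plus
scaffold lengths.  A count below 2 is considered a fortuitous mapping
and set to zero (`cleanCounts()`); the rule is idempotent and applied
before anything else, so all per-sample totals downstream refer to the
cleaned matrix.  The abundance of scaffold $g$ in sample $k$ is

$$Y_{gk} = \frac{c_{gk}}{L_g \, T_k},$$

with $c_{gk}$ the cleaned count, $L_g$ the scaffold length in
nucleotides and $T_k$ the cleaned read total of the sample.  No
effective-length correction is applied.  Per-sample totals
$N_k = \sum_g Y_{gk}$ accompany the matrix.  Because $T_k$ is a column
sum, $Y_{gk}/N_k$ is invariant under any rescaling of one sample's
counts — the basis of the scale-invariance tests.

# The n-sample trimmed-mean factor

All $n$ samples are normalized at once against a virtual reference:

1. **Common set.** $G$ holds every scaffold with $Y_{gk} \neq 0$ in all
   $n$ samples.  Restricting to $G$ excludes organ-specific transcripts
   from factor estimation by construction.
2. **Reference profile.** $Y_g = \sum_k Y_{gk} / n$ for $g \in G$ and
   $N = \sum_{g \in G} Y_g$.
3. **M/A statistics** per sample $k$ over $G$ (log base 2 throughout):
   $$M_g = \log_2 \frac{Y_{gk}/N_k}{Y_g/N}, \qquad
     A_g = \tfrac12 \log_2 \left( \frac{Y_{gk}}{N_k} \cdot
     \frac{Y_g}{N} \right),$$
   with weights $w_g = 1/Y_{gk} + 1/Y_g$ (the approximate form of the
   binomial expression
   $(N_k - Y_{gk})/(N_k Y_{gk}) + (N - Y_g)/(N Y_g)$, available via
   `exactWeights = TRUE`).
4. **Trimming.** M and A are min–max normalized per sample; gene $g$ is
   kept in $G^\ast$ when
   $$m_\ell < \frac{M_g - M_{\min}}{M_{\max} - M_{\min}} < m_u
     \quad\text{and}\quad
     a_\ell < \frac{A_g - A_{\min}}{A_{\max} - A_{\min}} < a_u,$$
   strictly, with defaults $(m_\ell, m_u) = (0.3, 0.7)$ and
   $(a_\ell, a_u) = (0.2, 0.8)$.  A degenerate range (all M equal, or
   all A equal) carries no trimming information and passes all genes;
   failing all genes would leave the factor undefined exactly where
   $R = 1$ is the obvious answer.
5. **Factor.**
   $$\log_2 \mathrm{TMM}_k = \frac{\sum_{g \in G^\ast} w_g M_g}
     {\sum_{g \in G^\ast} w_g}, \qquad R_k = 2^{\log_2 \mathrm{TMM}_k}.$$

The normalized expression reported is $(Y_{gk}/N_k)/R_k \times 10^6$ —
a per-million convention; the constant cancels in every ratio,
correlation and fold used downstream.

```{r tmm-example}
set.seed(1)
cts <- matrix(rpois(300, 200) + 20L, 100, 3,
              dimnames = list(sprintf("sc%03d", 1:100), c("A", "B", "F")))
sc <- ScaffoldCounts(cts, setNames(sample(300:2000, 100), rownames(cts)))
res <- normalizeTMM(estimateAbundance(cleanCounts(sc)))
normFactors(res)
```

## Numerical and design choices

* **Log base 2** throughout; factors satisfy
  $\log_2 R_k$ = the weighted mean of M over $G^\ast$ exactly.
* **Trimming is per sample**: each sample gets its own $G^\ast$.
* **Ties at a trim boundary are excluded** (the inequalities are strict).
* The reference is a **virtual sample**; factors are only reported for
  real samples, and $R = 1$ to within 1e-12 whenever a sample equals the
  reference in relative abundance.
* All four bounds are configurable through `TrimBounds()`.

## Known limitations of the estimator

The trimming window is anchored to the *extremes* of M and A rather than
to quantiles, and the weights are proportional to $1/Y$, i.e. large for
the least-abundant (noisiest) genes.  Two practical consequences, which
the package documents rather than hides:

* A single outlying gene moves $M_{\min}$ or $M_{\max}$ and thereby the
  whole kept window.  With strongly asymmetric differential expression
  the non-DE bulk can sit near a window edge, and the factor then
  reflects a flank of the bulk rather than its centre.  In the extreme
  noiseless case (M taking only two distinct values) the window can fall
  in the gap between them, leaving $G^\ast$ empty — reported as an error
  advising wider bounds.
* Because the weights grow as abundance falls, genes with counts near
  the cleaning threshold dominate the weighted mean, and the downward
  bias of log ratios at small counts propagates into $R$.

On low-noise data with mild composition differences the estimator is
accurate (see the identity and scale-invariance properties in the test
suite); on noisy data its factors should be read as approximate scaling
constants, not precise composition estimates.  The simulation tests
quantify this honestly: factor recovery on a 2000-gene, 3-sample design
with 5% 8-fold one-sided DE and negative-binomial noise deviates from
the analytic truth by far more than the no-noise analysis would suggest,
for exactly the two reasons above.

# Subcellular partitioning

Scaffolds are classified from tabular (12-column) nucleotide-alignment
hits against a chloroplast and a mitochondrial reference genome:

* chloroplast: e-value $\le 10^{-5}$, identity $\ge 95\%$, coverage
  $\ge 80\%$;
* mitochondrion: e-value $\le 10^{-5}$, identity $\ge 80\%$, coverage
  $\ge 50\%$;
* everything else — including every scaffold of length $\le 200$ nt,
  the sequencing-library length — is nuclear by exclusion.

Coverage is the alignment length over the *scaffold* (query) length;
`coverageBy = "subject"` switches the denominator.  The classifying hit
per scaffold and reference is the best by (e-value, then bit score).
When a scaffold passes both organelle filters, chloroplast takes
precedence and the conflict is recorded with both hits.  The three
classes are a disjoint cover; relaxing any threshold can only grow the
corresponding class.  `sharedSets()` decomposes per-group expressed
sets into Venn regions; because the denominator of a "shared
percentage" is ambiguous in general, both the all-group intersection
and the union are reported and the fraction is their ratio.

# Organ comparison statistics

`correlateCommon()` restricts two expression vectors to the genes
non-zero in both (commonly expressed), then computes Pearson's $r$ with
either the exact t-test, $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df, or
— for very large $n$ — the Fisher z-statistic
$z = \operatorname{atanh}(r)\sqrt{n-3}$.  Tests are two-sided by
default.  `wilcoxonRank()` is the one-sample signed-rank test against a
fixed value: exact for $\le 25$ non-zero differences without ties,
normal approximation with continuity correction otherwise; at least 5
non-zero differences are required.

`clusterExpression()` scales each row by its maximum (maxtf), takes
Pearson correlation as similarity, $1-r$ as distance, and builds the
tree by average linkage (UPGMA).  Any standard agglomerative criterion
would serve; UPGMA is chosen because it is deterministic for a given
input order and has a textbook definition that a hand computation can
verify.  Trees export to Newick with merge heights as branch lengths.

# Pathway fold-class annotation

A pathway is a node table (EC number or gene name, mapped scaffold IDs)
plus a directed edge table.  A node's level per sample is the **sum** of
its mapped scaffolds' normalized levels (isoforms aggregate by sum; a
per-scaffold reading is available by mapping one scaffold per node).
Given disjoint target and reference sample groups, each node receives:

* aggregate levels (mean by default — the group mean matches how a
  multi-stage organ series is compared against a single reference organ;
  max supports highest-sample readings);
* an orientation-free fold = larger/smaller aggregate;
* a tier by strict thresholds: $>2$ → 1 (↑), $>10$ → 2 (↑↑), $>100$ → 3
  (↑↑↑), otherwise 0 (≈).  A fold of exactly 2 is ≈.  A zero aggregate
  on one side with expression on the other is an infinite fold, tier 3 —
  a presence/absence call;
* the highest-expressing sample over all groups (first sample on ties);
* an absent flag for nodes with no resolvable scaffold.

Swapping target and reference flips direction but never fold or tier,
and rescaling the whole matrix changes nothing — both are tested
properties.  Exports: GraphViz DOT (glyph and sample letter per node,
red for target-up, green for reference-up) and a flat TSV.

# The synthetic-data generator

`simulateOrganData()` emits every input the toolkit reads, from a
seeded `simulationSpec()`.  The model: base expression $p_g$ is
log-normal (sdlog 1.2, a realistic bulk-RNA spread); the expected count
of gene $g$ in sample $k$ is proportional to
$\text{libsize}_k \, p_g L_g f_{gk}$ with $f_{gk}$ the planted fold
(default: 5% of genes 8-fold up in sample 1); counts are
negative-binomial with dispersion 0.1 (configurable; 0 gives Poisson);
dropout zeroes non-DE entries at rate 0.05 to emulate organ-specific
absence.  Defaults use six samples with unequal depths around $10^6$
reads, mirroring a six-organ single-genet design.  Organelle scaffolds
(5% chloroplast, 3% mitochondrial) carry planted hits strictly inside
the classification thresholds, plus decoy hits strictly outside; a toy
five-node pathway maps alternating DE and non-DE scaffold pairs.

Ground truth ships with the data: the true factor of sample $k$ is the
expected sample-vs-reference relative-abundance ratio of a non-DE gene,
which is identical for every non-DE gene and closed-form in the design
(lengths cancel in relative abundance); true classes, the DE gene set,
and true node tiers (from the noiseless expectation) accompany it.

What the generator does *not* model: read-level errors, mapping
ambiguity between paralogous scaffolds, assembly fragmentation, and
correlated expression modules.  Passing tests therefore demonstrate
algorithmic correctness and the stated invariances on structurally
faithful data — not performance on real libraries.

# Problem sizes in the test suite

Tests run on tables of 5–30 genes for formula-level checks, 100 random
tables of up to 20 genes × 4 samples for oracle equivalence (every
formula re-evaluated by an independent loop-based implementation,
agreement to 1e-10), and simulations of 200–2000 genes × 2–6 samples
for recovery and partition properties.  These sizes keep the full suite
fast while exercising every code path; nothing in the method scales
worse than the number of table cells.
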