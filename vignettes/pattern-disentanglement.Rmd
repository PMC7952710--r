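---
title: "Statistical pattern discovery and disentanglement for relational data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical pattern discovery and disentanglement for relational data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pddkit)
```

## The problem

Relational tables in clinical and genomic work — patient records with
mixed-mode attributes, or aligned protein sites with residues as values —
carry associations among attribute values (AVs) that come from several
underlying sources at once: different diseases, taxonomic groups, or
functional domains. Frequent-itemset miners applied to such tables return
thousands of overlapping rules because associations belonging to different
sources are *entangled*: one AV can take part in the patterns of two
groups, and the groups themselves overlap within entities. `pddkit`
separates those sources statistically before any pattern is grown, so
that the final pattern set is small, class-coherent, and traceable from
source to pattern to individual entity. Because the statistics are
residual-based rather than frequency-based, rare groups (a 5-of-80 class)
surface just as clearly as dominant ones, without resampling.

## The statistic

For two AVs with marginal counts $n_a$, $n_b$ in a table of $N$ entities,
let $o$ be their co-occurrence count and $e = n_a n_b / N$ its expectation
under independence. The adjusted standardized residual is

$$ d \;=\; \frac{(o - e)/\sqrt{e}}{\sqrt{(1 - n_a/N)(1 - n_b/N)}} , $$

which is asymptotically standard normal under independence, so
$|d| \ge 1.96$ marks two-sided 95% significance. The same form extends to
$k \ge 2$ AVs (one per attribute) with
$e = N\prod_i (n_i/N)$ and variance factor $\prod_i (1 - n_i/N)$; for
$k = 2$ the two coincide. The *SR matrix* collects the pairwise residuals
over all cross-attribute AV pairs; same-attribute pairs are mutually
exclusive events and are held at zero, which keeps the matrix symmetric
and eigendecomposable.

Small expected counts ($e < 1$) are permitted but flagged in a message:
with five-entity classes they are unavoidable, and the residual for such
cells is exactly the quantity that makes rare-class structure visible. No
continuity correction is applied and no multiple-testing adjustment is
made beyond the fixed threshold — a single interpretable cutoff is the
design point, not family-wise error control.

## Disentangling the sources

The SR matrix is eigendecomposed as is, without column centering: it is
already a deviation-from-independence representation, so centering would
destroy the calibration that makes 1.96 meaningful. Each eigenpair
$(\lambda, v)$ defines one *disentangled space* (DS): the principal
component $v$ over the AVs plus its re-projected residual space (RSRV),
the rank-one matrix $\lambda v v^\top$. Summed over all spaces the RSRVs
reconstruct SR exactly, so each space isolates one statistical source's
share of every pairwise residual.

Choices that matter here:

* **Ordering and sign.** Spaces are ranked by $|\lambda|$ (negative
  eigenvalues are genuine for symmetric matrices with zero blocks and are
  kept); the eigenvector sign is fixed so the largest-magnitude loading
  is positive. Both choices exist purely to make ordinals and
  pattern-group numbering deterministic across platforms.
* **Retention.** A space is kept iff its RSRV has at least one
  cross-attribute entry with $|{\cdot}| \ge 1.96$ and at least two
  significant AVs spanning two attributes. Retention is per space, so a
  weak middle space can be dropped while a later one is kept.
* **Pattern groups.** Within a retained space, significant AVs split by
  the sign of their PC loading into PG1 (positive) and PG2 (negative) —
  opposite sides of one contrast, e.g. the two classes of a binary
  outcome.

### Sub-pattern groups: why average linkage

A PG can still contain more than one source: when the leading contrast is
"class A versus everything else", the AV blocks of classes B and C both
land on the negative side. Sub-pattern groups (SubPGs) are formed by
average-linkage agglomeration on the SR submatrix of the PG's members,
merging while the average association between groups is $\ge +1.96$. Two
alternatives were considered and rejected:

* *Rank-one RSRV edges*: inside one rank-one space every same-side entry
  has the sign of $\lambda$, so no rule based on it can ever split a PG's
  members into two co-occurring blocks.
* *Single-link connected components on SR*: one entangled AV shared by
  two sources is positively associated with both blocks and bridges them
  into a single component.

Average linkage keeps both failure modes out: a single bridge AV cannot
outvote the block-to-block negative residuals, while a genuinely
mutually-positive group merges at once. UPGMA merge heights are monotone,
so cutting the dendrogram at the threshold is well defined (tiny
floating-point inversions are clamped). Each non-empty SubPG becomes a
*disentangled unit* addressed by the triple code `[DS PG SubPG]`, e.g.
`[2 1 2]`.

## Growing patterns

Within each SubPG, every AV subset (one AV per attribute, order $\ge 2$)
whose compound residual reaches the threshold and whose EID-intersection
— the set of entities containing all its AVs — has at least
`min_occurrence = 2` entities is a pattern. The search is levelwise with
the anti-monotone support prune only; significance is *not* used to prune
supersets because the compound residual is not anti-monotone. All
qualifying subsets are kept (the comprehensive view), which is what makes
per-entity pattern counts meaningful. Restricting candidates to
within-SubPG AVs is the entire payoff of disentanglement: it is what
shrinks an entangled rule explosion to a handful of patterns per source.
Repulsive subsets ($d \le -1.96$) are recorded separately and excluded
from the knowledge base. A `max_order = 8` cap guards the exponential
worst case; the tables this package targets have at most a dozen or so
attributes.

## The knowledge base and its uses

The knowledge base links units, patterns and entities on two levels: the
Summary section (per DSU: the union super-pattern and, per entity, how
many of the DSU's patterns it contains) and the Comprehensive section
(per pattern: 0/1 entity containment flags). A summary count always
equals the column sum of the unit's comprehensive flags. Entities with no
pattern remain as all-zero columns: that visibility is what outlier
detection reads. Row order (DSU-lexicographic, then significance
descending) and column order (input entity order) are fixed so exports
diff cleanly.

Downstream analytics are deliberately simple readings of the KB:

* **Entity clustering** assigns each covered entity to its max-count DSU
  (ties to the lower code) and merges DSU clusters whose covered-entity
  Jaccard overlap reaches `merge_overlap = 0.5`, transitively. Clusters
  are scored against reference classes by the optimal one-to-one
  cluster-to-class assignment (Hungarian algorithm, solved exactly);
  unassigned entities count as errors.
* **Outliers** are the all-zero columns. **Mislabeled entities** match at
  least one pattern but only patterns of classes other than their
  recorded label; the inferred class is the significance-weighted
  majority over the matched patterns. The two sets are disjoint by
  construction.
* **Classification** scores class $c$ for a new row as
  $\sum_{\text{matched patterns of } c} d \times \text{confidence}$,
  predicting the argmax. The weighting is this package's own choice: it
  lets strong, pure patterns dominate without any trained parameters. A
  row matching nothing abstains to the training-majority class, with the
  abstention reported — so accuracy is always defined but abstentions
  remain visible. Class labels never enter the statistics anywhere; they
  are attached to patterns afterwards as references.

`run_split_experiment` reads "repeated validation" as 10 stratified
random 80/20 splits rather than literal 10-fold cross-validation — an
80/20 split ratio and 10-fold partitioning are mutually exclusive, and
the split ratio is the stated condition. With `remove_anomalies = TRUE`
the default scope screens the *whole* table before splitting: anomaly
removal is data cleaning, and a mislabeled held-out row otherwise caps
measurable accuracy regardless of the classifier ("train"-only screening
remains available via `anomaly_scope`).

## The synthetic generator

`synthetic_spec()` plants exactly the structure the pipeline claims to
recover: per-class AV blocks over the attributes, optionally sharing AVs
across classes (entanglement); a fidelity parameter (default 0.9 — each
blocked cell takes its block value with probability 0.9, else a uniform
other value, a realistic per-site conservation level for conserved
protein regions and strong clinical indicators); transition groups that
take the target class's AV per attribute with a stated fraction;
all-uniform noise entities; and recorded-label flips whose true labels
are kept in a ground-truth sidecar. Each component draws from its own
RNG stream split from the seed, so changing the mislabel rate never
perturbs the table cells — the paired anomaly-removal experiment depends
on exactly this.

Three presets mirror the shapes the method is aimed at: `apc1_like`
(80 entities, 9 aligned-site-like attributes, imbalanced classes
30/25/20/5, two deliberately shared AVs), `cancer_transition_like`
(447/235 two-class with two 30-entity transition groups at interpolation
fractions 0.33 and 0.67), and `heart_like` (270 entities, 13 mixed-mode
attributes, classes 150/120, numeric attributes as class-separated
Gaussians). The presets mirror shape only; they do not statistically
clone any real dataset. What passing on them shows: recovery of planted
block structure, rare classes, mislabels and transition groups under
stochastic noise. What it does not show: behavior under missing-data
mechanisms, ordinal attributes with many levels, correlated background
noise, or label noise that is systematic rather than random — real
clinical tables have all four.

When scoring AV-block recovery, an AV planted in more than one block has
no single true block, so shared AVs are excluded from the adjusted Rand
index; every unshared planted AV is labeled by the first unit containing
it.

## Numerical and degenerate-input choices

* Quantization intervals are left-closed/right-open with the last bin
  closed; `equal_width` with 3 bins is the default (parameter-light, and
  small variations land in one interval). A stored scheme re-applied to
  its own training data reproduces it exactly; held-out values outside
  the training range clamp into the edge bins.
* Missing values are a reserved non-category excluded from the AV catalog
  and all statistics. Constant AVs ($n = N$) carry no association
  information and are dropped with a warning rather than failing the run.
* Eigenvalue ties order by (|λ| desc, peak-loading index asc); class-
  association and classification ties break lexicographically and are
  flagged.
* Degenerate marginals ($n \in \{0, N\}$) are errors in the residual
  functions themselves but are kept out of the pipeline by catalog
  construction.

## Problem sizes

The validation suite runs entirely on generated data: residual and
pattern-search oracles on hundreds of random tables up to $N = 50$;
type-I control at $N = 1000$; planted-source recovery on the 80-entity
preset over 20 seeds; mislabel recovery at $N = 500$ (5% planted flips)
over 20 seeds; and the paired anomaly-removal experiment at $N = 300$
with 10% flips, 10 splits × 20 seeds. These sizes were chosen as the
smallest at which the statistical claims are meaningfully testable —
e.g. a 5%-mislabel run needs enough flips for precision/recall to be
stable.

## Known limitations

* The SR matrix is dense over the AV catalog; a few hundred AVs is the
  intended regime, not thousands (no sparse eigensolvers).
* A pairwise association split evenly across two spaces (a perfectly
  balanced symmetric contrast) can fall below threshold in each space
  individually; in practice block-structured sources concentrate their
  residual mass in one space, but knife-edge symmetric cases exist.
* The comprehensive pattern list grows combinatorially with SubPG size;
  `max_order` caps the worst case at the cost of completeness beyond
  that order.
* Cross-SubPG patterns are out of scope by design — that restriction is
  the disentanglement, not an approximation of it.

## A short session

```{r, eval = FALSE}
g <- generate(preset("apc1_like", seed = 1))
fit <- pdd(g$table)
summary(fit)
cluster_entities(fit$kb)
anomalies(fit)
score_against_truth(fit, g$truth)
```
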