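---
title: "Methods: copy-number subtype discrimination with mRMR + IFS + cosine NNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number subtype discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnasubtype)
```

This vignette documents the statistical procedure the package implements,
the assumptions behind it, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where the procedure leaves them open.

## The procedure

The input is a samples × probes matrix of copy-number values with one binary
class label per sample (positive = ACA, negative = SCC in the motivating
application). The pipeline is scale-agnostic — raw copy number and log
ratios work equally, because every stage uses only the ordinal structure of
each probe and the direction of each sample vector. No missing values are
accepted; the container rejects them at load time rather than imputing.

**Discretization.** Mutual information is estimated from discrete densities,
so each probe is reduced to three states relative to its own distribution:
$-1$ below $\mu - \alpha\sigma$, $+1$ above $\mu + \alpha\sigma$, else $0$,
with $\mu$ the probe mean and $\sigma$ its sample standard deviation
($n-1$ denominator). The default $\alpha = 1$ follows the convention of the
original mRMR software. A zero-variance probe maps entirely to state 0 and
therefore carries zero relevance. The two threshold comparisons are strict,
so a value exactly at a cut stays in the neutral state.

**Mutual information.** The plug-in estimator on the observed joint cells,
$I(x,y) = \sum p(x,y)\log_2\!\frac{p(x,y)}{p(x)p(y)}$, in bits. The base
only rescales all values uniformly and cannot change any ranking. Cells with
zero joint probability contribute nothing.

**mRMR ranking.** Greedy forward selection: round 1 picks the probe with
maximum relevance $D_j = I(j;\text{class})$; round $m+1$ picks the
unselected probe maximizing $D_j - R_j$ where
$R_j = \frac{1}{m}\sum_{s \in S} I(j; s)$ is the mean redundancy against the
already-selected set $S$. This difference form (MID) is the default of the
reference mRMR implementations; the quotient form $D_j / R_j$ (MIQ) is
available via `criterion = "quotient"` for sensitivity analysis, defined as
$D_j$ when $R_j = 0$. Both relevance and redundancy are computed on the
discretized states (one code path). Ties at any round are broken by input
probe order — deterministic and order-stable. The vectorized implementation
accumulates each probe's cell terms in a fixed order so that exactly tied
count tables produce exactly tied scores, and it is tested for exact
agreement with a brute-force greedy oracle on instances up to 20 probes.

**Classifier and evaluation.** The nearest-neighbour classifier uses the
cosine nearness $d(x,y) = 1 - \frac{x \cdot y}{\|x\|\|y\|} \in [0,2]$,
which is invariant to per-sample positive scaling — appropriate for array
data measured on arbitrary per-array scales. A zero-length vector has no
direction, so it is an error rather than a silent convention. Evaluation is
leave-one-out (jackknife) cross-validation: each sample is predicted by the
classifier trained on all others; nearness ties go to the earliest training
sample. From the pooled confusion counts:
$Sn = \frac{TP}{TP+FN}$, $Sp = \frac{TN}{TN+FP}$,
$Acc = \frac{TP+TN}{n}$, and
$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$, with $MCC := 0$ when any
denominator factor vanishes (the standard convention). Metrics are kept at
full precision and displayed at 4 decimals.

**Incremental feature selection.** For $i = 1 \ldots N$ the top-$i$ prefix
of the mRMR list is evaluated by LOOCV, producing the IFS table
($i$, Sn, Sp, Acc, MCC). Every row is an independent, fresh LOOCV on exactly
that prefix — no warm starts — so each row can be reproduced in isolation;
this costs a constant factor over an incremental Gram update and removes any
question of accumulation order affecting a tie. The optimum is the smallest
$i$ achieving the maximum MCC: MCC is the optimization target because it is
robust to the class imbalance typical of these cohorts, and parsimony breaks
plateau ties. No early stopping: the full curve is always produced.

**Probe-to-gene mapping.** Probe $p$ maps to gene $g$ iff the chromosomes
match and $\text{start}(g) - e \le \text{pos}(p) < \text{end}(g) + e$ with
extension $e = 2000$ bp by default, applied symmetrically (strand is
ignored). Coordinates are 0-based half-open internally (BED convention); a
probe exactly at $\text{end}(g)+e-1$ maps, at $\text{end}(g)+e$ does not —
the boundary follows half-open arithmetic since no external convention
forces either choice. The overlap is computed with
`GenomicRanges::findOverlaps()` and is tested against an all-pairs oracle;
the pair set is monotone non-decreasing in $e$.

**Over-representation.** For a query gene list against a gene set within a
universe, the 2×2 table is $a = |list \cap set|$, $b = |list \setminus set|$,
$c = |set \setminus list|$, $d = |universe \setminus (list \cup set)|$ (the
set is intersected with the universe first). The p-value is the one-sided
hypergeometric upper tail $P(X \ge a)$, summed in log space
(log-sum-exp over `dhyper(..., log = TRUE)` terms) for stability on
genome-sized universes; degenerate margins give $p = 1$. Raw p-values are
reported without multiplicity correction, matching the classical
presentation of such tables; a Benjamini–Hochberg column is opt-in
(`p_adjust = TRUE`). When no universe is supplied, the union of collection
members and the query list is used with a warning — supply the array or
genome gene universe for honest inference, since a too-small universe
inflates significance.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1.0 | discretization width in per-probe sd units |
| `top_n` | 1000 | probes kept by MaxRel/mRMR ranking |
| `criterion` | `"difference"` | mRMR combination form (MID vs MIQ) |
| `max_n` | `top_n` | IFS prefix budget |
| `extension` | 2000 bp | symmetric gene-span extension for mapping |
| `p_adjust` | `FALSE` | append a BH-adjusted column to enrichment |

## The synthetic-data generator

`synthetic_spec()` / `generate_cna()` emulate the structure that makes this
feature-selection problem interesting, with defaults mirroring the
motivating cohort (208 positive, 93 negative samples):

* **Background**: every probe is i.i.d. Gaussian noise around a diploid
  baseline (2.0), sd `noise_sd = 0.3`. Gaussian is the simplest adequate
  choice — the pipeline only consumes ordinal structure.
* **Planted signal**: `n_informative = 10` parent probes receive a
  class-mean shift of `effect_size × noise_sd` (default effect 2). Shift
  signs alternate across parents: real subtype contrasts involve both gains
  and losses, and a one-sided design would make the two class-mean vectors
  collinear — invisible to the scale-invariant cosine nearness by
  construction.
* **Incomplete penetrance**: each positive-class sample carries each planted
  alteration with probability `penetrance = 0.8`, and the per-carrier shift
  is scaled by `1/penetrance` so the class-mean shift contract holds
  exactly. Tumour cohorts are heterogeneous — no recurrent CNA is present in
  every tumour — and this is what keeps the LOOCV MCC curve informative
  across the whole planted set rather than saturating after a handful of
  probes: samples carrying few alterations are classified correctly only
  once most planted probes have entered the prefix.
* **Redundancy**: each parent has `block_size = 2` partner probes equal to
  the parent plus independent Gaussian jitter (`jitter_sd = 0.2`), giving a
  parent–partner correlation above 0.9 by construction. This creates exactly
  the relevance/redundancy trade-off mRMR exists to exploit, and makes
  "parents are selected before their copies, copies are deferred relative to
  their MaxRel positions" a testable property.
* **Determinism**: one integer seed drives a single generator stream;
  equal specs produce byte-identical matrices.

What the generator does **not** emulate: array physics (probe-specific
response, GC waves), segmentation artifacts (spatially correlated errors
along the genome beyond the planted blocks), chromosome-arm-scale events,
or population substructure. Passing the synthetic validation therefore
demonstrates that the machinery is correct and recovers planted signal under
realistic noise, penetrance and redundancy — not that any particular
accuracy will be attained on real arrays.

The companion helpers keep the downstream stages testable:
`generate_annotation()` lays probes on one chromosome at 10 kb spacing with
a 1:1 gene per probe, and `generate_genesets()` builds one planted set
(genes of the informative parents, padded to `set_size`) plus random null
sets over the probe-gene universe.

## Validation scale and acceptance checks

The test suite validates the full synthetic pipeline at 301 samples × 2,000
probes with the top 200 mRMR probes — large enough for stable mutual
information estimates at realistic cohort size, small enough to run in a few
seconds per replicate — over five fixed seeds, summarized by the median of
the per-seed planted-parent recovery and optimal MCC. The median is used
because a single replicate's optimum size sits on a discrete MCC plateau and
can fluctuate by a few probes either way; the per-seed values are also
reported by `scripts/acceptance.R`. Desk-scale checks recompute published
classifier metrics from their implied confusion matrix and published
enrichment p-values from their printed contingency counts. Property-based
tests pin the greedy ranking to a brute-force oracle (≤ 20 probes), the
hypergeometric tail to explicit pmf enumeration (small tables) and to direct
summation within 1e-10 relative error (universes up to 1,000), and LOOCV
bookkeeping to its conservation and no-leakage invariants.

## Known limitations

* Only binary class labels; no multi-class extension.
* k = 1 nearest neighbour with cosine nearness only — no distance weighting
  or alternative metrics.
* Mutual information is estimated from three discrete states; probes whose
  class signal survives discretization poorly (e.g. variance differences
  with equal means) are under-ranked.
* The enrichment model treats gene sets as flat (no GO-graph propagation)
  and tests each set marginally.
* LOOCV is computed exactly (n classifier fits per prefix); for very large
  cohorts a user may want to subsample prefixes of the IFS curve.
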