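---
title: "Predicting strain-specific gene expression from co-expression neighborhoods"
author: "coexpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting strain-specific gene expression from co-expression neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A yeast perturbation experiment measures genome-wide expression in four
strains — a wild type and three transcription-factor deletion strains —
at eight time points (0, 10, 20, 30, 45, 60, 90, 120 minutes) after a
chemical treatment, with two biological replicates per sample. For a
designated *prediction strain*, the expression of a set of *target
genes* is hidden; the task is to predict it from (i) the targets'
profiles in the three complete strains and (ii) all other genes'
profiles in all four strains.

`coexpred` treats this as a missing-value estimation problem on a
co-expression network rather than a regulatory-network inference
problem: if two genes are co-expressed across the strains with complete
data, they are likely co-expressed in the prediction strain too, because
the deleted regulators act on overlapping processes. Values are assumed
to be normalized, log-scale intensities (RMA-style); the package never
re-normalizes or centers them.

## Distances

For genes $i, j$ and strain $s$, let $d_s(i,j)$ be the Euclidean
distance between their timepoint profiles in $s$. The working distance
is the combined
$$D_{ij} = \sqrt{\textstyle\sum_{s \in \text{complete}} d_s(i,j)^2},$$
i.e. the Euclidean distance between profiles concatenated across every
strain except the prediction strain. Replicates are averaged before the
distance by default; `replicates = "concat"` instead keeps them as
extra coordinates (the original protocol does not state which was used;
the mean is the default because it halves the influence of
replicate-level noise without changing the geometry of strong signals).
Because $D$ never touches the prediction strain, it is invariant under
masking and is computed once per dataset and reused everywhere.

## The four predictors

**Standard KNN** (`predictKNN`, $k = 10$): the estimate of a target's
expression at time $t$ is the plain average of the prediction-strain
values at $t$ of its $k$ nearest genes under $D$. Prediction targets
are never used as neighbors of other prediction targets — their
prediction-strain values are hidden — and this prohibition is enforced
in all four models. $k = 10$ is the default of record, selected by the
random-gene holdout protocol below.

**Mutual KNN, "KNN\*"** (`predictKNNStar`, $K = 20$, fallback 3): genes
belong to pathways of different sizes, so a fixed $k$ is a compromise.
In the mutual nearest neighbor graph, an edge $i\!-\!j$ exists only when
each gene lies in the other's top-$K$ list, so neighborhood sizes adapt
to the local co-expression structure. Targets that nobody reciprocates
would be isolated; each target is therefore guaranteed its top three
nearest eligible genes. Mutual membership is tested on the *plain*
top-$K$ lists over all genes (the prohibition removes forbidden genes
from the final set, not from the lists): forbidding targets from other
genes' lists would destroy genuine mutual edges that the construction
is designed to detect.

**Dense subnet** (`predictDenseSubnet`, $K = 20$, $m = 10$): take the
target's top-$K$ eligible genes, and within the subgraph they induce in
the global $K$-NN graph keep the $m$ of highest degree. The rationale:
candidates that are densely interconnected form the pathway the target
sits in, while well-ranked but weakly connected candidates may be
coincidentally similar. Edges are treated as undirected (an edge exists
if either endpoint lists the other); degree ties break by smaller
distance to the target, then dataset gene order, and edges to the
target itself are not counted, so the selection reflects candidate
interconnection only.

**Linear regression** (`predictRegression`): for each timepoint $t$,
ordinary least squares of the prediction-strain value at $t$ on the
same gene's $3 \times 8 = 24$ complete-strain values plus an intercept,
fitted over all genes that are not masked. The original formula lists
unnamed constants; we interpret them as intercept plus coefficients,
since omitting the intercept would force regression through the origin
of an arbitrary log-intensity scale. Rank-deficient designs abort with
the names of the collinear columns rather than silently dropping them.

Neighbor averaging is unweighted in all three KNN variants, matching
the formula of record; distance-weighted averaging is deliberately not
a default anywhere.

### Determinism and tie-breaking

Equidistant neighbors are ordered by dataset gene order (stable sort),
making every construction deterministic across platforms. In the
exact-recovery limit (identical module members, distance 0 ties) any
resolution yields the same prediction, but determinism matters for
reproducible neighbor lists and the paired holdout design.

## Evaluation

Predictions are scored against the gold standard per the challenge
protocol. Under the official configuration (`evalConfig("rank",
"spearman")`) both matrices are rank-transformed per timepoint — rank 1
for the strongest induction, rank $n$ for the strongest repression,
midranks for ties. A *gene profile* is the cross-target vector at one
timepoint; a *time profile* is the cross-timepoint vector of one
target. Accuracy is the Spearman (or Pearson) correlation per profile;
overall accuracies are arithmetic means, overall p-values geometric
means (computed in log space), and the score is
$-0.5\log_{10}(p_G\,p_T)$. Three alternative variants vary the
transform and correlation; on untied data the three rank-invariant
variants give identical gene-profile accuracies, which the tests
assert.

P-values are one-sided (upper tail) throughout. For Spearman profiles
of length $\le 10$ — in particular the 8-timepoint time profiles — the
p-value is computed by exact enumeration of all $n!$ orderings of
untied ranks (the null distribution depends only on $n$ and is cached);
a perfect 8-point time profile thus has $p = 1/40320 \approx
2.48\times10^{-5}$. Longer profiles (the 50-gene gene profiles) and all
Pearson variants use the one-sided $t$ approximation with $n-2$ degrees
of freedom. Both modes are exposed in `profilePValue`; the report
records which was used. Degenerate (constant) profiles have no defined
correlation: accuracy is set to 0 and the p-value to 1, with a warning.
At $|r| = 1$ the $t$ approximation underflows; p-values are clamped at
the smallest positive double so a perfect prediction keeps a finite
score.

The challenge text defines induction relative to the untreated wild
type; `evalConfig(baseline = )` optionally subtracts a per-gene
reference vector from both matrices before scoring. It is off by
default — predictions are scored as-is — because the official transform
already ranks within each timepoint and the baseline reading of the
challenge description is an interpretation, not a stated rule.

## Model selection

`holdoutRound` masks `nHeld` (default 50) uniformly sampled non-target
genes in the prediction strain, predicts them, and scores the overall
gene-profile accuracy against their true values; `repeatHoldout`
repeats this 10 times (per-repeat seeds `baseSeed + 0, 1, ...`) and
averages. Only gene-profile accuracy drives selection: time-profile
accuracy depends on which genes are drawn and is a poor guide for
targets that were chosen for their special behavior. `sweepK` runs the
protocol over a grid of $k$ with the *same* held-out sets for every $k$
(a paired design, so curve differences are not confounded by mask
sampling noise; whether the original sweep was paired is unstated, and
pairing strictly reduces the variance of the comparison).

## The synthetic generator

The real challenge data were distributed privately, so everything here
is exercised on a generator (`simConfig` / `simulateExpression`) that
emulates the design: genes grouped into co-expression modules whose
latent time profiles are smoothed, unit-variance random walks; strain
effects that scale and offset whole module profiles (deleting a
regulator shifts its pathway coherently); per-gene loadings and
offsets; i.i.d. Gaussian replicate noise on the log-like scale; and a
fraction of module-free background genes. Targets are sampled with
probability proportional to (prediction-strain perturbation)^`targetBoost`,
mirroring the observation that real challenge targets were the genes
most perturbed by the treatment. The gold standard is the replicate-mean
of the generated prediction-strain values, exactly as generated.

Defaults are the study conditions: 6000 genes, 4 strains, 8 timepoints
(the challenge minutes), 2 replicates, 50 targets, module sizes uniform
on 10–30 (placing the useful neighborhood scale around the $k$ = 10–30
region), strain-effect sd 0.3, noise sd 0.1 of the unit signal sd,
15% background genes. The `"heterogeneous"` preset (500 genes, module
sizes 3–40, noise sd 0.3) creates the mixed-pathway-size, noisier
regime in which adaptive neighborhoods are expected to beat a fixed
$k$. All draws flow from one seed; generation is byte-reproducible.

What the generator does *not* emulate: probe-level microarray noise
(saturation, probe affinity), non-Gaussian heavy tails, condition-
specific partial co-expression, or the actual regulons of the deleted
factors. Passing tests therefore demonstrate correctness of the
machinery and qualitative behavior (noise monotonicity, plateau of the
$k$ curve, the adaptive-neighborhood advantage), not real-data accuracy
levels.

## Numerical choices and problem sizes

* Exact-recovery tests use modules larger than $K$: when a module has
  fewer than $K{+}1$ members, a gene's top-$K$ list reaches outside its
  module and an outside candidate can out-degree module mates in the
  dense-subnet ranking — behavior of the heuristic, not a bug.
* Oracle-equivalence tests compare against loop-based brute-force
  reimplementations on 200 random instances of 26–60 genes, at
  tolerance 1e-12 (exact set-and-order equality for neighbor lists).
* Challenge-scale checks run the full 6000-gene preset: distance matrix
  once (~15 s), then 10-repeat holdout and an 8-point $k$ sweep; the
  whole suite stays within a couple of minutes on one core.
* Exact p-value enumeration is refused for $n > 10$ ($n!$ blow-up);
  Monte-Carlo agreement is asserted within 3 standard errors at
  $10^5$ draws.

## Known limitations

The dense-subnet degree count uses the undirected reading of the K-NN
graph; a directed in-edge count is a plausible alternative reading of
the original construction and can change selections on asymmetric
neighborhoods. The linear model fits each timepoint independently and
ignores residual correlation across timepoints. The evaluation's exact
null assumes untied ranks; with midrank ties it is an approximation.
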