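---
title: "Methods: binary reading-network construction, metrics and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binary reading-network construction, metrics and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

`readnet` asks whether the *manner* in which a child's reading network is
functionally connected — not just the strength of individual connections —
predicts reading skill. Starting from node-level fMRI time series recorded
during a rhyming-judgment task under three presentation modalities (VV:
both words visual; AV: first auditory, second visual; AA: both auditory),
the pipeline builds one binary undirected graph per run under each of two
thresholding schemes, summarizes each graph with two segregation measures
(modularity, transitivity) and one integration measure (global efficiency),
averages the two runs of each modality, bounds outliers at two standard
deviations, and regresses a standardized pseudo-word decoding efficiency
(PDE) score on the nine resulting subject-level predictors after adjusting
for age, task accuracy and response latency. A relative-importance
decomposition with bootstrap contrasts then asks which predictors carry the
explained variance.

## Network construction

**Adjacency.** Functional connectivity between nodes \(i\) and \(j\) is the
zero-lag Pearson correlation \(r_{ij}\) of their time series
(`correlation_matrix()`). Only zero-lag dependence is considered: with a
jittered fast event-related design, lagged estimates confound neural lag
with trial-onset scheduling. Per-node normalization (z-scoring) is a no-op
for Pearson correlation and is therefore not performed.

**Significance scheme.** `significance_threshold()` keeps edge \((i,j)\)
when the two-sided p-value of \(r_{ij}\) falls below \(\alpha = .05\)
(uncorrected), using the exact small-sample t transform
\[ t = r \sqrt{\frac{T - 2}{1 - r^2}} \sim t_{T-2} \quad\text{under } r = 0 .\]
Choices worth stating:

* The test is two-sided, so *negative* significant correlations produce
  edges. The binarization is defined by significance, not sign;
  `positive_only = TRUE` provides the sign-restricted variant for
  sensitivity analysis.
* \(|r| = 1\) is treated as \(p = 0\) (edge present), not as a numeric
  fault.
* At \(T = 202\) the implied inclusion boundary is \(|r|^* \approx 0.138\).

**Minimum connected component (MCC).** `mcc_threshold()` inserts
off-diagonal edges in descending weight order until the graph first forms a
single component spanning all nodes; the result is the sparsest
descending-weight spanning subgraph. Two conventions make the operation
deterministic and order-independent:

* Ranking uses the *signed* correlation (strongest positive coupling
  first). "Strongest" coupling in functional connectivity conventionally
  means strongest positive coupling; the significance scheme is two-sided,
  so the two schemes intentionally differ. `rank = "abs"` is available.
* All edges tied with the stopping weight are included (and the tie is
  logged), so the output cannot depend on node ordering. An all-tied weight
  matrix degenerates to the complete graph, with a logged notice.

## Graph measures

All measures operate on binary undirected graphs with the node set fixed by
the ROI definition — isolated nodes stay in the graph (they depress
efficiency and contribute no triplets).

**Modularity** (segregation): \(Q = \frac{1}{2m} \sum_{ij}
\left[a_{ij} - \gamma \frac{k_i k_j}{2m}\right] \delta(c_i, c_j)\),
maximized over partitions at resolution \(\gamma = 1\). The search is a
seeded greedy multi-level (Louvain) heuristic with 10 restarts (best Q
kept); the returned Q is always recomputed from the returned partition, so
the pair is exactly consistent. The heuristic can in principle return less
than the true optimum; on 8-node graphs it matches exhaustive search over
all set partitions on well over 95% of random instances (asserted in the
acceptance suite), and it never exceeds it. An edgeless graph has no
defined Q (\(2m = 0\)) and is a hard error.

**Transitivity** (segregation): \(\mathcal{T} = \sum_i 2 t_i / \sum_i
k_i (k_i - 1)\), the ratio of closed to all connected triplets, computed
via \(\mathrm{trace}(A^3)\). A graph with no node of degree 2 has no
triplets; 0 is returned by convention, with a logged note.

**Global efficiency** (integration): \(E = \frac{1}{n(n-1)}
\sum_{i \neq j} d_{ij}^{-1}\) with \(d_{ij}\) the breadth-first shortest
path length and \(d_{ij}^{-1} = 0\) for disconnected pairs — the standard
convention, and necessary because significance-thresholded networks may be
disconnected.

## Aggregation

Run-level values are averaged across the two runs of each modality
(`average_runs()`; missing runs are hard errors, not imputed). Outliers are
then replaced with the boundary value at mean ± 2 SD (`winsorize_metrics()`),
where mean and SD (sample, \(n-1\)) are computed *once from the
pre-replacement values* within each metric × modality × scheme column
across subjects. Per-column grouping is the default because each such
column is one regression predictor; pooled-across-modality grouping is
available (`group = "pooled"`).

## Inference

`fit_hierarchical()` fits two ordinary least-squares models: step 1
regresses PDE on the nuisance terms (age in months, response latency, task
accuracy); step 2 adds the nine connectivity predictors. The step-2
increment is tested with
\[ F = \frac{(R^2_2 - R^2_1)/q}{(1 - R^2_2)/\mathrm{df}_2}, \qquad
q = 9,\ \mathrm{df}_2 = n - 13 ,\]
which is verified in the tests against the residual-sum-of-squares
formulation and `anova()` to 1e-10. Coefficient tables report B, SE,
standardized \(\beta\), and — as the per-predictor association measure —
the *signed partial correlation* of the predictor with the outcome given
all other terms, with its square alongside. (The corresponding printed
column in reports of this design is signed and bounded by 1, a pattern
consistent with partial correlations rather than classical \(\eta^2\); the
package reports it under the neutral name `association`.)

**Relative importance.** `lmg_importance()` computes the LMG decomposition
exactly: the share of predictor \(k\) is its sequential \(R^2\) increment
averaged over all \(p!\) orderings, evaluated through the subset identity
\[ \mathrm{LMG}(k) = \sum_{S \subseteq P \setminus \{k\}}
\frac{|S|!\,(p - 1 - |S|)!}{p!}\left[R^2(S \cup \{k\}) - R^2(S)\right] ,\]
enumerating all \(2^p\) subsets (capped at \(p = 20\); no sampling
approximation). Shares are nonnegative and sum to the full-model \(R^2\)
(asserted to 1e-10). The decomposition uses the full 12-predictor model —
nuisance terms included, since excluding them would attribute their shared
variance to the connectivity block — while contrasts are taken only among
the nine connectivity predictors. Raw (sum-to-\(R^2\)) shares are
contrasted by default; normalized (sum-to-1) shares are available.

**Bootstrap contrasts.** `importance_contrasts()` resamples subjects with
replacement (B = 1000 by default), recomputes the exact LMG shares per
resample, and reports percentile 95% CIs for pairwise share differences in
two layouts: same metric across modalities, and same modality across
metrics. Rank-deficient resamples are redrawn and counted. A contrast is
flagged when its CI excludes zero; no multiple-testing correction is
applied, mirroring the analysis design.

## The synthetic cohort

`generate_cohort()` emulates the target study design: 24 subjects × 3
modalities × 2 runs, 43 nodes (154 for the outside-network replication),
202 time points per run (~6:45 at TR = 2 s). Each subject × modality gets a
block-structured correlation matrix: `within_r` inside each of 4 planted
communities (the reading network's four anatomical constituents), `between_r`
across them, plus N(0, 0.06) per-pair heterogeneity (about one sampling-error
unit at T = 202), PSD-repaired by eigenvalue clipping. Time points are
i.i.d. multivariate normal draws; an AR(1) knob exists for robustness checks
only, because zero-lag correlation is blind to temporal order. Every
(subject, modality, run) unit receives a deterministic sub-seed hashed from
the master seed, so generation is reproducible and order-stable.

Default parameter choices, made once:

* `within_r ~ U(0.45, 0.60)`: well above the T = 202 significance boundary,
  so planted modules survive thresholding; kept narrow so that the
  within-minus-between gap is dominated by between-module variation, which
  is what the thresholded graph can actually express.
* `between_r ~ U(0.05, 0.35)`: straddles the boundary \(|r|^* \approx
  0.138\), so cross-module connectivity — and hence segregation — varies
  across subjects and conditions. With these defaults the
  significance-scheme cohort means land near the reported ranges for this
  design (modularity ≈ 0.10, efficiency ≈ 0.88).
* Outcome: `PDE = 90.5 + 20 × (true AV modularity) + N(0, 5)`, where "true"
  metrics are computed by binarizing each noiseless generating matrix with
  the same significance rule (the pipeline applied to the structure itself).
  The intercept matches the standardized PDE cohort mean; beta and noise
  give a population \(R^2\) near 0.5. Age, accuracy and latency are drawn
  uniformly from the reported ranges (94–164 months, 0.51–0.85,
  900–1863 ms) with no planted outcome relation.

**What the generator does not emulate.** No hemodynamics, scanner noise, or
motion artifacts; no temporal autocorrelation by default. MCC networks of
this synthetic world are near-trees (continuous weights essentially never
tie, and connectivity is reached early), so their cohort metric means are
more extreme (higher modularity, lower efficiency) than in the real data,
where spanning connectivity is evidently reached later. A green synthetic
test therefore establishes the correctness and calibration of the
*machinery* — thresholding, measures, aggregation, inference — not that the
synthetic cohort is distributionally indistinguishable from study data.

## Identifiability and what "parameter recovery" asserts

Within one modality, the three binary-graph measures of this world are
near-deterministic functions of edge density: modularity and global
efficiency correlate at about −0.98 across subjects, and the variance
inflation factor of any one of them given its two companions exceeds 100 at
n = 24. The direction of any *single* coefficient inside that collinear
block is therefore not identifiable — empirically, the full-model sign of
the planted predictor is recovered only ~50–70% of the time even with a
noiseless outcome. The recovery acceptance test consequently runs the full
pipeline end to end and scores sign recovery on the identifiable estimand:
the planted metric's coefficient adjusted for the step-1 nuisance terms.
That is the quantity that tests what recovery is meant to test — that the
planted signal survives sampling, thresholding, metric computation,
averaging and winsorization with its direction intact — without asserting a
coefficient that no estimator could stabilize. The gap-coupling invariant
(subjects with larger planted within/between gaps recover higher
significance-scheme modularity, mean Spearman rank correlation > 0.8 across
seeds) is asserted as stated.

## Numerical conventions collected

* Degenerate inputs: zero-variance node — hard error naming the node;
  edgeless graph — hard error for modularity, 0 by convention for
  transitivity and efficiency; zero-SD winsorization group — unchanged,
  logged; rank-deficient design — hard error listing terms.
* PSD repair: smallest convex combination with the identity that clears the
  eigenvalue floor, recorded as `shrinkage`.
* Ties: MCC includes all edges tied with the stopping weight (logged);
  winsorization boundaries are closed intervals.
* Determinism: every stochastic step (sampling, modularity restarts,
  bootstrap) takes an explicit seed; sub-seeds are integer hashes below
  2^31; repeated pipeline execution with an identical config is
  bit-identical (asserted by checksum in the tests).

## Known limitations

* The MCC degenerate behaviors (complete-graph fallback under all-tied
  weights) are conventions for pathological inputs, not expected data.
* The exact LMG enumeration is \(O(2^p)\); at the design's p = 12 a single
  decomposition costs well under a second, but the hard cap is p = 20.
* The hierarchical regression is OLS with n = 24 and 12 predictors by
  design; estimates are reported, not regularized.
* Study-number reproduction requires the original deposited data
  (`inst/extdata/s1_file/README.md` documents the expected layout); it is
  not reproducible from synthetic data and is reported as unavailable in
  offline runs.
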