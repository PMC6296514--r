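# readnet

Graph-theoretic analysis of task-based functional connectivity in the
reading network, for researchers studying how the *pattern* of connectivity
— segregation and integration, not just connection strength — relates to
reading skill in children with reading difficulty.

Given node-level fMRI time series from a rhyming-judgment task run under
three presentation modalities (VV, AV, AA; two runs each), the package:

1. builds zero-lag Pearson correlation adjacency matrices per run;
2. binarizes them under two thresholding schemes — uncorrected significance
   of each correlation (two-sided t test, α = .05) and the **minimum
   connected component** (edges added in descending weight order until the
   graph first spans all nodes);
3. computes three binary-undirected measures per network: **modularity**
   *Q* = (1/2m) Σᵢⱼ [aᵢⱼ − γ kᵢkⱼ/2m] δ(cᵢ,cⱼ) (maximized over partitions,
   γ = 1), **transitivity** 𝒯 = Σᵢ 2tᵢ / Σᵢ kᵢ(kᵢ−1), and **global
   efficiency** E = (1/n(n−1)) Σᵢ≠ⱼ 1/dᵢⱼ (0 for disconnected pairs);
4. averages the two runs per modality and replaces outliers beyond
   mean ± 2 SD with the boundary value;
5. fits a two-step hierarchical OLS regression of pseudo-word decoding
   efficiency (PDE) on age, task accuracy and response latency (step 1)
   plus the nine connectivity predictors (step 2), testing the increment
   with the nested F statistic, and decomposes the explained variance with
   an exact LMG relative-importance analysis and bootstrap contrasts.

A synthetic-cohort generator with planted modular covariance
(`synth_config()` / `generate_cohort()`) emulates the full study design
(24 subjects × 3 modalities × 2 runs, 43 nodes, 202 time points), so every
stage is testable without access to the original data.

## Worked example

```r
library(readnet)

cfg <- pipeline_config(
  input  = "synthetic",
  synth  = synth_config(seed = 1),   # 24 x 3 x 2 runs, 43 nodes, T = 202
  metric_seed = 1, bootstrap_B = 1000, bootstrap_seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
<pipeline_result> 144 runs, 144 aggregated rows, schemes: significance, mcc
<hierarchical_fit> scheme = significance, n = 24
  step 1 (nuisance): F(3,20) = 0.37, p = 0.779, adjR2 = -0.090
  step 2 (+9 metrics): F(12,11) = 2.46, p = 0.074, adjR2 = 0.432
  increment: F(9,11) = 3.04, p = 0.043
<hierarchical_fit> scheme = mcc, n = 24
  step 1 (nuisance): F(3,20) = 0.37, p = 0.779, adjR2 = -0.090
  step 2 (+9 metrics): F(12,11) = 0.56, p = 0.834, adjR2 = -0.299
  increment: F(9,11) = 0.64, p = 0.742
```

Read: the nuisance-only model explains nothing (adjusted R² ≈ 0, as
expected — the generator plants no nuisance–outcome relation), while adding
the nine significance-scheme connectivity metrics yields a significant
increment (nested F(9,11) = 3.04, p = .043): the planted link from AV-
condition modularity to the PDE outcome survives the entire
threshold–measure–aggregate chain. The MCC scheme, whose near-tree networks
carry the planted signal less faithfully in this synthetic world, shows no
increment on this seed. `res$contrasts$significance` lists the 18 pairwise
LMG-share contrasts (same metric across modalities, same modality across
metrics) with bootstrap CIs.

For study-style data on disk (per-run `<subject>_<modality>_run<k>.tsv`
matrices plus `subjects.csv`), use `reproduce_study_analysis(data_dir)`;
`inst/extdata/s1_file/README.md` documents the expected layout.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch on the default
synthetic cohort under the given seed — generation, both thresholding
schemes, all metrics, aggregation, both hierarchical fits and the bootstrap
importance contrasts — printing the model summaries and writing the results
JSON to `--out`.
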