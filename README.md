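# oncomodules

Tumour cohorts are heterogeneous because different tumours run on
different *combinations* of perturbed signalling pathways. `oncomodules`
turns tumour-specific causal assignments between somatic genome
alterations (SGAs) and differentially expressed genes (DEGs) — a table of
`(tumour, SGA, DEG, posterior)` rows in which each DEG has exactly one
assigned cause per tumour — into:

1. **significant drivers** and SGA→DEG relationships, via four recurrence
   filtering standards (≥ 5 DEGs per tumour to call a driver; a driver in
   ≥ 30 tumours *and* ≥ 25% of its observed tumours; a relationship in
   ≥ 50 tumours *or* ≥ 20% of the SGA's driver tumours);
2. a weighted **DEG co-regulation network**, where the weight `W_ij` is
   the number of tumours in which DEGs *i* and *j* share an assigned SGA
   cause, with full per-edge provenance;
3. **DEG modules** by spectral consensus clustering: pseudo-distances
   `D_ij = 1/W_ij`, Gaussian affinities
   `A_ij = exp(-D_ij² / 2σ²)`, normalized-Laplacian embedding, seedable
   k-means repeated (default 100×) into a consensus matrix, and a
   stability-based (1 − PAC) choice of the module count;
4. **dominant drivers** per module (SGAs contributing > 10% of a module's
   internal co-regulation instances) and hypergeometric gene-set overlap;
5. **patient features**: per-module mean expression over the module's
   platform-effective DEGs, joined with clinical covariates, z-scored;
6. **patient subgroups** by PAM (k-medoids) consensus clustering with
   group count chosen from the consensus-CDF area (AUCDFC) and stability;
7. **survival evaluation**: Kaplan–Meier curves, multi-group log-rank
   tests, Cox proportional-hazards models (Efron ties) with Wald tests,
   and Harrell's concordance index.

A seedable synthetic-cohort generator with planted pathway structure
(archetypal activation profiles, interchangeable drivers, passenger SGAs,
module-dependent hazards) makes the whole pipeline testable without
access to restricted cohort data.

## Worked example

```r
library(oncomodules)

cohort <- generate_cohort(cohort_spec(), seed = 1)
res <- run_pipeline(cohort,
                    pipeline_config(module_runs = 30, group_ks = 2:8,
                                    group_resamples = 40),
                    seed = 1)

res$network
#> DEG co-regulation network: 200 nodes, 3900 edges, 141432 co-regulation instances

res$manifest$k_modules
#> [1] 5

head(res$dominance[res$dominance$dominant, ], 4)
#>   module    sga n_instances proportion dominant
#> 1      1 DRV5_2       14574  0.5072217     TRUE
#> 2      1 DRV5_1       14159  0.4927783     TRUE
#> 3      2 DRV3_1       14091  0.5503867     TRUE
#> 4      2 DRV3_2       11511  0.4496133     TRUE

res$groupings$all_features$k
#> [1] 4

res$survival$all_features$logrank$p_value
#> [1] 4.601245e-08

res$survival$all_features$cox$all$cindex
#> [1] 0.6648377
```

The five planted pathways come back as five modules whose dominant SGAs
are exactly the planted drivers (each pathway's two interchangeable
drivers split its co-regulation instances roughly in half). Patients fall
into four groups matching the planted mechanism archetypes, and the
groups differ strongly in survival (log-rank p ≈ 5 × 10⁻⁸); the pooled
Cox model ranks patient risk with C ≈ 0.66.

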