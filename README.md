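# vnet — social network inference for induced-cooperation field experiments

`vnet` is an R package for behavioural ecologists analysing how
experimentally induced cooperation restructures the social network of a
wild primate group. The design it targets splits a group into a
two-member **small cooperation class** and a **large class** (the rest
of the group); paired feeders release food only when members of both
classes operate them together, creating a matching market in which the
small-class members are the short side. From raw timestamped event logs
(scan samples and all-occurrence behavioural bouts) the package
computes:

* **Association networks** per condition — spatial proximity away from
  the feeders, affiliative interactions (allogrooming, contact sitting,
  play), and cooperation attempts — with simple-ratio indices
  α̂ᵢⱼ = xᵢⱼ/dᵢⱼ over per-day presence.
* **Social differentiation** S, the coefficient of variation of the
  latent association probabilities, via a moment estimator that removes
  binomial sampling variance:
  S² = max(0, [var_w(α̂) − mean(α̂(1−α̂)/d)]) / ᾱ², with bootstrap
  standard errors over sampling days.
* **Preferred/avoided association tests** against a presence-constrained
  ("semi-random") permutation null: each day's association slots are
  reshuffled only among the individuals present that day.
* **Mantel and partial Mantel tests** of partner choice (sex, age,
  rank, relatedness, and relatedness controlling for matriline and
  siblings), restricted to the between-class dyads through a mask and
  permuting labels within cooperation classes.
* **David's Score** dominance indices (DS = w + w₂ − l − l₂) from
  agonistic bouts near the feeders.
* **Ward-linkage dendrograms** (heights = within-cluster
  sum-of-squares increments) with cophenetic validation, and **Newman
  modularity** communities of the cooperation network.
* A **synthetic-data generator** with known ground truth (planted
  differentiation, rank-assortment strength β, pedigree-based
  relatedness) for power and calibration studies, and a one-command
  **pipeline** producing a differentiation table, permutation-test
  results, the Mantel grid, and structure outputs.

## Worked example

Simulate a 10-individual group observed over 30 days with
rank-assortative cooperation (β = 8), then analyse its cooperation
network:

```r
library(vnet)

cfg    <- sim_config(n_individuals = 10, n_periods = 30,
                     rank_assortment = 8, seed = 11)
bundle <- simulate_study(cfg)
net    <- cooperation_network(bundle$events, bundle$presence)

S  <- social_differentiation(net$occurrence)
se <- bootstrap_se(net$occurrence, social_differentiation,
                   n_boot = 1000, seed = 1)
sprintf("S = %.4f +/- %.4f (%s)", S, se, classify_differentiation(S))
#> "S = 2.1435 +/- 0.0772 (extreme)"
```

The cooperation network is far more differentiated than a homogeneous
society (S ≤ 0.3 would be homogeneous; beyond 2.0 is extreme): the
class design plus rank assortment concentrates events on few dyads. The
permutation test confirms the concentration is not a presence artefact:

```r
preferred_association_test(net$occurrence, n_perm = 1000, seed = 2)
#> <preferred/avoided association test> relabel engine, 1000 permutations
#>   statistic stat_real stat_null_mean stat_null_sd           p n_perm
#>  mean_index 0.2543121      0.2582952  0.001753421 0.008991009   1000
#>    sd_index 0.6575364      0.1621230  0.016899051 0.000999001   1000
```

The real SD of dyadic indices (0.66) dwarfs the null's (0.16), with p
at the floor 1/(n_perm+1) — individuals cooperate with preferred
partners. Is rank the driver? Compute David's Scores from the agonistic
bouts and run the masked, class-constrained Mantel test:

```r
ds <- davids_score(wins_from_log(bundle$events, bundle$roster))
mt <- mantel_test(net$matrix$values, rank_similarity(ds$ds)$values,
                  mask    = between_class_mask(bundle$roster)$values,
                  classes = setNames(bundle$roster$coop_class,
                                     bundle$roster$id),
                  n_perm = 1000, seed = 3)
mt
#> <Mantel test> Z = 244.5526, MCC = 0.793, p = 0.000999001
#>   (greater, 1000 permutations, 16 dyads)
```

Only the 2 × 8 between-class dyads enter; similar-rank partners
cooperate far more than the within-class permutation null allows.
Finally, the structure of the cooperation network:

```r
ward_dendrogram(net$matrix, normalise = net$occurrence$d)
#> <Ward dendrogram> 10 individuals, cophenetic 0.925 (good)
newman_communities(net$matrix)
#> <communities> 2 communities, Q = 0.4594
```

Two social units, each clumped around one small-class member — the
signature pattern of the matching market.

The same analysis runs end to end from files via the pipeline
(`run_pipeline(config)` with a YAML/list config) or the CLI
(`Rscript inst/cli/vnet.R run --config pipeline.yaml --out out/`),
producing `report.json`, `table1.csv` (differentiation table),
`table2.csv` (Mantel grid), Newick dendrograms, community CSVs and
GraphML networks — byte-identical across reruns with the same seed.

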