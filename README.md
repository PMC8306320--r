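# rivnet

Molecular-ecological-network analysis of riverine bacterioplankton
communities along human-disturbance gradients.

Rivers draining human-modified catchments carry microbial communities whose
co-occurrence structure — how many associations taxa maintain, how modular
the network is, which taxa act as keystones — shifts with land-use pressure.
`rivnet` packages the full analysis chain used in such studies, for
microbial ecologists working from OTU count tables:

- **HAILS**, the human activity intensity of land surface:
  `HAILS = 100% × Σ Sᵢ / S` over the directly human-influenced cover
  classes (farmland + urban by default), with tertile or fixed-threshold
  classification of sub-basins into low/middle/high-intensity reaches.
- **Ensemble co-occurrence networks**: per reach × season, all taxon pairs
  are scored with Spearman, Pearson, Bray–Curtis and symmetrized
  Kullback–Leibler measures; permutation p-values (add-one estimator) get
  per-measure Benjamini–Hochberg FDR control, and an edge needs
  |r| > 0.8, q ≤ 0.05 and ≥ 2 direction-concordant significant measures.
- **Topology**: the standard 13-index summary (total nodes/links,
  negative:positive ratio, power-law R², average degree, clustering
  coefficient, path distance, degree centralization, density, modularity,
  module count), plus a checker that verifies printed index tables against
  the exact identities `TL = NL + PL`, `avgK = 2TL/TN`,
  `GD = avgK/(TN−1)` and flags inconsistent cells.
- **Modules and keystones**: deterministic greedy modularity maximization;
  within-module degree z-score and participation coefficient with the
  zi > 2.5 / pi > 0.62 role scheme (network hubs, module hubs, connectors,
  peripherals); module composition profiles and cross-network shared-node
  (Venn) statistics.
- **Sloan neutral community model**: immigration rate `m` and fit `R²`
  from occurrence frequency vs mean relative abundance, with an exact
  read-sampling (beta-binomial) detection model as default and the
  classical sharp detection limit as an option.
- **Environment statistics**: Shapiro–Wilk screening with log
  transformation, Pearson correlation tables with pairwise deletion,
  keystone-taxa × water-chemistry bipartite networks, one-way ANOVA with
  Fisher's LSD post hoc tests.
- **Synthetic data with known truth** for every stage: planted correlation
  blocks (copula-calibrated Spearman), neutral communities with known `m`,
  environment variables tied to planted blocks, land-use gradients.

## Worked example

```r
library(rivnet)

cfg <- demo_config(output_dir = "demo_run", seed = 1)   # bundled synthetic study
res <- run_pipeline(cfg)

res$topology
#>       group TN TL NL PL         NP         R     avgK     avgCC      APD
#> 1 lower_wet 17 49  6 43 0.13953488 0.8919933 5.764706 0.8655462 1.020000
#> 2 upper_wet 15 39  2 37 0.05405405 0.3614815 5.200000 0.8952381 1.204082
#>          CD        GD         M NM
#> 1 0.0875000 0.3602941 0.5122865  3
#> 2 0.1483516 0.3714286 0.4917817  2

res$ncm
#>       group         m         R2  N_T n_taxa
#> 1 upper_wet 0.0698614 0.29392885 5000     40
#> 2 lower_wet 0.2868867 0.01872868 5000     40
```

The demo simulates two river reaches, each with two planted 8-taxon
correlation blocks. The inferred networks consist almost entirely of the
planted taxa (15–17 nodes of the 16 planted per group, dense positive
intra-block structure with the planted negative pairs as negative links),
every retained edge satisfies the strong-correlation and FDR rules, and
module detection splits each network along the planted blocks. The low
neutral-model `R²` values are the expected signature of these deliberately
structured communities — deterministically co-varying taxa do not follow
the neutral occurrence-frequency curve. `run_pipeline()` writes the
networks (edge-list TSV and GraphML), role and topology tables, HAILS
classification, correlation tables and a manifest recording every seed,
parameter and output-file hash; rerunning the same configuration reproduces
the bundle byte for byte.

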