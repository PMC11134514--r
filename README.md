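# taskhardness

**How hard will a low-data bioactivity-prediction task be, given the source
assays you already have?**

Few-shot and meta-learning methods (prototypical networks and relatives)
can rescue protein targets with only a handful of labeled molecules — but
only when the source-task collection actually contains transferable
knowledge. `taskhardness` quantifies, before any meta-learning is run, the
hardness of each target task as the sum of three independently normalized
components:

* **EXT_CHEM** — external chemical-space hardness: the optimal transport
  dataset distance (OTDD) between the target's labeled molecules and each
  source task's, aggregated over the *k* nearest sources (difficulty-
  weighted by default). The OTDD ground cost between feature–label pairs is

  `c((x, y), (x', y')) = ||x − x'||² + W₂(α_y, α_{y'})²`,

  where `α_y` is the Gaussian model of the features carrying label `y` and
  `W₂` is the closed-form (Bures) 2-Wasserstein distance between Gaussians.
* **EXT_PROT** — external protein-space hardness: Euclidean (or cosine)
  distance between protein embeddings, aggregated over the *k* nearest
  sources; protein complexes score as their most distant member.
* **INT_CHEM** — internal hardness: `1 − ROC-AUC` of a random forest (or
  k-NN) trained on only `m_train ∈ {16, 32, 64}` of the target's own
  molecules.

Each component is min-max normalized across the run's target tasks and
combined as `w_chem·EXT_CHEM + w_prot·EXT_PROT + w_int·INT_CHEM` (equal
weights by default). The package validates the metric on synthetic task
universes with planted relatedness: combined hardness anti-correlates with
the performance gain of a prototypical network over a single-task baseline,
and rationally selected source tasks beat random selections.

The package includes its own exact (transportation-simplex) and entropic
(log-domain Sinkhorn) discrete optimal-transport solvers, a desk-scale
prototypical network, and a seeded synthetic-universe generator so the
entire pipeline runs and is testable with no downloads.

## Worked example

Generate a small universe with planted relatedness (per-target
`rho ∈ {0, 0.25, 0.5, 0.75, 1}`; `rho = 1` targets have designated source
tasks sharing their chemistry and protein anchors), compute both distance
matrices, and combine the three components:

```r
library(taskhardness)

universe <- generate_universe(universe_config(
  n_sources = 12, n_targets = 5, chem_dim = 8, prot_dim = 8,
  n_molecules = 60, k_related = 2, seed = 7))

sources <- lapply(universe$sources, featurize_molecules, featurizer = "loaded")
targets <- lapply(universe$targets, featurize_molecules, featurizer = "loaded")

chem   <- chem_distance_matrix(sources, targets)      # OTDD, exact solver
prot   <- prot_distance_matrix(universe$sources, universe$targets)
report <- compute_hardness(chem, prot, targets, sources,
                           hardness_config(k = 3))
report[, c("task_id", "ext_chem_norm", "ext_prot_norm",
           "int_chem_norm", "combined")]
#>   task_id ext_chem_norm ext_prot_norm int_chem_norm combined
#> 1  TGT001         0.712        1.0000         0.326    2.038
#> 2  TGT002         1.000        0.8930         0.744    2.637
#> 3  TGT003         0.450        0.2684         0.000    0.718
#> 4  TGT004         0.193        0.0618         0.481    0.736
#> 5  TGT005         0.000        0.0000         1.000    1.000
```

The planted relatedness of the five targets is `0, 0.25, 0.5, 0.75, 1`,
and hardness recovers it (more related ⇒ easier externally):

```r
rho <- vapply(universe$truth, `[[`, numeric(1), "rho")
cor(rho, report$combined)
#> [1] -0.726
```

Hardness also drives rational source-task selection — for the fully
related target the top-ranked sources are exactly its designated ones:

```r
select_source_tasks("TGT005", chem, prot, k = 3)
#> [1] "SRC005" "SRC006" "SRC011"
universe$truth$TGT005$related_sources
#> [1] "SRC005" "SRC006"
```

`run_pipeline()` wires all stages (simulate/load → featurize → distances →
hardness → prototypical-network evaluation → hardness-gain correlation)
with per-stage caching, and `inst/cli/taskhard` exposes the same stages as
shell subcommands (`simulate`, `chem-distance`, `prot-distance`,
`hardness`, `select-sources`, `pipeline`).

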