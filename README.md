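# actflowsel

Activity-flow mapping of visual category selectivity: a generative,
network-based account of how localized, category-selective brain responses
(to bodies, faces, places, and tools) can arise from distributed activity
flowing over intrinsic functional connectivity.

The package is written for systems/cognitive neuroscientists who want to
test distributed-versus-local accounts of functional selectivity with a
fully specified synthetic ground truth: every analysis stage — connectivity
estimation, activity-flow mapping, selectivity statistics, network
decomposition, null models, permutation inference — is implemented as a
tested function, and a simulation generator produces data in which the true
distributed fraction of each response is known and recoverable.

## The model

Activity-flow mapping treats a held-out target region *j*'s task activation
as the connectivity-weighted sum of all other regions' activations:

    mapped_j = Σ_{i ≠ j} a_i · w_ij

where `a_i` is region *i*'s task-evoked activation (GLM beta) and `w_ij` the
resting-state connectivity between *i* and *j*. Connectivity is estimated by
the three-stage **combinedFC** procedure (partial-correlation skeleton →
bivariate-correlation collider pruning → per-target multiple regression), or
by cross-validated L1-regularized regression at the vertex level.

Category selectivity is the ratio of mean min-max-normalized responses to a
category's conditions over the mean response to the other categories'
conditions (1.0 = no selectivity), and the **distributed contribution** is
100 × mapped / actual selectivity — the share of observed selectivity that
distributed network interactions alone reproduce. Networks are ranked by
dominance analysis (partial R² over all 4095 candidate predictor subsets for
12 networks), and inference uses max-T permutation testing. Null models
substitute connectivity fingerprints between complexes or rewire the graph
while preserving degrees and edge-weight multisets.

## Worked example

The `analysis/` directory holds the study workflow as numbered drivers
(simulate → GLM → connectivity → activity flow → selectivity → networks and
nulls). Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/05_selectivity.R
```

simulates 20 participants (60 regions, 12 networks, four two-unit functional
complexes, 24 task conditions, generative local fraction 0.25) and prints,
for independent discovery/replication halves:

```
[discovery] group means (outliers removed):
 complex   actual   mapped contribution_pct
    body 2.703835 2.021499         74.76547
    face 2.083589 1.564201         75.02935
   place 2.003729 1.529450         76.27290
    tool 2.291765 1.731232         75.52052
max-T: all mapped selectivities > 1.0 corrected p <= 0.001499; ...

local_fraction sweep (expected contribution = 100*(1-lf)):
  lf = 0.00 -> mean contribution 99.9%
  lf = 0.25 -> mean contribution 74.9%
  lf = 0.50 -> mean contribution 50.0%
  lf = 0.75 -> mean contribution 25.0%
```

Reading: each complex is selective for its category (actual ratio well above
the 1.0 null), the connectivity-based mapping reproduces most of that
selectivity (mapped ratio), and the contribution percentage recovers the
simulated distributed share (75% here) — the quantity the analysis is built
to estimate. In equivalent minimal code:

```r
library(actflowsel)
cfg   <- sim_config(seed = 20, local_fraction = 0.25, n_participants = 20)
model <- generate_ground_truth(cfg)
rest  <- simulate_rest(model, cfg)
task  <- simulate_task(model, cfg)
betas <- estimate_betas(task$task_bold[[1]], task$design_matrix)
fc    <- combinedfc(rest[[1]])
mapped <- map_activity(betas, fc, targets = complex_units(model))$mapped
```

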