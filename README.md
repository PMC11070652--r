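# shellscore

Scoring protein–ligand docking poses by predicting their RMSD to the
native binding mode with a shell-graph transformer.

## The problem

Docking samplers generate dozens of candidate placements ("poses") of a
small molecule in a protein pocket; picking the near-native ones (RMSD
< 2 Å to the crystallographic pose) is the job of the scoring function.
`shellscore` treats scoring as regression: it predicts each pose's
heavy-atom RMSD — computed in the common frame, no re-superposition,
optionally minimised over the ligand's graph automorphisms — and ranks
poses by the prediction.

## The model

The binding interface is sliced into *n* concentric shells centred on the
whole ligand: a protein atom belongs to shell *k* when its distance *r* to
the nearest ligand atom falls in `(d0 + (k-2)·d, d0 + (k-1)·d]`. Each
shell becomes a graph over all ligand atoms plus that shell's protein
atoms: ligand bonds are edges with a fixed distance feature of 1,
protein–ligand contacts inside the shell's band are "Non-covalent" edges
whose distance feature is the band's outer boundary (DistMax), and no
protein–protein edges exist. Nodes carry 171-dimensional one-hot features
(protein atoms use the leading 97 dimensions, ligand atoms the trailing
74); edges carry a 7-way category plus the distance, 8 dimensions in all.

Each shell graph is encoded by its own graph transformer whose attention
scores are biased by the graph topology,

```
A_ij = (h_i W_Q)(h_j W_K)^T / sqrt(d) + b_phi(i,j) + c_ij ,
```

where `b_phi(i,j)` is a learnable scalar per attention head indexed by the
Floyd–Warshall shortest-path hop count between nodes *i* and *j*
(truncated at `hop_max`, with a dedicated slot for unreachable pairs,
marked −1), and `c_ij = (1/N) Σ_p <x_{e_p}, w_p>` averages learnable
projections of the edge features along one shortest path. Degree
(centrality) encoding is deliberately omitted. Per-shell 128-dimensional
embeddings are concatenated (1280 values at ten shells) and regressed onto
RMSD by an MLP with a softplus output; a pose whose shells contain no
protein atom at all scores `+Inf` (the ligand has left the site).

Training minimises the MSE with AdamW at initial learning rate 0.001,
halved every 25 epochs, early stopping after 25 non-improving validation
epochs, a 150-epoch cap, best-checkpoint selection, and a four-part
complex-disjoint ensemble reported as mean ± sd. Forward and backward
passes are hand-written base-R matrix algebra, finite-difference-verified
and bit-reproducible under a fixed seed.

Evaluation covers RMSE, Pearson and Spearman correlation, docking power
(`m(k)/M`), hit rate (`mean h(k)/P`), enrichment factor
(`mean h(k)/(P·α(k))`, 1 ≈ random) and the Jensen–Shannon divergence
(base-2, in [0, 1]) between binned RMSD distributions.

## Worked example

Synthetic complexes with analytically exact labels (decoys are rigid
translations of the native ligand, so a translation by `t` has RMSD
exactly `|t|`) let the whole pipeline run in minutes on one CPU:

```r
library(shellscore)

# 1. the synthetic docking study: 10 complexes x (20 decoys + 4 natives)
poses <- make_learnable_dataset(seed = 1)
length(poses)
#> [1] 240

# 2. a reduced two-shell model trained with the step-halved AdamW recipe
cfg <- gs_config(layout = shell_layout(d0 = 3, d = 3, n_shells = 2),
                 d_hidden = 32, n_heads = 4, n_layers = 1, d_ff = 64,
                 head_widths = c(32, 16), readout = "mean", seed = 1)
cids <- vapply(poses, function(p) p$complex_id, "")
val_ids <- c("cplx_09", "cplx_10")
model <- train_model(train = poses[!(cids %in% val_ids)],
                     validation = poses[cids %in% val_ids],
                     config = cfg)
model
#> shell-graph scoring model: 2 shells, 1 layers x 4 heads, d_hidden 32, embedding 128 (concat 256)
#> trained 70 epochs (best val loss 0.2825)

# 3. score the two held-out complexes and evaluate the ranking
rk <- predict_poses(poses[cids %in% val_ids], model)
head(rk, 3)
#>   complex_id          pose_id     score rmsd
#> 1    cplx_09 cplx_09_pose_001 0.7914126    0
#> 2    cplx_09 cplx_09_pose_002 0.7914126    0
#> 3    cplx_09 cplx_09_pose_003 0.7914126    0
evaluate_rankings(rk, k_top = 1, k_hit = 5)
#> evaluation of 48 poses / 2 complexes (near-native < 2.0 A):
#>   RMSE 0.532 | Pearson 0.836 | Spearman 0.779
#>   docking power (k=1) 1.000 | hit rate (k=5) 0.279 | EF 1.337
```

Reading the numbers: training stopped after 70 epochs (patience 25 on the
validation loss); on 48 held-out poses from two unseen complexes the
predicted RMSDs track the true ones at Pearson r = 0.84 with RMSE 0.53 Å,
the top-scored pose of every held-out complex is near-native (docking
power 1.0 at k = 1), and inspecting the 5 best-scored of 24 poses recovers
28% of each complex's near-native set — an enrichment of 1.34 over random
inspection. The replicated native poses share one score because they are
identical conformations.

A thin command-line interface over the same functions lives at
`inst/cli/shellscore.R` (`make-fixtures`, `featurize`, `train`, `score`,
`evaluate`), writing its configuration next to every artifact.

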