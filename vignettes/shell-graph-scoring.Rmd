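---
title: "Shell-graph transformer scoring of docking poses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell-graph transformer scoring of docking poses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellscore)
```

## The problem

A docking sampler produces tens of candidate placements ("poses") of a small
molecule in a protein binding site; a scoring function must rank them so
that near-native poses (those within 2 Å RMSD of the experimentally
determined binding mode) come out on top. `shellscore` approaches this as a
regression problem: predict each pose's heavy-atom RMSD to the native ligand
directly, then rank by the prediction. RMSD here is the docking convention —
computed in the common coordinate frame with no re-superposition, optionally
minimised over the ligand's graph automorphisms so chemically equivalent
atoms (e.g. the two ortho carbons of a phenyl ring) can swap without
penalty.

## Shell graphs

The binding interface is partitioned into `n` concentric shells centred on
the *whole ligand*: the shell of a protein atom is determined by its
distance `r` to the nearest ligand atom, with shell `k` covering the
half-open band `(d0 + (k-2)·d, d0 + (k-1)·d]` (shell 1 covers `(0, d0]`).
Because the centre is the whole molecule rather than a single atom, shells
are irregular surfaces that follow the ligand's shape. Defaults are
`d0 = 3` Å, `d = 1` Å and `n = 10` shells (outer boundary 12 Å, covering
the usual non-covalent interaction range); all three are configurable and
the boundary values themselves are not printed constants of the method.

Each shell becomes one graph: the nodes are **all** ligand atoms plus the
protein atoms assigned to that shell. Ligand covalent bonds are edges whose
distance feature is fixed at 1; every protein–ligand atom pair whose
Euclidean distance falls inside the shell's band becomes a "Non-covalent"
edge whose distance feature is the band's *outer* boundary (DistMax), not
the raw distance — the model is told which distance regime a contact
belongs to rather than its exact geometry. No protein–protein edges exist,
which keeps the graphs bipartite apart from the ligand's own bond skeleton
and concentrates attention on cross-interface dependencies. A protein atom's
defining contact (the nearest ligand atom) always lies inside its own
shell's band, so every protein node touches the ligand. Using the same
half-open band for membership and for edge creation is a deliberate choice:
it makes membership and connectivity consistent by construction.

If *no* protein atom falls inside any shell, the ligand has left the
binding site entirely; such "dissociated" poses short-circuit to a predicted
RMSD of `+Inf` and rank last.

## Node and edge features

Nodes are 171-dimensional one-hot block vectors: protein atoms populate the
leading 97 dimensions (atom type 7, degree 10, implicit valence 6,
neighbouring hydrogens 6, hybridization 9, amino-acid type 22, PDB atom
name 37), ligand atoms the trailing 74 (atom type 7, degree 10, implicit
valence 6, neighbouring hydrogens 6, hybridization 9, formal charge 22,
ring size 12, aromaticity 2); the complementary block is zero-padded so the
two roles can never be confused. Edges are 8-dimensional: a 7-way category
(Single, Double, Triple, Aromatic, Non-covalent, Other, Unknown) plus the
distance feature described above.

Two conventions deserve comment:

* **OTHER-as-zeros for atom types.** Protein atom types are H, C, N, O, P,
  S and metal (Ca, Fe, K, Mg, Mn, Na, Zn); ligand types replace the metal
  category with halogen (F, Cl, Br, I). The residual "other" category has
  no slot of its own — an element outside the named sets encodes as
  all-zeros in that block. Widths of 7 are what make the 97/74/171 layout
  add up; a one-hot block that can be all-zero is equivalent to a (width+1)
  block with the last slot dropped.
* **Block vocabularies.** The block widths are fixed, but the category
  membership behind each width is a modelling choice: degrees 0–8 plus
  OTHER, implicit valences and hydrogen counts 0–4 plus OTHER, nine
  hybridization states, the 20 standard amino acids plus a non-standard
  slot plus OTHER, the 36 most common PDB atom names, formal charges −10 to
  +10 plus OTHER, and ring sizes none/3–10/OTHER (two reserved zero slots
  keep the printed width of 12). All vocabularies live in one
  `feature_schema()` object so they can be revised without touching the
  encoders.

Derived atom properties are computed from the bond graph. For ligands,
implicit valence is the gap between the (charge-adjusted) standard valence
and the bond-order sum, attached hydrogens add implicit hydrogens to
explicit H neighbours, hybridization follows aromatic > SP (triple or two
doubles) > SP2 (double) > SP3, and an atom's ring size is the largest ring
containing it among the shortest cycles through each bond (rings above 10
atoms collapse to OTHER). Protein files carry no bond orders, so protein
bonds are perceived from covalent radii (cutoff `r1 + r2 + 0.4` Å, metals
excluded) and hybridization comes from residue templates (backbone
carbonyl/amide atoms SP2, aromatic side-chain rings, carboxylates and
guanidinium SP2, everything else SP3). Hydrogens are used when present in
the input but never added; protonation is out of scope.

## The encoder

Each shell graph is encoded by its own graph-transformer stack (weights are
not shared between shells: each shell observes a different molecular
environment). Attention scores between nodes i and j are

```
A_ij = (h_i W_Q)(h_j W_K)^T / sqrt(d) + b_phi(i,j) + c_ij
```

* **Spatial encoding** `b_phi(i,j)`: one learnable scalar per attention head
  per shortest-path hop count, computed over the unweighted graph with
  Floyd–Warshall. Hops are truncated at `hop_max` (default 5) and
  unreachable pairs get the sentinel value −1, which owns its own table
  slot. The table is shared across the layers of one encoder.
* **Edge encoding** `c_ij`: the mean over the path positions of the dot
  product between each edge's 8-dimensional feature vector and a learnable
  position-indexed weight vector. Paths longer than `hop_max` are truncated
  to their first `hop_max` edges. Shortest paths are reconstructed
  deterministically (breadth-first search processed in increasing node id,
  so ties resolve toward the smallest intermediate id) — attention biases
  are therefore reproducible, at the cost that rebuilding a graph from a
  permuted atom order may legitimately pick a different equal-length path.
  Self pairs and unreachable pairs contribute `c = 0`. The raw distance
  feature (1 for ligand bonds up to the outer shell radius for contacts)
  enters unscaled; its range is bounded by the layout.
* **Centrality (degree) encoding is deliberately absent** — in ablation it
  does not help this task and can hurt.

After the biased multi-head attention, each layer applies the output
projection, a residual connection, layer normalisation, a two-layer
feed-forward block, and a second residual + normalisation (post-LN
ordering). A virtual readout node rides along in every graph with zero bias
slots toward all atoms; the embedding of a shell is either that node's
final representation (`readout = "cls"`) or the mean over the atom rows
(`readout = "mean"`), projected to 128 dimensions. The projection width 128
is an architectural constant; with ten shells the concatenated pose vector
has length 1280.

The concatenated embeddings pass through a ReLU MLP (default widths
256 → 64 at full scale) to a single scalar, mapped through softplus so the
predicted RMSD is non-negative.

## Training recipe

The loss is the mean squared error between predicted and true RMSD.
Optimisation uses AdamW (β₁ = 0.9, β₂ = 0.999, decoupled weight decay 0.01
— applied to weight matrices only; biases, layer-norm parameters and the
learnable attention-bias scalars are exempt, the usual transformer
convention) with an initial learning rate of 0.001 halved every
`STEP = 25` epochs. Training stops at 150 epochs or as soon as the
validation loss has failed to improve by at least `1e-4` for `STEP`
consecutive epochs ("the loss" in the early-stopping rule is read as the
*validation* loss: monitoring the training loss would defeat the
best-checkpoint selection); the parameters returned are those of the epoch
with the lowest validation loss. For ensemble training the labelled
complexes are split into four parts — poses of one complex never straddle
parts — each member trains on one part and validates on a randomly chosen
other part, and evaluation metrics are reported as mean ± standard
deviation across the four members. So that every part contains native
conformations, the native pose of each complex is replicated four times in
the dataset.

The forward and backward passes are hand-written dense matrix algebra in
double precision (R has no single-precision numeric type); gradient
correctness is pinned against central finite differences in the test suite,
and training is bit-reproducible under a fixed configuration seed.

Two initialisation conventions stabilise the narrow desk-scale models:
hidden ReLU layers of the regression head start with small positive biases
(0.01), and the output bias is warm-started to the softplus-inverse of the
mean training label. Without these, a narrow head occasionally initialises
all-dead and training collapses.

## Evaluation metrics

Rankings sort ascending by predicted RMSD with stable tie order (`+Inf`
scores last). With near-native defined as true RMSD < 2 Å (strict,
configurable):

* **Docking power** (top-k, default k = 1): fraction of complexes with at
  least one near-native pose among the k best-scored.
* **Hit rate** (default k = 10): per complex, near-natives in the top k
  over near-natives overall, averaged over complexes; complexes without any
  near-native pose are excluded and reported.
* **Enrichment factor**: hit rate divided by the fraction of poses
  inspected, `alpha(k) = k / n_poses`; random ranking gives 1 in
  expectation.
* **RMSE / Pearson / Spearman** between predicted and true RMSD.
* **Jensen–Shannon divergence** (base-2 logarithms, hence bounded by
  `[0, 1]`) between binned RMSD distributions of two pose sets, restricted
  to a stated range such as < 2 Å or < 10 Å.

All ranking metrics are rank-based and therefore invariant under strictly
monotone transforms of the scores. The default k values (1 for docking
power, 10 for hit rate/EF) are package choices; the metrics are reported
together with the k used.

## Synthetic data: what it emulates and what it does not

The fixture generator builds toy complexes — the template ligand (an
aromatic six-ring with a carbonyl tail, eight heavy atoms) at the origin,
protein atoms with standard residue/atom-name context placed along random
directions at controlled nearest-ligand distances — and decoy sets created
by *rigid translation* of the native ligand. A whole-molecule translation
by `t` has RMSD exactly `|t|`, so fixture labels are analytically exact and
independent of any RMSD implementation; that is the entire point of using
translations rather than physically realistic torsional decoys. The
learnable dataset (10 complexes × 20 decoys + 4 replicated natives = 240
poses, 60 protein atoms per pocket at radii drawn from 2.5–5.5 Å, decoy
RMSDs uniform on (0, 3] Å) makes shell occupancy shift monotonically with
the displacement magnitude, so the shell-graph features demonstrably carry
the label signal.

Desk-scale training uses a reduced model — 2 shells with `d0 = 3`,
`d = 3` Å (two bands covering the 0–6 Å contact range), 1 layer, hidden
width 32, head widths 32/16, mean-pooling readout — and the full training
recipe. Under these conditions the trained model reaches a training MSE
below 0.25 Å² and a validation Pearson correlation above 0.8 on two
held-out complexes (the test suite computes both). The validation
correlation sits close to that bound by construction of the conditions:
across RNG seeds it varies by roughly ±0.05, which is worth knowing when
re-running the suite with modified settings.

Passing these tests shows that the architecture, biases, recipe and
metrics are implemented coherently and that the model can extract a
geometric signal from shell graphs. It does **not** show that the method
reaches publication-scale accuracy on real docking data: that requires
training on hundreds of thousands of sampled poses from thousands of real
complexes, with torsional decoys, symmetry-corrected labels and held-out
benchmark sets — all outside this package's scope.

## Numerical and degenerate-input choices

* Shell membership and edge creation both use half-open `(lower, upper]`
  intervals; a distance exactly on a boundary belongs to the inner shell.
* `phi(i, i) = 0` uses its own spatial-bias slot; self pairs and
  unreachable pairs contribute zero edge bias.
* Softmax rows are computed with max-subtraction; layer norm uses
  `eps = 1e-5`.
* A shell graph with zero protein atoms is still encoded (ligand-only
  graph); only the *all-shells-empty* case short-circuits to `+Inf`.
* Mol2 charge columns hold partial charges; formal charges are taken as
  their rounded values (integer for the files this package reads and
  writes). SDF formal charges come from `M  CHG` lines.
* Alternate locations in PDB files: only blank or 'A' records are kept,
  giving a deterministic single conformer. Waters (HOH/WAT/DOD) are always
  removed.
* The curation rotatable-bond cap defaults to 20 and the covalent-contact
  cutoff to 1.8 Å between non-metal heavy atoms; both are configurable
  because no canonical values exist.

## Known limitations

* Ring perception uses shortest cycles through each bond — exact for the
  5–60-atom ligands in scope, but not a full smallest-set-of-smallest-rings
  treatment of dense fused cages.
* Protein hybridization is template-based; exotic co-factors fall back to
  UNSPECIFIED/OTHER categories.
* Automorphism enumeration caps at 10⁴ mappings; pathological symmetric
  molecules beyond that are truncated with a warning.
* Training is CPU-bound R matrix algebra: fine for desk-scale models,
  orders of magnitude away from GPU training on full docking datasets.
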