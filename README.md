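# nmdn

Normalized mixture density network (NMDN) scoring of protein–ligand
binding poses, with a companion interaction module that predicts binding
affinity (pKd), in pure R.

## The problem and the model

Docking pipelines produce many candidate poses per protein–ligand pair;
scoring must pick the native-like pose and rank ligands for screening.
`nmdn` scores a pose through the distances between protein residues and
ligand atoms. For every residue *i* and ligand atom *j* within 9 Å, a
mixture density network predicts a Gaussian mixture over the
residue–atom minimum distance,

    p_ij(r) = Σ_n ρ_ij,n · N(r | μ_ij,n, σ_ij,n),

from the concatenated residue and atom embeddings (a 5-layer MLP with
batch normalization, ReLU and dropout; three readouts give ρ via
softmax, μ, and σ via softplus with a 0.01 Å floor). Training minimizes
the negative log density at the observed distance, −ln p_ij(d_ij),
summed over all pairs within the training cutoff (metal–ligand pairs get
their own head).

A raw likelihood rewards predictable distances, not favorable ones, so
the pose score normalizes against a reference probability near the
cutoff, in the manner of a statistical potential:

    p_ref_ij   = (1/6) Σ p_ij(r),  r ∈ {8.5, 8.6, …, 9.0} Å
    NMDN score = Σ_pairs [ ln p_ij(d_ij) − ln p_ref_ij ]

The interaction module predicts affinity from the same pairs: each
distance is expanded in 64 radial basis functions on e^(−d) under a
quintic smooth cutoff (d* = 10 Å); shifted-softplus + linear branches of
the two embeddings and the distance branch combine by Hadamard product
into a 128-d gated vector; concatenated with a 64-d RBF expansion of the
ligand's MMFF-strain RMSD (192-d total) it reads out the pair
contribution, and

    pKd = Σ PL_ij + Σ ML_kj + α_gw·ΔG_gas→water + α_wo·ΔG_oct→water,

with the solvation coefficients averaged from pairwise readouts. A
weak-binder hinge variant, max(pred − label − 1, 0), fine-tunes the
interaction module for screening. Enrichment factors, docking success
rates, ranking correlations, symmetry-aware ligand RMSD and the combined
two-score top-1% selection complete the evaluation stack. Everything
trains through a built-in reverse-mode autodiff engine — no external
deep-learning framework is needed.

## Worked example

Train a small head on distances drawn from known per-class mixtures,
then score a native-like pose against a decoy:

```r
library(nmdn)

classes <- list(
  "A:C" = mixture_density(c(0.6, 0.4), c(3.0, 6.0), c(0.4, 0.7)),
  "G:O" = mixture_density(c(0.3, 0.7), c(2.5, 5.0), c(0.3, 0.9)))
samp <- gen_mixture_distances(classes, 2000, seed = 7)

enc <- baseline_encoder(seed = 5)
X <- cbind(enc$aa_table[samp$aa, ], enc$elem_table[samp$element, ])
head <- new_mdn_head(128, hidden = 64, n_layers = 5, n_components = 5, seed = 3)
head <- fit_mdn_head(head, X, samp$d, epochs = 6, batch_size = 256,
                     lr = 2e-3, seed = 3)

model <- nmdn_model(encoder = enc, hidden = 64, n_components = 5, seed = 3)
model$pl_head <- head

native <- gen_paired_complex(c("A","G","A"), c("C","O","C"),
                             c(3.1, 5.2, 2.8), pose_id = "native-like")
decoy  <- gen_paired_complex(c("A","G","A"), c("C","O","C"),
                             c(8.4, 1.2, 8.8), pose_id = "decoy")
predict(model, native, type = "nmdn")
#> <nmdn score 'native-like': total 18.5489 (PL 18.5489 over 3 pairs, ML 0.0000 over 0 pairs)>
predict(model, decoy, type = "nmdn")
#> <nmdn score 'decoy': total 1.3182 (PL 1.3182 over 3 pairs, ML 0.0000 over 0 pairs)>
```

The native-like pose — whose distances sit where the class mixtures put
their mass — scores far above the decoy. The learned per-class mixture
is inspectable directly:

```r
pair_mixture(enc$aa_table["A", ], enc$elem_table["C", ], head)
#> learned weights: 0.012 0.589 0.165 0.216 0.017
#> learned means:   2.78 2.97 6.20 5.91 6.26
#> learned sigmas:  1.13 0.43 0.68 0.64 1.17
```

(the planted "A:C" truth was weights 0.6/0.4 at means 3.0/6.0 — the five
learned components collapse onto those two modes.)

Real structures enter through `load_protein()` (PDB, altLoc-aware,
metal ions), `load_ligand_poses()` (multi-record SDF, V2000/V3000), and
`run_protocol()`, which scores every pose per pair, selects the top-1
pose by NMDN score, and predicts its pKd. A thin command-line front end
lives in `inst/cli/nmdn.R` (`score`, `rank-poses`, `predict-pkd`,
`screen`).

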