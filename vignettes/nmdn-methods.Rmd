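---
title: "Normalized mixture-density scoring of protein-ligand poses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized mixture-density scoring of protein-ligand poses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdn)
```

## The scoring problem

Docking programs generate many candidate binding poses for a
protein-ligand pair; the scoring problem is to recognise which pose, if
any, is native-like, and to rank ligands by their likelihood of binding.
`nmdn` implements a statistical-potential-style learned score for this
problem. Its central object is a **mixture density network (MDN)**: for
every residue-atom pair the network predicts a full probability
distribution over the pair distance, and a pose is scored by how probable
its *observed* distances are under those predicted distributions,
normalized against a reference probability taken near the interaction
cutoff.

A complex is represented heterogeneously: protein residues (each a set of
heavy-atom coordinates and an amino-acid identity), ligand atoms (element
and coordinate, vocabulary H, B, C, N, O, F, P, S, Cl, Br, I), and
optional metal ions. The geometric quantity that drives everything is the
**residue-atom minimum distance** `d_ij`: the minimum over the residue's
heavy atoms of the Euclidean distance to ligand atom `j`. Metal-ligand
distances `d_kj` are point-to-point. Only pairs within a cutoff
(default 9 Å) participate.

## The mixture density heads

For each pair, the residue embedding and ligand-atom embedding are
concatenated and passed through an MLP of 5 blocks (linear, batch
normalization, ReLU, dropout). Three linear readouts map the hidden state
to the mixture parameters of a Gaussian mixture over distance:

* weights `rho` through a softmax, so they always lie on the simplex;
* means `mu` through an affine readout, with biases initialized equally
  spaced over (1, 9) Å so components start spread over the relevant range;
* standard deviations `sigma` through a softplus plus a floor
  `sigma_min = 0.01` Å, so densities can never collapse to a point mass.

The full-scale hidden width is 4096; every width is configurable, and the
package's own studies use narrow heads (width 64) that train in seconds.
The metal-ligand head has the same architecture with its own parameters
and input dimensions. The training loss per pair is the negative log
density at the observed distance, computed via log-sum-exp so it never
overflows; the batch loss sums over all pairs within the *training*
cutoff, protein-ligand and metal-ligand terms added.

## Reference normalization and the pose score

A raw log-density rewards pairs whose distances are merely *predictable*,
not necessarily *favorable*. Following the statistical-potential idea, the
per-pair score is normalized by a reference probability near the cutoff:

* `p_ref` is the average predicted density over the six points
  `{ref - 0.5, ref - 0.4, ..., ref}` (with the default reference distance
  of 9 Å these are 8.5 ... 9.0 Å). Averaging six points rather than
  evaluating a single point at the cutoff makes the normalizer robust to
  local wiggles in the predicted density.
* the pair score is the log ratio `ln p(d) - ln p_ref`. The printed form
  of the score equation was not available to us, so the log-ratio
  convention (standard for statistical potentials, and additive over
  pairs) is the package's design choice; a plain-ratio variant is
  available behind `form = "ratio"` for comparison.

The pose score (`nmdn_score`) is the sum of pair scores over all
protein-ligand and metal-ligand pairs within the test cutoff. An empty
pair set scores exactly 0. Training and test cutoffs are independent
configuration values; by default both are 9 Å and the reference distance
equals the test cutoff, a simplification supported by cutoff sweeps in
which alternative reference distances performed comparably.

## The interaction module (pKd score)

Binding affinity is predicted as a sum of gated pairwise contributions
plus solvation corrections:

* each pair distance is expanded in 64 radial basis functions on the
  transformed distance `e^{-d}` — Gaussians with learnable centers
  (initialized equally spaced between `e^{-10}` and 1) and learnable
  widths (initialized so adjacent bases overlap at half maximum; the
  printed initialization expression was truncated in our source, so the
  half-maximum-overlap convention is our choice) — damped by a quintic
  smooth cutoff `phi(d) = 1 - 6x^5 + 15x^4 - 10x^3`, `x = d/d*`,
  `d* = 10` Å, which is 1 at contact, 0 beyond `d*`, and continuously
  differentiable at both ends;
* residue and ligand-atom embeddings pass through shifted-softplus
  (`SSP(x) = ln(e^x + 1) - ln 2`, so `SSP(0) = 0`) then linear maps to
  128 dimensions; the RBF vector passes through a linear map to 128; the
  three branch vectors combine by Hadamard product into the gated pair
  hidden vector;
* the protein-ligand readout concatenates this 128-vector with a 64-entry
  RBF expansion of the ligand's MMFF-optimization RMSD (a ligand-strain
  feature), giving the 192-dimensional readout input; metal-ligand pairs
  read out directly from the 128-vector, with no RMSD feature;
* two further linear readouts on the gated hidden vector give pairwise
  solvation coefficients, averaged over all protein-ligand pairs within
  9 Å into `alpha_gw` and `alpha_wo`; the predicted affinity is
  `pKd = sum PL_ij + sum ML_kj + alpha_gw * dG_gas->water +
  alpha_wo * dG_oct->water`. The linear pairing of coefficients with the
  two transfer free energies follows the gw/wo coefficient naming; the
  printed equation was unavailable, so linearity is our (simplest
  consistent) choice.

Solvation free energies and the MMFF RMSD are *inputs* (`ligand_extras`),
read from a CSV table; any per-ligand source is accepted. The affinity
loss is mean absolute error in pKd log-units. For virtual screening, a
fine-tuning objective treats weak binders (measured activity worse than
10 uM) with a hinge: prediction up to one log-unit above the measured
value carries no penalty — absorbing experimental error — and linear
penalty beyond. During this fine-tuning only the interaction module is
updated; the mixture heads stay frozen.

## Embedding providers

Production embeddings come from pretrained encoders and are consumed
through a keyed archive (a directory of `protein/<id>.tsv`,
`ligand/<id>.tsv`, `metal/<id>.tsv` matrices); any widths are accepted as
long as row counts match the complex. The residue provider is frozen by
default (protein language models are not fine-tuned here); ligand and
metal providers are trainable. So the whole stack can train and test
offline, the package ships a deterministic **baseline featurizer**:
learnable lookup tables over amino-acid codes, ligand elements and metal
elements, plus a zero-initialized linear refinement of rotation-invariant
local geometry features (distance statistics to the other ligand atoms).
Because the refinement starts at zero, an untrained baseline embedding is
a pure lookup, which is what makes the class-conditional density recovery
studies below well-posed. Non-standard residues map to code "X" and are
retained for geometry.

## Training machinery

No automatic-differentiation framework is assumed: the package contains a
small tape-based reverse-mode engine on matrices (`R/autodiff.R`) that
drives Adam training of the heads, the interaction module, and the
trainable encoder tables, with analytic backward passes for batch
normalization (batch statistics in training, frozen running statistics at
inference), dropout (inverted, masks drawn under the config seed), the
log-sum-exp mixture likelihood, and the RBF/gating algebra. A
finite-difference gradient check (`gradient_check`) compares reverse-mode
gradients with central differences; its relative error uses
`max(|analytic|, |fd|, 1e-4)` in the denominator because coordinates
whose true gradient sits below the central-difference noise floor
(~1e-10 absolute at step 1e-5) can only be compared absolutely. The check
runs in deterministic training mode (batch statistics, dropout off) so
the batch-norm training path is exercised; note that ReLU is
non-differentiable at 0, so check batches should avoid inputs that land
activations exactly on the kink (identical pairs with zero-initialized
batch-norm shifts do).

The combined objective is
`w_nmdn * (L_density_PL + L_density_ML) + w_pkd * L_affinity` with both
weights defaulting to 1; the relative weighting is not prescribed by the
method, so it is exposed in `nmdn_config`. Optimizer choices (Adam,
learning rate 1e-4 default, optional per-epoch decay) are likewise
package choices, not part of the method. The mean-absolute-error affinity
objective keeps a constant gradient magnitude near its optimum, so runs
that must converge tightly use `lr_decay` just below 1. Training is
deterministic given the seed and single-threaded linear algebra;
divergent (non-finite) losses abort with diagnostics. Checkpoints are
single files restoring evaluation-mode outputs exactly.

## What the synthetic generators emulate

All studies run on synthetic complexes, designed so ground truth is known
in closed form:

* `gen_complex` places a compact ligand (ball of radius 2 Å) and residues
  in "near" (3-5.5 Å) or "far" (13-20 Å) shells, so the fraction of pairs
  within the 9 Å cutoff is calibrated to a requested value;
* `gen_paired_complex` plants exact pair distances: each residue is a
  single atom 30 Å from every other pair, so residue `m` interacts with
  exactly one ligand atom at exactly the planted distance;
* `gen_mixture_distances` samples class-conditional distances from known
  two-component Gaussian mixtures keyed by (amino acid, ligand element),
  truncated to (0, 9] Å — classes are keyed this way precisely so a small
  head fed baseline lookup embeddings can genuinely learn
  class-conditional densities;
* `gen_pose_systems` builds multi-pose systems in which pose 1 draws its
  distances from the class mixtures and decoys from a uniform background,
  together with each pose's true likelihood-ratio score;
* `gen_screen_library` draws latent ligand quality scores with a
  controllable active/inactive separation, making expected enrichment
  analytic;
* `gen_affinity_dataset` plants a linear affinity rule the interaction
  module can represent: class-weighted `exp(-d)` terms (exactly the RBF
  transform's natural coordinate) plus linear solvation terms.

These generators deliberately omit almost everything that makes real
structures hard: side-chain chemistry, protonation, crystallographic
noise, correlated pair geometry, decoy realism, and the gap between a
pretrained encoder's embedding space and a lookup table. Passing the
package's studies therefore demonstrates that the machinery is correct
and recovers planted truth — not that the default configuration matches
benchmark performance on real complexes, which requires the external
encoders, curated training data and externally generated poses that are
out of scope here.

## Study problem sizes and numerical choices

The packaged studies use sizes chosen to make every property sharply
testable at desk scale: density calibration over 1,000 random mixtures
(trapezoid quadrature with grids refined around every component);
recovery training on 5,000 distances per class for two classes with a
width-64, 5-layer head (8 epochs, batch 256, Adam 2e-3); pose selection
over 200 systems of 6 pairs and 3 poses; affinity recovery on 200
training and 40 validation complexes (150 epochs, batch 25, Adam 5e-3,
decay 0.985); invariance over 100 random rigid motions and atom
permutations.

Remaining numerical conventions: mixture weights use softmax (zero logits
give the uniform mixture); `sigma_min = 0.01` Å; dropout 0.1 (off at
evaluation; evaluation mode is fully deterministic); batch-norm epsilon
1e-5 and momentum 0.1, running statistics frozen at inference;
enrichment-factor ties broken by ranking on score then ligand id (stable
and order-independent); top-pose ties broken lexicographically on pose
id; the combined two-score selection takes the top 0.5% from each score,
then — when the union falls short of the 1% budget because the sets
overlap — appends next-ranked unselected ligands one at a time,
alternating between the scores starting with the NMDN score (the
alternation order is a convention we fixed; with at least one ligand per
score enforced for small libraries); ligand RMSD is computed without
superposition, in the shared protein frame, optionally minimized over
element-colored graph automorphisms; a complex with no protein-ligand
pair within 9 Å has undefined solvation coefficients, which are set to 0
with a warning; an empty pair set is a valid input scoring 0, not an
error.

Two interface notes. The enrichment factor supports both the
top-fraction reading (default, used for top-x% reports) and the
false-positive-rate reading (ROC enrichment), because both conventions
are in active use. SDF input accepts V2000 and V3000 records; records
whose coordinates are all-zero in z are rejected as 2D (a genuinely
planar 3D molecule lying exactly in the xy-plane would be a false
positive of this heuristic — rotate it out of plane if that ever
matters).

## Known limitations

* The baseline featurizer is a stand-in for pretrained encoders in terms
  of *interface and trainability*, not representational power.
* Minimum distance is taken over all residue heavy atoms; if a
  Calpha-only or side-chain-only convention is ever needed it would be a
  one-line change in `enumerate_pairs`, but the all-heavy-atom reading is
  the natural one for "minimum distance".
* The R implementation targets correctness and desk-scale studies;
  training at the width-4096, ~12k-complex scale calls for an
  accelerator-backed implementation consuming the same file contracts.
* Pose generation, covalent-binder handling, protonation and
  biological-assembly expansion are out of scope; poses arrive via the
  documented one-SDF-per-pair contract.
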