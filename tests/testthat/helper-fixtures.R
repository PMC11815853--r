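# Shared fixtures. The density-recovery model is expensive to train, so it
# is built lazily once per test run and reused by every test that needs a
# trained head.

.fixture_env <- new.env(parent = emptyenv())

# planted two-component mixtures per (amino acid, ligand element) class
recovery_classes <- function() {
  list(
    "A:C" = mixture_density(c(0.6, 0.4), c(3.0, 6.0), c(0.4, 0.7)),
    "G:O" = mixture_density(c(0.3, 0.7), c(2.5, 5.0), c(0.3, 0.9))
  )
}

# Train a narrow mixture head on 5,000 distances per class and return the
# encoder, head, classes and a model wrapping them.
recovery_fixture <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  classes <- recovery_classes()
  samp <- gen_mixture_distances(classes, 5000, seed = 7)
  enc <- baseline_encoder(seed = 5)
  X <- cbind(enc$aa_table[samp$aa, , drop = FALSE],
             enc$elem_table[samp$element, , drop = FALSE])
  head <- new_mdn_head(sum(enc$dims[1:2]), hidden = 64, n_layers = 5,
                       n_components = 5, dropout = 0.1, seed = 3)
  head <- fit_mdn_head(head, X, samp$d, epochs = 8, batch_size = 256,
                       lr = 2e-3, seed = 3)
  model <- nmdn_model(encoder = enc, hidden = 64, n_components = 5, seed = 3)
  model$pl_head <- head
  .fixture_env$recovery <- list(classes = classes, enc = enc, head = head,
                                model = model)
  .fixture_env$recovery
}

# KL(truth || learned) over (0, cutoff] by grid quadrature, both densities
# renormalized on the truncated support
kl_truncated <- function(truth, learned, cutoff = 9, n_grid = 2000) {
  r <- seq(1e-3, cutoff, length.out = n_grid)
  dr <- diff(r[1:2])
  pt <- density_at(truth, r); pl <- density_at(learned, r)
  pt <- pt / (sum(pt) * dr); pl <- pl / (sum(pl) * dr)
  sum(pt * (log(pt) - log(pl))) * dr
}

# small tidy model for structural tests
tiny_model <- function(seed = 2) {
  nmdn_model(encoder = baseline_encoder(dims = c(8L, 8L, 8L), seed = seed),
             hidden = 6, n_components = 3, n_layers = 2,
             interaction_hidden = 5, seed = seed)
}

random_rigid_motion <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 10))
}

apply_rigid <- function(complex, motion) {
  tf <- function(M) sweep(M %*% t(motion$R), 2, -motion$t, "-")
  complex$lig_coords <- tf(complex$lig_coords)
  if (nrow(complex$metal_coords)) complex$metal_coords <- tf(complex$metal_coords)
  complex$residues <- lapply(complex$residues, function(r) {
    r$heavy_atom_coords <- tf(r$heavy_atom_coords)
    r
  })
  complex
}

permute_ligand <- function(complex, perm) {
  complex$lig_elements <- complex$lig_elements[perm]
  complex$lig_coords <- complex$lig_coords[perm, , drop = FALSE]
  complex
}

# a toy PDB with two residues (ALA, GLY), one altLoc pair, and a ZN ion
write_toy_pdb <- function(path, altloc = TRUE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.450   0.000   0.000  1.00  0.00           C",
    if (altloc) c(
      "ATOM      3  CB AALA A   1       2.000   1.000   0.000  0.30  0.00           C",
      "ATOM      4  CB BALA A   1       2.000   1.200   0.000  0.70  0.00           C"
    ) else
      "ATOM      3  CB  ALA A   1       2.000   1.000   0.000  1.00  0.00           C",
    "ATOM      5  N   GLY A   2       3.000   0.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.450   0.000   0.000  1.00  0.00           C",
    "HETATM    7 ZN    ZN A 101       5.000   5.000   5.000  1.00  0.00          ZN",
    "HETATM    8  O   HOH A 201       8.000   8.000   8.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

# benzene: 6 C + 6 H with aromatic ring bonds, flat in a tilted plane so
# the record is genuinely 3D
benzene_pose <- function() {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hyd <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  tilt <- matrix(c(1, 0, 0, 0, cos(0.3), -sin(0.3), 0, sin(0.3), cos(0.3)), 3, 3)
  coords <- rbind(ring, hyd) %*% tilt
  bonds <- cbind(atom1 = c(1:6, 1:6), atom2 = c(2:6, 1, 7:12),
                 order = c(rep(2L, 3), rep(1L, 3), rep(1L, 6)))
  bonds[1:6, 3] <- c(2L, 1L, 2L, 1L, 2L, 1L)
  list(elements = c(rep("C", 6), rep("H", 6)), coords = coords,
       bonds = bonds, title = "benzene")
}
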