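# Synthetic complexes, distance samples and screening libraries.
#
# Geometry is deliberately simple: single- or few-atom residues placed in
# shells around a compact ligand so that the fraction of residue-atom
# pairs inside the scoring cutoff is controllable, and "paired" layouts in
# which each residue interacts with exactly one ligand atom at a planted
# distance, so the true pair-distance distribution is known in closed
# form. All generators are pure functions of their parameters and seed.

ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), unname(AA_THREE_TO_ONE))

random_unit_vector <- function(n = 1L) {
  v <- matrix(stats::rnorm(3L * n), n, 3L)
  v / sqrt(rowSums(v^2))
}

#' Generate a random synthetic complex
#'
#' Ligand atoms are placed inside a ball of radius 2 Angstrom around the
#' origin. A fraction `within_fraction` of residues is placed so that all
#' of their atoms fall within the 9 Angstrom cutoff of every ligand atom;
#' the rest are placed beyond it. Metals are placed near the ligand.
#'
#' @param n_residues,n_lig_atoms,n_metals entity counts
#' @param seed RNG seed (the generator is deterministic per seed)
#' @param within_fraction expected fraction of residue-atom pairs inside
#'   the 9 Angstrom cutoff (default 0.7)
#' @param max_atoms_per_residue residues carry 1..this many heavy atoms
#' @param pose_id pose identifier
#' @return an [nmdn_complex()]
#' @export
gen_complex <- function(n_residues, n_lig_atoms, n_metals = 0L, seed = 1L,
                        within_fraction = 0.7, max_atoms_per_residue = 3L,
                        pose_id = paste0("synth-", seed)) {
  n_metals <- as.integer(n_metals)
  stopifnot(n_residues >= 1L, n_lig_atoms >= 1L, n_metals >= 0L)
  set.seed(seed)
  lig_coords <- random_unit_vector(n_lig_atoms) *
    stats::runif(n_lig_atoms, 0, 2)
  lig_elements <- sample(c("C", "N", "O", "S", "F", "Cl"), n_lig_atoms,
                         replace = TRUE, prob = c(0.5, 0.15, 0.2, 0.05, 0.05, 0.05))
  residues <- vector("list", n_residues)
  near <- stats::runif(n_residues) < within_fraction
  for (i in seq_len(n_residues)) {
    center_dist <- if (near[i]) stats::runif(1, 3, 5.5) else stats::runif(1, 13, 20)
    center <- random_unit_vector() * center_dist
    n_atoms <- sample.int(max_atoms_per_residue, 1L)
    coords <- center[rep(1L, n_atoms), , drop = FALSE] +
      random_unit_vector(n_atoms) * stats::runif(n_atoms, 0, 1)
    residues[[i]] <- nmdn_residue("A", i, sample(unname(AA_THREE_TO_ONE), 1L),
                                  coords)
  }
  metal_elements <- character(0)
  metal_coords <- matrix(numeric(0), 0L, 3L)
  if (n_metals > 0L) {
    metal_elements <- sample(c("Zn", "Mg", "Ca"), n_metals, replace = TRUE)
    metal_coords <- random_unit_vector(n_metals) * stats::runif(n_metals, 3, 6)
  }
  nmdn_complex(residues, lig_elements, lig_coords, metal_elements,
               metal_coords, pose_id = pose_id)
}

#' Generate a paired-geometry complex with planted pair distances
#'
#' Each residue is a single heavy atom placed 30 Angstrom away from all
#' other residue/ligand-atom pairs, so that residue `m` is within the
#' cutoff of exactly one ligand atom, at exactly `distances[m]`. The pair
#' set of such a complex is the planted distance vector itself.
#'
#' @param aa one-letter amino-acid codes (length m)
#' @param elements ligand element symbols (length m)
#' @param distances planted pair distances, Angstrom (length m, < 9)
#' @param pose_id pose identifier
#' @return an [nmdn_complex()]
#' @export
gen_paired_complex <- function(aa, elements, distances, pose_id = "paired") {
  m <- length(distances)
  stopifnot(length(aa) == m, length(elements) == m, all(distances > 0))
  residues <- vector("list", m)
  lig_coords <- matrix(0, m, 3L)
  for (i in seq_len(m)) {
    base <- c(30 * (i - 1L), 0, 0)
    residues[[i]] <- nmdn_residue("A", i, aa[i], matrix(base, 1L))
    lig_coords[i, ] <- base + c(distances[i], 0, 0)
  }
  nmdn_complex(residues, elements, lig_coords, pose_id = pose_id)
}

#' Sample labelled pair distances from per-class mixtures
#'
#' Draws `n_per_class` distances for every (amino acid, element) class
#' from its mixture, truncated by rejection to `(0, train_cutoff]`.
#'
#' @param class_params named list of [mixture_density()] objects; names are
#'   "AA:El" class labels (e.g. "A:C")
#' @param n_per_class samples per class
#' @param seed RNG seed
#' @param train_cutoff truncation bound, Angstrom (default 9)
#' @return data frame with columns `class`, `aa`, `element`, `d`
#' @export
gen_mixture_distances <- function(class_params, n_per_class, seed = 1L,
                                  train_cutoff = 9.0) {
  set.seed(seed)
  out <- lapply(names(class_params), function(cl) {
    mix <- class_params[[cl]]
    d <- numeric(0)
    while (length(d) < n_per_class) {
      k <- sample.int(length(mix$weights), n_per_class, replace = TRUE,
                      prob = mix$weights)
      x <- stats::rnorm(n_per_class, mix$means[k], mix$sigmas[k])
      d <- c(d, x[x > 0 & x <= train_cutoff])
    }
    d <- d[seq_len(n_per_class)]
    parts <- strsplit(cl, ":", fixed = TRUE)[[1L]]
    data.frame(class = cl, aa = parts[1L], element = parts[2L], d = d)
  })
  do.call(rbind, out)
}

#' Generate a synthetic screening library
#'
#' Latent quality scores are standard normal; actives are shifted upward
#' by `score_separation`, which makes expected enrichment analytically
#' controllable (separation 0 gives EF about 1 on average; large
#' separation saturates EF at its maximum).
#'
#' @param n_ligands library size
#' @param active_fraction fraction of actives
#' @param score_separation mean score shift of actives (in SD units)
#' @param seed RNG seed
#' @return data frame with columns `ligand_id`, `score`, `is_active`
#' @export
gen_screen_library <- function(n_ligands, active_fraction = 0.02,
                               score_separation = 0, seed = 1L) {
  set.seed(seed)
  n_active <- round(n_ligands * active_fraction)
  is_active <- c(rep(TRUE, n_active), rep(FALSE, n_ligands - n_active))
  score <- stats::rnorm(n_ligands) + ifelse(is_active, score_separation, 0)
  data.frame(ligand_id = sprintf("L%06d", seq_len(n_ligands)),
             score = score, is_active = is_active)
}

#' Generate pose-ranking systems with known generative mixtures
#'
#' Each system is one paired-geometry "pocket" observed under `n_poses`
#' alternative poses: every pose replants the pair distances, drawn either
#' from the class mixtures (native-like) or from a uniform background on
#' (1, cutoff). The true per-pose log-likelihood ratio (class mixture
#' density at the planted distances, normalized by the class reference
#' probability) is returned so scoring can be checked against the ground
#' truth.
#'
#' @param class_params named list of [mixture_density()], names "AA:El"
#' @param n_systems number of systems
#' @param n_pairs pairs per system
#' @param n_poses poses per system (pose 1 is drawn from the mixtures)
#' @param seed RNG seed
#' @param cutoff scoring cutoff (default 9)
#' @return list of systems; each has `poses` (list of complexes) and
#'   `true_ll` (true likelihood-ratio scores per pose)
#' @export
gen_pose_systems <- function(class_params, n_systems = 50L, n_pairs = 6L,
                             n_poses = 3L, seed = 1L, cutoff = 9.0) {
  set.seed(seed)
  classes <- names(class_params)
  ref_pts <- cutoff - seq(0.5, 0, by = -0.1)
  lapply(seq_len(n_systems), function(si) {
    cls <- sample(classes, n_pairs, replace = TRUE)
    aa <- vapply(strsplit(cls, ":", fixed = TRUE), `[[`, character(1), 1L)
    el <- vapply(strsplit(cls, ":", fixed = TRUE), `[[`, character(1), 2L)
    poses <- vector("list", n_poses)
    true_ll <- numeric(n_poses)
    for (pi in seq_len(n_poses)) {
      d <- numeric(n_pairs)
      for (m in seq_len(n_pairs)) {
        mix <- class_params[[cls[m]]]
        if (pi == 1L) {
          repeat {
            k <- sample.int(length(mix$weights), 1L, prob = mix$weights)
            x <- stats::rnorm(1L, mix$means[k], mix$sigmas[k])
            if (x > 0.5 && x < cutoff) break
          }
          d[m] <- x
        } else {
          d[m] <- stats::runif(1L, 1, cutoff - 1e-3)
        }
      }
      poses[[pi]] <- gen_paired_complex(aa, el, d,
                                        pose_id = sprintf("sys%03d-pose%d", si, pi))
      true_ll[pi] <- sum(vapply(seq_len(n_pairs), function(m) {
        mix <- class_params[[cls[m]]]
        log_density_at(mix, d[m]) - log(mean(density_at(mix, ref_pts)))
      }, numeric(1)))
    }
    list(poses = poses, true_ll = true_ll, classes = cls)
  })
}

#' Generate an affinity dataset from a planted linear rule
#'
#' Paired-geometry complexes over a small set of (amino acid, element)
#' classes; labels follow a planted rule that the interaction module can
#' represent: a class-weighted exponential of each pair distance plus
#' linear solvation terms,
#' `pKd = scale * sum_m w_class(m) exp(-d_m) + a_gw * dG_gas_to_water +
#' a_wo * dG_oct_to_water + intercept`.
#'
#' @param n number of complexes
#' @param seed RNG seed
#' @param n_pairs pairs per complex (default 4)
#' @param classes list of c(aa, element) class definitions
#' @param class_weights planted per-class weights
#' @param scale overall interaction scale (default 8)
#' @param a_gw,a_wo planted solvation coefficients
#' @param intercept planted intercept (default 5, a mid-range pKd)
#' @return list of records (`complex`, `label`, `extras`) ready for
#'   [fit_nmdn()]
#' @export
gen_affinity_dataset <- function(n, seed = 1L, n_pairs = 4L,
                                 classes = list(c("A", "C"), c("G", "O"),
                                                c("L", "N")),
                                 class_weights = c(3, -2, 1.5), scale = 8,
                                 a_gw = 0.15, a_wo = -0.1, intercept = 5) {
  stopifnot(length(classes) == length(class_weights))
  lapply(seq_len(n), function(i) {
    set.seed(seed * 100000L + i)
    k <- sample(seq_along(classes), n_pairs, replace = TRUE)
    d <- stats::runif(n_pairs, 2, 8)
    aa <- vapply(k, function(z) classes[[z]][1L], character(1))
    el <- vapply(k, function(z) classes[[z]][2L], character(1))
    cx <- gen_paired_complex(aa, el, d, pose_id = sprintf("aff%04d", i))
    ex <- ligand_extras(stats::runif(1, 0, 2), stats::runif(1, -10, -2),
                        stats::runif(1, -4, 2))
    lab <- scale * sum(class_weights[k] * exp(-d)) +
      a_gw * ex$dG_gas_to_water + a_wo * ex$dG_oct_to_water + intercept
    list(complex = cx, label = lab, extras = ex)
  })
}

#' Write a complex's protein (and metals) as a PDB file
#'
#' Residue heavy atoms are written as carbon ATOM records (the synthetic
#' generators do not model side-chain chemistry); metals become HETATM
#' records. Round-trips through [load_protein()].
#' @param complex an [nmdn_complex()]
#' @param path output PDB path
#' @export
write_complex_pdb <- function(complex, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_along(complex$residues)) {
    r <- complex$residues[[i]]
    res3 <- ONE_TO_THREE[[r$aa_code]]
    for (a in seq_len(nrow(r$heavy_atom_coords))) {
      serial <- serial + 1L
      xyz <- r$heavy_atom_coords[a, ]
      writeLines(sprintf(
        "ATOM  %5d  C%-2d %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, a, res3, r$chain_id, r$seq_index, xyz[1], xyz[2], xyz[3]), con)
    }
  }
  for (k in seq_along(complex$metal_elements)) {
    serial <- serial + 1L
    el <- complex$metal_elements[k]
    xyz <- complex$metal_coords[k, ]
    writeLines(sprintf(
      "HETATM%5d %-4s %3s M%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, toupper(el), toupper(el), k, xyz[1], xyz[2], xyz[3],
      toupper(el)), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write ligand poses as a multi-record V2000 SDF file
#'
#' @param poses list of poses: each a list with `elements`, `coords`, and
#'   optionally `bonds` and `title` (an [nmdn_complex()] is also accepted)
#' @param path output SDF path
#' @export
write_ligand_sdf <- function(poses, path) {
  if (inherits(poses, "nmdn_complex")) poses <- list(poses)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    if (inherits(p, "nmdn_complex"))
      p <- list(elements = p$lig_elements, coords = p$lig_coords,
                bonds = p$lig_bonds, title = p$pose_id)
    n <- length(p$elements)
    nb <- if (is.null(p$bonds)) 0L else nrow(p$bonds)
    writeLines(c(if (is.null(p$title)) "ligand" else p$title,
                 "  synthetic", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (a in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         p$coords[a, 1L], p$coords[a, 2L], p$coords[a, 3L],
                         p$elements[a]), con)
    }
    if (nb > 0L) for (b in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0", p$bonds[b, 1L], p$bonds[b, 2L],
                         p$bonds[b, 3L]), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
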