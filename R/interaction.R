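# Interaction module: binding-affinity (pKd) prediction from gated
# pairwise protein/metal-ligand contributions, a ligand-strain RMSD
# feature, and linear solvation corrections.
#
# Per protein-ligand pair, the distance is expanded in 64 radial basis
# functions on the exponentially transformed distance e^{-d} (PhysNet
# lineage) under a quintic smooth cutoff; protein and ligand embeddings
# pass through shifted-softplus + linear branches; the three 128-d branch
# vectors combine by Hadamard product. The gated hidden vector is
# concatenated with a 64-d RBF expansion of the ligand's MMFF RMSD (192-d
# total) and read out to the scalar pair contribution; two further linear
# readouts give the pairwise solvation coefficients. Metal-ligand pairs
# follow the same flow without the RMSD feature or solvation readouts.

#' Quintic smooth cutoff function
#'
#' `phi(d) = 1 - 6x^5 + 15x^4 - 10x^3` with `x = d/d_star`, clamped to 0
#' for `d >= d_star`; continuously differentiable at both ends, with
#' `phi(0) = 1` and `phi(d_star) = 0`.
#' @param d distance(s), Angstrom (non-negative)
#' @param d_star cutoff, Angstrom (default 10)
#' @return values in `[0, 1]`
#' @export
smooth_cutoff <- function(d, d_star = 10.0) {
  stopifnot(all(d >= 0), d_star > 0)
  x <- pmin(d / d_star, 1)
  1 - 6 * x^5 + 15 * x^4 - 10 * x^3
}

#' Radial basis specification
#'
#' 64 Gaussian basis functions on the transformed distance `e^{-d}`, with
#' learnable centers initialized equally spaced between `e^{-10}` and 1 and
#' learnable widths initialized so adjacent basis functions overlap at half
#' maximum; each basis value is damped by the smooth cutoff at
#' `d_star = 10` Angstrom.
#'
#' @param n_basis number of basis functions (default 64)
#' @param d_star smooth-cutoff distance, Angstrom (default 10)
#' @return object of class `nmdn_rbf_spec` with `centers`, `beta`, `d_star`
#' @export
rbf_spec <- function(n_basis = 64L, d_star = 10.0) {
  centers <- seq(exp(-10), 1, length.out = n_basis)
  delta <- diff(centers[1:2])
  beta <- rep(4 * log(2) / delta^2, n_basis)
  structure(list(centers = matrix(centers, 1L), beta = matrix(beta, 1L),
                 n_basis = as.integer(n_basis), d_star = d_star),
            class = "nmdn_rbf_spec")
}

#' Expand a distance in radial basis functions
#'
#' `g_k(d) = exp(-beta_k (e^{-d} - mu_k)^2) * phi(d)`; all entries lie in
#' `[0, 1]` and the whole vector vanishes for `d >= d_star`.
#' @param d distance(s), Angstrom
#' @param spec an [rbf_spec()]
#' @return matrix `length(d) x n_basis`
#' @export
rbf_expand <- function(d, spec = rbf_spec()) {
  stopifnot(all(d >= 0))
  E <- exp(-d)
  M <- outer(E, as.numeric(spec$centers), "-")
  G <- exp(-sweep(M^2, 2L, as.numeric(spec$beta), "*"))
  G * smooth_cutoff(d, spec$d_star)
}

# autodiff RBF expansion with learnable centers/widths (leaves mu, beta)
ad_rbf <- function(d, mu, beta, d_star) {
  n <- length(d)
  K <- ncol(ad_value(mu))
  E <- matrix(exp(-d), n, K)
  M <- ad_sub_rvec(ad_node(E), mu)
  A <- ad_mul_rvec(ad_mul(M, M), beta)
  G0 <- ad_exp(ad_scale(A, -1))
  phi <- matrix(smooth_cutoff(d, d_star), ncol = 1L)
  ad_mul_cvec(G0, ad_node(phi))
}

#' Create interaction-module parameters
#'
#' @param d_prot,d_lig,d_metal embedding widths
#' @param hidden gated hidden width (default 128; with the 64-entry RMSD
#'   expansion this gives the 192-dimensional readout input)
#' @param n_basis RBF count (default 64)
#' @param d_star smooth-cutoff distance (default 10)
#' @param cutoff pair cutoff for affinity contributions, Angstrom (default 9)
#' @param seed initialization seed
#' @return object of class `nmdn_interaction`
#' @export
new_interaction_params <- function(d_prot, d_lig, d_metal = d_lig,
                                   hidden = 128L, n_basis = 64L,
                                   d_star = 10.0, cutoff = 9.0, seed = 1L) {
  set.seed(seed)
  gl <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)),
                                   nin, nout)
  rb <- rbf_spec(n_basis, d_star)
  params <- list(
    W_prot = gl(d_prot, hidden), b_prot = matrix(0, 1L, hidden),
    W_lig = gl(d_lig, hidden), b_lig = matrix(0, 1L, hidden),
    W_dist = gl(n_basis, hidden), b_dist = matrix(0, 1L, hidden),
    rbf_mu = rb$centers, rbf_beta = rb$beta,
    rmsd_mu = rb$centers, rmsd_beta = rb$beta,
    W_ro = gl(hidden + n_basis, 1L), b_ro = matrix(0, 1L, 1L),
    W_gw = gl(hidden, 1L), b_gw = matrix(0, 1L, 1L),
    W_wo = gl(hidden, 1L), b_wo = matrix(0, 1L, 1L),
    W_metal = gl(d_metal, hidden), b_metal = matrix(0, 1L, hidden),
    W_lig_ml = gl(d_lig, hidden), b_lig_ml = matrix(0, 1L, hidden),
    W_dist_ml = gl(n_basis, hidden), b_dist_ml = matrix(0, 1L, hidden),
    rbf_mu_ml = rb$centers, rbf_beta_ml = rb$beta,
    W_ro_ml = gl(hidden, 1L), b_ro_ml = matrix(0, 1L, 1L)
  )
  structure(list(params = params, hidden = as.integer(hidden),
                 n_basis = as.integer(n_basis), d_star = d_star,
                 cutoff = cutoff,
                 d_prot = as.integer(d_prot), d_lig = as.integer(d_lig),
                 d_metal = as.integer(d_metal)),
            class = "nmdn_interaction")
}

#' Gated pair hidden vector
#'
#' Combines the shifted-softplus + linear transforms of the residue and
#' ligand-atom embeddings with the linear transform of the RBF-expanded
#' distance by element-wise (Hadamard) product.
#' @param h_prot,h_lig embeddings (numeric vectors)
#' @param d pair distance, Angstrom
#' @param inter an [new_interaction_params()] object
#' @param branch "pl" (default) or "ml" (h_prot is then the metal embedding)
#' @return numeric vector of length `hidden`
#' @export
gated_pair_hidden <- function(h_prot, h_lig, d, inter, branch = c("pl", "ml")) {
  branch <- match.arg(branch)
  p <- inter$params
  ssp <- function(x) softplus(x) - log(2)
  if (branch == "pl") {
    a <- ssp(as.numeric(h_prot)) %*% p$W_prot + p$b_prot
    b <- ssp(as.numeric(h_lig)) %*% p$W_lig + p$b_lig
    spec <- structure(list(centers = p$rbf_mu, beta = p$rbf_beta,
                           n_basis = inter$n_basis, d_star = inter$d_star),
                      class = "nmdn_rbf_spec")
    g <- rbf_expand(d, spec) %*% p$W_dist + p$b_dist
  } else {
    a <- ssp(as.numeric(h_prot)) %*% p$W_metal + p$b_metal
    b <- ssp(as.numeric(h_lig)) %*% p$W_lig_ml + p$b_lig_ml
    spec <- structure(list(centers = p$rbf_mu_ml, beta = p$rbf_beta_ml,
                           n_basis = inter$n_basis, d_star = inter$d_star),
                      class = "nmdn_rbf_spec")
    g <- rbf_expand(d, spec) %*% p$W_dist_ml + p$b_dist_ml
  }
  as.numeric(a * b * g)
}

#' Protein-ligand pair contribution
#'
#' Concatenates the gated hidden vector (128) with the RBF expansion of
#' the ligand's MMFF RMSD (64) into the 192-dimensional readout input, and
#' applies the linear readout; the same hidden vector feeds two linear
#' readouts for the pairwise solvation coefficients.
#' @param hidden gated pair hidden vector (length `hidden`)
#' @param mmff_rmsd ligand MMFF RMSD, Angstrom (non-negative)
#' @param inter an [new_interaction_params()]
#' @return list with `value` (PL_ij), `alpha_gw`, `alpha_wo`, and the
#'   readout input dimension `dim_in`
#' @export
pl_contribution <- function(hidden, mmff_rmsd, inter) {
  stopifnot(mmff_rmsd >= 0)
  p <- inter$params
  spec <- structure(list(centers = p$rmsd_mu, beta = p$rmsd_beta,
                         n_basis = inter$n_basis, d_star = inter$d_star),
                    class = "nmdn_rbf_spec")
  xin <- c(as.numeric(hidden), as.numeric(rbf_expand(mmff_rmsd, spec)))
  list(value = as.numeric(xin %*% p$W_ro + p$b_ro),
       alpha_gw = as.numeric(as.numeric(hidden) %*% p$W_gw + p$b_gw),
       alpha_wo = as.numeric(as.numeric(hidden) %*% p$W_wo + p$b_wo),
       dim_in = length(xin))
}

#' Metal-ligand pair contribution
#'
#' Linear readout directly from the 128-d gated hidden vector; the RMSD
#' feature and solvation readouts are not used for metal-ligand pairs.
#' @param hidden gated pair hidden vector from the "ml" branch
#' @param inter an [new_interaction_params()]
#' @return list with `value` (ML_kj) and `dim_in`
#' @export
ml_contribution <- function(hidden, inter) {
  p <- inter$params
  list(value = as.numeric(as.numeric(hidden) %*% p$W_ro_ml + p$b_ro_ml),
       dim_in = length(as.numeric(hidden)))
}

#' Ligand extras: MMFF RMSD and solvation transfer free energies
#'
#' @param mmff_rmsd RMSD between the pose and its MMFF94-optimized
#'   conformation, Angstrom (non-negative)
#' @param dG_gas_to_water,dG_oct_to_water ligand transfer free energies,
#'   kcal/mol
#' @return object of class `nmdn_ligand_extras`
#' @export
ligand_extras <- function(mmff_rmsd = 0, dG_gas_to_water = 0,
                          dG_oct_to_water = 0) {
  stopifnot(mmff_rmsd >= 0, is.finite(dG_gas_to_water), is.finite(dG_oct_to_water))
  structure(list(mmff_rmsd = mmff_rmsd,
                 dG_gas_to_water = dG_gas_to_water,
                 dG_oct_to_water = dG_oct_to_water),
            class = "nmdn_ligand_extras")
}

#' Read a ligand-extras table
#'
#' CSV with columns `ligand_id, mmff_rmsd, dG_gas_to_water,
#' dG_oct_to_water`.
#' @param path CSV path
#' @return named list of [ligand_extras()] keyed by ligand_id
#' @export
read_ligand_extras <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "mmff_rmsd", "dG_gas_to_water", "dG_oct_to_water")
  if (!all(need %in% names(df)))
    stop("ligand extras table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    ligand_extras(df$mmff_rmsd[i], df$dG_gas_to_water[i], df$dG_oct_to_water[i]))
  names(out) <- df$ligand_id
  out
}

# Vectorized autodiff forward over a batch of complexes. `pd` carries
# pair-level matrices/indices (see build_pairdata); leaves are
# ad_leaf-wrapped params. Returns per-complex nodes.
interaction_forward <- function(inter, pd, leaves = NULL) {
  P <- if (is.null(leaves)) lapply(inter$params, ad_leaf) else leaves
  G <- pd$n_complex
  zero <- ad_node(matrix(0, G, 1L))
  pl_sum <- zero; alpha_gw <- zero; alpha_wo <- zero
  pl_contrib <- NULL
  if (pd$n_pl > 0L) {
    a <- ad_add_rvec(ad_matmul(ad_ssp(pd$Hp), P$W_prot), P$b_prot)
    b <- ad_add_rvec(ad_matmul(ad_ssp(pd$Hl_pl), P$W_lig), P$b_lig)
    Grbf <- ad_rbf(pd$d_pl, P$rbf_mu, P$rbf_beta, inter$d_star)
    g <- ad_add_rvec(ad_matmul(Grbf, P$W_dist), P$b_dist)
    hidden <- ad_mul(ad_mul(a, b), g)
    Rrbf <- ad_rbf(pd$rmsd_pl, P$rmsd_mu, P$rmsd_beta, inter$d_star)
    pl_contrib <- ad_add_rvec(ad_matmul(ad_concat_cols(hidden, Rrbf), P$W_ro),
                              P$b_ro)
    agw <- ad_add_rvec(ad_matmul(hidden, P$W_gw), P$b_gw)
    awo <- ad_add_rvec(ad_matmul(hidden, P$W_wo), P$b_wo)
    gp <- sort(unique(pd$group_pl))
    cnt <- as.numeric(table(factor(pd$group_pl, levels = gp)))
    pl_sum <- ad_embed_rows(ad_rowsum_by(pl_contrib, pd$group_pl), gp, G)
    alpha_gw <- ad_embed_rows(
      ad_mul_cvec(ad_rowsum_by(agw, pd$group_pl), ad_node(matrix(1 / cnt, ncol = 1L))),
      gp, G)
    alpha_wo <- ad_embed_rows(
      ad_mul_cvec(ad_rowsum_by(awo, pd$group_pl), ad_node(matrix(1 / cnt, ncol = 1L))),
      gp, G)
  }
  ml_sum <- zero
  ml_contrib <- NULL
  if (pd$n_ml > 0L) {
    a <- ad_add_rvec(ad_matmul(ad_ssp(pd$Hm), P$W_metal), P$b_metal)
    b <- ad_add_rvec(ad_matmul(ad_ssp(pd$Hl_ml), P$W_lig_ml), P$b_lig_ml)
    Grbf <- ad_rbf(pd$d_ml, P$rbf_mu_ml, P$rbf_beta_ml, inter$d_star)
    g <- ad_add_rvec(ad_matmul(Grbf, P$W_dist_ml), P$b_dist_ml)
    hidden <- ad_mul(ad_mul(a, b), g)
    ml_contrib <- ad_add_rvec(ad_matmul(hidden, P$W_ro_ml), P$b_ro_ml)
    gp <- sort(unique(pd$group_ml))
    ml_sum <- ad_embed_rows(ad_rowsum_by(ml_contrib, pd$group_ml), gp, G)
  }
  solv <- ad_add(ad_mul(alpha_gw, ad_node(matrix(pd$dG_gw, ncol = 1L))),
                 ad_mul(alpha_wo, ad_node(matrix(pd$dG_wo, ncol = 1L))))
  pkd <- ad_add(ad_add(pl_sum, ml_sum), solv)
  list(pkd = pkd, pl_sum = pl_sum, ml_sum = ml_sum,
       alpha_gw = alpha_gw, alpha_wo = alpha_wo,
       pl_contrib = pl_contrib, ml_contrib = ml_contrib)
}

# Flatten a list of (complex, embeddings, extras) into pair-level arrays
# for the interaction module at its affinity cutoff.
build_pairdata <- function(complexes, embeddings_list, extras_list,
                           cutoff = 9.0, include_hydrogens = TRUE) {
  G <- length(complexes)
  Hp <- list(); Hl_pl <- list(); d_pl <- list(); group_pl <- list(); rmsd_pl <- list()
  Hm <- list(); Hl_ml <- list(); d_ml <- list(); group_ml <- list()
  dG_gw <- numeric(G); dG_wo <- numeric(G)
  for (gi in seq_len(G)) {
    cx <- complexes[[gi]]; em <- embeddings_list[[gi]]; ex <- extras_list[[gi]]
    ps <- enumerate_pairs(cx, cutoff = cutoff,
                          include_hydrogens = include_hydrogens)
    if (nrow(ps$pl) > 0L) {
      Hp[[length(Hp) + 1L]] <- em$residue_emb[ps$pl$i, , drop = FALSE]
      Hl_pl[[length(Hl_pl) + 1L]] <- em$ligand_emb[ps$pl$j, , drop = FALSE]
      d_pl[[length(d_pl) + 1L]] <- ps$pl$d
      rmsd_pl[[length(rmsd_pl) + 1L]] <- rep(ex$mmff_rmsd, nrow(ps$pl))
      group_pl[[length(group_pl) + 1L]] <- rep(gi, nrow(ps$pl))
    }
    if (nrow(ps$ml) > 0L) {
      Hm[[length(Hm) + 1L]] <- em$metal_emb[ps$ml$k, , drop = FALSE]
      Hl_ml[[length(Hl_ml) + 1L]] <- em$ligand_emb[ps$ml$j, , drop = FALSE]
      d_ml[[length(d_ml) + 1L]] <- ps$ml$d
      group_ml[[length(group_ml) + 1L]] <- rep(gi, nrow(ps$ml))
    }
    dG_gw[gi] <- ex$dG_gas_to_water
    dG_wo[gi] <- ex$dG_oct_to_water
  }
  list(
    n_complex = G,
    n_pl = if (length(d_pl)) length(unlist(d_pl)) else 0L,
    Hp = if (length(Hp)) do.call(rbind, Hp) else NULL,
    Hl_pl = if (length(Hl_pl)) do.call(rbind, Hl_pl) else NULL,
    d_pl = unlist(d_pl), rmsd_pl = unlist(rmsd_pl),
    group_pl = unlist(group_pl),
    n_ml = if (length(d_ml)) length(unlist(d_ml)) else 0L,
    Hm = if (length(Hm)) do.call(rbind, Hm) else NULL,
    Hl_ml = if (length(Hl_ml)) do.call(rbind, Hl_ml) else NULL,
    d_ml = unlist(d_ml), group_ml = unlist(group_ml),
    dG_gw = dG_gw, dG_wo = dG_wo
  )
}

#' Predict binding affinity (pKd) for one pose
#'
#' `pKd = sum PL_ij + sum ML_kj + alpha_gw * dG_gas_to_water +
#' alpha_wo * dG_oct_to_water`, where the solvation coefficients are the
#' means of the pairwise readouts over the protein-ligand pairs within the
#' affinity cutoff. With no protein-ligand pair within the cutoff the
#' coefficients are undefined and set to 0 with a warning.
#'
#' @param complex an [nmdn_complex()]
#' @param embeddings an `nmdn_embeddings`
#' @param extras a [ligand_extras()]
#' @param inter an [new_interaction_params()]
#' @param cutoff affinity pair cutoff, Angstrom (default 9)
#' @param include_hydrogens include ligand hydrogens (default TRUE)
#' @return object of class `nmdn_affinity`: `pkd`, `pl_sum`, `ml_sum`,
#'   `alpha_gw`, `alpha_wo`, `solvation_correction`, per-pair contribution
#'   tables
#' @export
predict_pkd <- function(complex, embeddings, extras, inter,
                        cutoff = 9.0, include_hydrogens = TRUE) {
  stopifnot(inherits(inter, "nmdn_interaction"))
  pd <- build_pairdata(list(complex), list(embeddings), list(extras),
                       cutoff = cutoff, include_hydrogens = include_hydrogens)
  if (pd$n_pl == 0L)
    warning("no protein-ligand pairs within ", cutoff,
            " A; solvation coefficients set to 0", call. = FALSE)
  out <- interaction_forward(inter, pd)
  structure(list(
    pose_id = complex$pose_id,
    pkd = as.numeric(ad_value(out$pkd)),
    pl_sum = as.numeric(ad_value(out$pl_sum)),
    ml_sum = as.numeric(ad_value(out$ml_sum)),
    alpha_gw = as.numeric(ad_value(out$alpha_gw)),
    alpha_wo = as.numeric(ad_value(out$alpha_wo)),
    solvation_correction = as.numeric(ad_value(out$alpha_gw)) * extras$dG_gas_to_water +
      as.numeric(ad_value(out$alpha_wo)) * extras$dG_oct_to_water,
    pl_contrib = if (!is.null(out$pl_contrib)) as.numeric(ad_value(out$pl_contrib)) else numeric(0),
    ml_contrib = if (!is.null(out$ml_contrib)) as.numeric(ad_value(out$ml_contrib)) else numeric(0)
  ), class = "nmdn_affinity")
}

#' @export
print.nmdn_affinity <- function(x, ...) {
  cat(sprintf("<nmdn affinity '%s': pKd %.3f (PL %.3f, ML %.3f, solvation %.3f)>\n",
              x$pose_id, x$pkd, x$pl_sum, x$ml_sum, x$solvation_correction))
  invisible(x)
}

#' Mean absolute error affinity loss
#' @param pred predicted pKd value(s)
#' @param label experimental pKd value(s)
#' @return batch-averaged MAE
#' @export
pkd_loss <- function(pred, label) {
  mean(abs(pred - label))
}

#' Screening loss with a weak-binder hinge
#'
#' Binders contribute their absolute error. Weak binders contribute
#' `max(pred - label - 1.0, 0)`: predictions up to one log-unit above the
#' measured (weak) affinity carry no penalty, accounting for experimental
#' error, while over-prediction beyond that is penalized linearly.
#' @param pred predicted pKd value(s)
#' @param label experimental pKd value(s)
#' @param is_binder logical vector; FALSE marks weak binders
#' @return batch-averaged loss
#' @export
screen_loss <- function(pred, label, is_binder) {
  stopifnot(length(pred) == length(label), length(label) == length(is_binder))
  per <- ifelse(is_binder, abs(pred - label), pmax(pred - label - 1.0, 0))
  mean(per)
}
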