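# Interaction module: RBF expansion, gated pair contributions, affinity
# prediction and losses.

test_that("the smooth cutoff meets its boundary and shape conditions", {
  expect_equal(smooth_cutoff(0), 1.0)
  expect_equal(smooth_cutoff(10, d_star = 10), 0.0)
  expect_equal(smooth_cutoff(5, d_star = 10), 1 - 6 / 32 + 15 / 16 - 10 / 8)
  d <- seq(0, 12, by = 0.01)
  phi <- smooth_cutoff(d, 10)
  expect_true(all(diff(phi) <= 1e-12))          # monotone non-increasing
  expect_true(all(phi >= 0 & phi <= 1))
  expect_true(all(phi[d >= 10] == 0))
  # continuity of value and first derivative at d*
  eps <- 1e-6
  expect_equal(smooth_cutoff(10 - eps, 10), 0, tolerance = 1e-12)
  expect_equal((smooth_cutoff(10 - eps, 10) - smooth_cutoff(10 - 2 * eps, 10)) / eps,
               0, tolerance = 1e-9)
})

test_that("RBF expansion has 64 entries peaking at the right distances", {
  spec <- rbf_spec()
  g <- rbf_expand(3.0, spec)
  expect_equal(ncol(g), 64L)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(rbf_expand(10.0, spec) == 0))
  expect_true(all(rbf_expand(12.0, spec) == 0))
  # with very narrow widths the k-th basis dominates exactly at d = -ln(mu_k)
  narrow <- spec
  narrow$beta[] <- 1e6
  for (k in c(10L, 30L, 55L)) {
    dk <- -log(narrow$centers[1, k])
    gk <- rbf_expand(dk, narrow)
    expect_equal(gk[1, k], smooth_cutoff(dk, spec$d_star), tolerance = 1e-9)
    expect_equal(which.max(gk[1, ]), k)
  }
  # centers are initialized equally spaced between e^-10 and 1
  expect_equal(spec$centers[1, 1], exp(-10))
  expect_equal(spec$centers[1, 64], 1)
  expect_equal(max(abs(diff(as.numeric(spec$centers)) -
                         diff(spec$centers[1, 1:2]))), 0, tolerance = 1e-15)
})

test_that("the gated hidden vector is the Hadamard product of its branches", {
  inter <- new_interaction_params(8, 8, 8, hidden = 16, seed = 7)
  hp <- rnorm(8); hl <- rnorm(8); d <- 4.3
  h <- gated_pair_hidden(hp, hl, d, inter)
  expect_length(h, 16L)
  # independent re-composition
  ssp <- function(x) log(exp(x) + 1) - log(2)
  expect_equal(ssp(0), 0)
  p <- inter$params
  spec <- rbf_spec(64, inter$d_star)
  spec$centers <- p$rbf_mu; spec$beta <- p$rbf_beta
  a <- as.numeric(ssp(hp) %*% p$W_prot + p$b_prot)
  b <- as.numeric(ssp(hl) %*% p$W_lig + p$b_lig)
  g <- as.numeric(rbf_expand(d, spec) %*% p$W_dist + p$b_dist)
  expect_equal(h, a * b * g, tolerance = 1e-12)
  # zero distance branch annihilates the product
  inter0 <- inter
  inter0$params$W_dist[] <- 0; inter0$params$b_dist[] <- 0
  expect_equal(gated_pair_hidden(hp, hl, d, inter0), rep(0, 16))
})

test_that("pair contributions use the documented readout dimensions", {
  inter <- new_interaction_params(8, 8, 8, hidden = 128, seed = 8)
  h <- rnorm(128)
  pl <- pl_contribution(h, mmff_rmsd = 1.1, inter)
  expect_equal(pl$dim_in, 192L)
  ml <- ml_contribution(h, inter)
  expect_equal(ml$dim_in, 128L)
  # dot-product oracles
  p <- inter$params
  spec <- rbf_spec(64, inter$d_star)
  spec$centers <- p$rmsd_mu; spec$beta <- p$rmsd_beta
  xin <- c(h, as.numeric(rbf_expand(1.1, spec)))
  expect_equal(pl$value, sum(xin * p$W_ro) + p$b_ro[1], tolerance = 1e-12)
  expect_equal(pl$alpha_gw, sum(h * p$W_gw) + p$b_gw[1], tolerance = 1e-12)
  expect_equal(ml$value, sum(h * p$W_ro_ml) + p$b_ro_ml[1], tolerance = 1e-12)
  # zeroed readouts give zero contributions
  inter0 <- inter
  inter0$params$W_ro[] <- 0; inter0$params$b_ro[] <- 0
  expect_equal(pl_contribution(h, 1.1, inter0)$value, 0)
})

test_that("pKd decomposes into pair contributions plus solvation", {
  mdl <- tiny_model()
  cx <- gen_complex(5, 4, n_metals = 1, seed = 60)
  ex <- ligand_extras(1.4, -7.5, -1.2)
  aff <- predict(mdl, cx, type = "pkd", extras = ex)
  # independent recomposition from the per-pair tables
  recomposed <- sum(aff$pl_contrib) + sum(aff$ml_contrib) +
    aff$alpha_gw * ex$dG_gas_to_water + aff$alpha_wo * ex$dG_oct_to_water
  expect_equal(aff$pkd, recomposed, tolerance = 1e-8)
  expect_equal(aff$pkd, aff$pl_sum + aff$ml_sum + aff$solvation_correction,
               tolerance = 1e-12)
  # per-pair path agrees with the vectorized path
  em <- model_embed(mdl, cx)
  ps <- enumerate_pairs(cx, 9)
  manual <- vapply(seq_len(nrow(ps$pl)), function(r) {
    h <- gated_pair_hidden(em$residue_emb[ps$pl$i[r], ],
                           em$ligand_emb[ps$pl$j[r], ], ps$pl$d[r],
                           mdl$interaction)
    pl_contribution(h, ex$mmff_rmsd, mdl$interaction)$value
  }, numeric(1))
  expect_equal(aff$pl_contrib, manual, tolerance = 1e-10)
  # solvation coefficients are the means of the pairwise readouts
  alphas <- vapply(seq_len(nrow(ps$pl)), function(r) {
    h <- gated_pair_hidden(em$residue_emb[ps$pl$i[r], ],
                           em$ligand_emb[ps$pl$j[r], ], ps$pl$d[r],
                           mdl$interaction)
    pl_contribution(h, ex$mmff_rmsd, mdl$interaction)$alpha_gw
  }, numeric(1))
  expect_equal(aff$alpha_gw, mean(alphas), tolerance = 1e-10)
})

test_that("bumping the PL readout bias shifts pKd by pairs x delta", {
  mdl <- tiny_model()
  cx <- gen_complex(5, 4, seed = 61)
  ex <- ligand_extras(0.5, -3, -1)
  base <- predict(mdl, cx, type = "pkd", extras = ex)
  n_pl <- length(base$pl_contrib)
  delta <- 0.37
  mdl2 <- mdl
  mdl2$interaction$params$b_ro[] <- mdl2$interaction$params$b_ro[] + delta
  bumped <- predict(mdl2, cx, type = "pkd", extras = ex)
  expect_equal(bumped$pkd - base$pkd, n_pl * delta, tolerance = 1e-9)
})

test_that("pKd is invariant under rigid motions and atom reindexing", {
  mdl <- tiny_model()
  cx <- gen_complex(5, 5, n_metals = 1, seed = 62)
  ex <- ligand_extras(1.0, -6, 0.5)
  base <- predict(mdl, cx, type = "pkd", extras = ex)$pkd
  set.seed(8)
  for (rep in 1:10) {
    cxr <- apply_rigid(cx, random_rigid_motion())
    expect_equal(predict(mdl, cxr, type = "pkd", extras = ex)$pkd, base,
                 tolerance = 1e-6)
    perm <- sample(length(cx$lig_elements))
    cxp <- permute_ligand(cx, perm)
    expect_equal(predict(mdl, cxp, type = "pkd", extras = ex)$pkd, base,
                 tolerance = 1e-6)
  }
})

test_that("an isolated ligand warns and zeroes solvation coefficients", {
  res <- list(nmdn_residue("A", 1, "A", matrix(c(100, 0, 0), 1)))
  cx <- nmdn_complex(res, "C", matrix(c(0, 0, 0), 1))
  mdl <- tiny_model()
  expect_warning(aff <- predict(mdl, cx, type = "pkd",
                                extras = ligand_extras(1, -5, -1)),
                 "solvation")
  expect_equal(aff$alpha_gw, 0)
  expect_equal(aff$alpha_wo, 0)
  expect_equal(aff$pkd, 0)
})

test_that("affinity losses follow MAE and the weak-binder hinge", {
  expect_equal(pkd_loss(7.2, 7.2), 0)
  expect_equal(pkd_loss(6.0, 7.5), 1.5)
  set.seed(9)
  p <- rnorm(40, 6); l <- rnorm(40, 6)
  expect_equal(pkd_loss(p, l), mean(abs(p - l)), tolerance = 1e-12)

  expect_equal(screen_loss(6.5, 5.0, FALSE), 0.5)
  expect_equal(screen_loss(5.9, 5.0, FALSE), 0)   # inside the +1 allowance
  expect_equal(screen_loss(6.0, 7.0, TRUE), 1.0)
  # hinge is zero exactly when pred <= label + 1 for weak binders
  grid <- expand.grid(pred = seq(2, 10, by = 0.25),
                      label = seq(2, 10, by = 0.5))
  per <- vapply(seq_len(nrow(grid)), function(i)
    screen_loss(grid$pred[i], grid$label[i], FALSE), numeric(1))
  expect_true(all(per >= 0))
  expect_equal(per == 0, grid$pred <= grid$label + 1.0)
})

test_that("ligand extras tables read and validate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ligand_id,mmff_rmsd,dG_gas_to_water,dG_oct_to_water",
               "lig1,0.8,-7.2,-1.5", "lig2,1.9,-3.0,0.4"), f)
  ex <- read_ligand_extras(f)
  expect_named(ex, c("lig1", "lig2"))
  expect_equal(ex$lig2$mmff_rmsd, 1.9)
  expect_error(ligand_extras(-1, 0, 0))
})
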