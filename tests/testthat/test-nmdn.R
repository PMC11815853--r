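# Mixture density math and the normalized score.

random_mixture <- function(K = NULL) {
  if (is.null(K)) K <- sample(1:4, 1)
  w <- rexp(K); w <- w / sum(w)
  mixture_density(w, runif(K, 1, 8), runif(K, 0.1, 2))
}

test_that("mixture densities evaluate, normalize, and stay positive", {
  # standard normal peak
  m1 <- mixture_density(1, 3, 1)
  expect_equal(density_at(m1, 3), 1 / sqrt(2 * pi), tolerance = 1e-9)
  # two components average their densities
  m2 <- mixture_density(c(0.5, 0.5), c(2, 6), c(1, 1))
  expect_equal(density_at(m2, 4),
               0.5 * dnorm(4, 2, 1) + 0.5 * dnorm(4, 6, 1), tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:25) {
    m <- random_mixture()
    q <- integrate(function(r) density_at(m, r), -50, 50,
                   rel.tol = 1e-9)$value
    expect_equal(q, 1, tolerance = 1e-4)
    # positivity holds on the log scale even deep in the tails
    expect_true(all(is.finite(log_density_at(m, seq(-5, 15, by = 0.5)))))
  }
})

test_that("the distance NLL equals the independent log-sum-exp oracle", {
  set.seed(32)
  for (rep in 1:50) {
    m <- random_mixture()
    # draw d near a component so the plain-arithmetic oracle cannot underflow
    k <- sample(length(m$means), 1)
    d <- max(0.2, m$means[k] + runif(1, -2, 2) * m$sigmas[k])
    oracle <- -log(sum(m$weights * dnorm(d, m$means, m$sigmas)))
    expect_equal(nmdn_nll(m, d), oracle, tolerance = 1e-10)
  }
  # extreme distances do not underflow to -Inf/NaN
  far <- mixture_density(1, 2, 0.05)
  expect_true(is.finite(nmdn_nll(far, 8.9)))
})

test_that("the reference probability is the six-point average below ref", {
  set.seed(33)
  for (rep in 1:20) {
    m <- random_mixture()
    ref <- runif(1, 5, 10)
    pts <- c(ref - 0.5, ref - 0.4, ref - 0.3, ref - 0.2, ref - 0.1, ref)
    oracle <- mean(sapply(pts, function(p) density_at(m, p)))
    expect_equal(reference_probability(m, ref), oracle, tolerance = 1e-12)
  }
  # near-constant density over [8.5, 9]: p_ref is that constant
  flat <- mixture_density(1, 5, 500)
  expect_equal(reference_probability(flat, 9), density_at(flat, 8.75),
               tolerance = 1e-6)
})

test_that("pair scores are log ratios against the reference", {
  m <- mixture_density(c(0.7, 0.3), c(3, 6), c(0.5, 1))
  # at the distance where density equals p_ref the score crosses zero
  pref <- reference_probability(m, 9)
  dstar <- uniroot(function(d) density_at(m, d) - pref, c(6, 14),
                   tol = 1e-14)$root
  expect_equal(pair_score(m, dstar, 9), 0, tolerance = 1e-9)
  # score increases with the density at fixed reference
  ds <- seq(1, 8, by = 0.25)
  expect_equal(order(pair_score(m, ds, 9)), order(density_at(m, ds)))
  # ratio form is the exponential of the log form
  expect_equal(pair_score(m, 4, 9, form = "ratio"),
               exp(pair_score(m, 4, 9)), tolerance = 1e-12)
})

test_that("heads produce valid, deterministic mixtures", {
  head <- new_mdn_head(16, hidden = 12, n_layers = 2, n_components = 4,
                       seed = 5)
  hp <- rnorm(8); hl <- rnorm(8)
  m1 <- pair_mixture(hp, hl, head)
  m2 <- pair_mixture(hp, hl, head)
  expect_identical(m1, m2)
  expect_equal(sum(m1$weights), 1, tolerance = 1e-12)
  expect_true(all(m1$sigmas >= head$sigma_min))
  expect_error(pair_mixture(rnorm(4), hl, head), "dimension")

  # zeroed density readout weights: softmax of zero logits is uniform
  head0 <- head
  head0$params$W_rho[] <- 0
  head0$params$b_rho[] <- 0
  m0 <- pair_mixture(hp, hl, head0)
  expect_equal(m0$weights, rep(0.25, 4), tolerance = 1e-12)
})

test_that("the aggregated score sums per-pair scores and handles empties", {
  mdl <- tiny_model()
  # far-apart pair set: empty, score exactly zero
  res <- list(nmdn_residue("A", 1, "A", matrix(c(100, 0, 0), 1)))
  cx0 <- nmdn_complex(res, "C", matrix(c(0, 0, 0), 1), pose_id = "far")
  sb0 <- predict(mdl, cx0, type = "nmdn")
  expect_equal(sb0$nmdn_score, 0)

  # three-pair paired complex: total equals the sum of independent
  # pair_mixture/pair_score calls
  cx <- gen_paired_complex(c("A", "G", "L"), c("C", "O", "N"),
                           c(3.2, 5.5, 7.1))
  em <- model_embed(mdl, cx)
  sb <- predict(mdl, cx, type = "nmdn")
  manual <- sum(vapply(1:3, function(m) {
    mix <- pair_mixture(em$residue_emb[m, ], em$ligand_emb[m, ], mdl$pl_head)
    pair_score(mix, enumerate_pairs(cx, 9)$pl$d[m], 9)
  }, numeric(1)))
  expect_equal(sb$nmdn_score, manual, tolerance = 1e-9)
  expect_equal(sb$nmdn_score, sb$nmdn_pl_total + sb$nmdn_ml_total)
})

test_that("the aggregated score is invariant under rigid motions", {
  mdl <- tiny_model()
  cx <- gen_complex(5, 5, n_metals = 1, seed = 77)
  base <- predict(mdl, cx, type = "nmdn")$nmdn_score
  set.seed(7)
  for (rep in 1:10) {
    sc <- predict(mdl, apply_rigid(cx, random_rigid_motion()),
                  type = "nmdn")$nmdn_score
    expect_equal(sc, base, tolerance = 1e-6)
  }
})

test_that("pose rankings are stable across test cutoffs", {
  fx <- recovery_fixture()
  # plant all distances below the smallest cutoff tested, so every cutoff
  # sees the same pair set and the ranking comparison is apples-to-apples
  systems <- gen_pose_systems(fx$classes, n_systems = 10, n_pairs = 6,
                              n_poses = 2, seed = 19, cutoff = 5)
  for (sys in systems) {
    ranks <- sapply(c(5, 6, 7, 8, 9), function(cf) {
      s <- vapply(sys$poses, function(p) {
        em <- embed_with_baseline(fx$enc, p)
        nmdn_score(p, em, fx$head, cutoff = cf, ref_distance = cf)$nmdn_score
      }, numeric(1))
      which.max(s)
    })
    expect_length(unique(ranks), 1L)
  }
})
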