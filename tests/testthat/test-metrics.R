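# Screening and pose-selection metrics.

test_that("enrichment factors follow their definitions and bounds", {
  # 1000 ligands, 20 actives, 4 of them in the top 1% (10 ligands)
  tab <- data.frame(ligand_id = sprintf("L%04d", 1:1000),
                    score = c(seq(100, 91, length.out = 10), runif(990)),
                    is_active = c(rep(c(TRUE, FALSE), c(4, 6)),
                                  rep(c(TRUE, FALSE), c(16, 974))))
  expect_equal(enrichment_factor(tab, 0.01), (4 / 10) / (20 / 1000))

  # all actives ranked first saturates the bound
  tab2 <- data.frame(ligand_id = sprintf("L%03d", 1:100),
                     score = 100:1,
                     is_active = rep(c(TRUE, FALSE), c(5, 95)))
  ef <- enrichment_factor(tab2, 0.05)
  expect_equal(ef, 1 / 0.05)
  # brute-force recomputation on the same toy
  n_top <- ceiling(0.05 * 100)
  brute <- (sum(tab2$is_active[order(-tab2$score)][1:n_top]) / n_top) /
    (sum(tab2$is_active) / 100)
  expect_equal(ef, brute)

  # random scores average to EF ~ 1 (Monte Carlo, 3 standard errors)
  set.seed(71)
  efs <- replicate(500, {
    t3 <- data.frame(ligand_id = sprintf("L%03d", 1:200), score = rnorm(200),
                     is_active = rep(c(TRUE, FALSE), c(20, 180)))
    enrichment_factor(t3, 0.1)
  })
  expect_lt(abs(mean(efs) - 1), 3 * sd(efs) / sqrt(length(efs)))

  expect_error(enrichment_factor(
    data.frame(ligand_id = "a", score = 1, is_active = FALSE), 0.5),
    "actives")
})

test_that("fpr-mode enrichment recovers the ROC definition", {
  # scores fully separate actives from inactives: TPR = 1 at any FPR
  tab <- data.frame(ligand_id = sprintf("L%03d", 1:110),
                    score = c(rep(10, 10) + runif(10), rnorm(100)),
                    is_active = rep(c(TRUE, FALSE), c(10, 100)))
  expect_equal(enrichment_factor(tab, 0.01, mode = "fpr"), 1 / 0.01)
})

test_that("docking success counts systems with a good pose in the top k", {
  tab <- data.frame(system_id = c("s1", "s2", "s3"),
                    pose_id = "p1", score = 1,
                    rmsd = c(1.0, 2.5, 0.8))
  ds <- docking_success(tab, threshold = 2, top_k = 1)
  expect_equal(ds$rate, 2 / 3)
  expect_equal(ds$median_top1_rmsd, 1.0)

  # top-5 rescues a system whose best-scored pose is off
  tab5 <- data.frame(system_id = "s1", pose_id = paste0("p", 1:5),
                     score = c(9, 8, 7, 6, 5),
                     rmsd = c(3.1, 1.2, 4.0, 5.0, 6.0))
  expect_equal(docking_success(tab5, top_k = 1)$rate, 0)
  expect_equal(docking_success(tab5, top_k = 5)$rate, 1)

  # brute-force agreement on random systems
  set.seed(72)
  for (rep in 1:10) {
    n_sys <- sample(3:8, 1)
    tb <- do.call(rbind, lapply(seq_len(n_sys), function(s)
      data.frame(system_id = paste0("s", s),
                 pose_id = paste0("p", 1:5), score = rnorm(5),
                 rmsd = runif(5, 0, 5))))
    k <- sample(1:3, 1)
    got <- docking_success(tb, top_k = k)$rate
    brute <- mean(vapply(split(tb, tb$system_id), function(x)
      any(x$rmsd[order(-x$score)][1:k] <= 2), logical(1)))
    expect_equal(got, brute)
  }
})

test_that("ranking powers weight per-target correlations by ligand count", {
  # perfectly monotone predictions
  rp <- ranking_powers(1:10, (1:10)^3)
  expect_equal(rp$mean_spearman, 1.0)
  # two-target weighted average: (10 * 0.5 + 30 * 0.9) / 40
  set.seed(73)
  rp2 <- ranking_powers(rnorm(40), rnorm(40),
                        target = rep(c("a", "b"), c(10, 30)))
  manual <- (10 * rp2$per_target$pearson[1] + 30 * rp2$per_target$pearson[2]) / 40
  expect_equal(rp2$weighted_pearson, manual, tolerance = 1e-12)
  # spearman equals pearson on ranks
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(ranking_powers(x, y)$mean_spearman,
               cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("top-pose selection is deterministic under ties and reordering", {
  poses <- data.frame(pose_id = c("b", "a", "c"), score = c(2, 3, 1))
  expect_equal(select_top_pose(poses), "a")
  ties <- data.frame(pose_id = c("z", "m", "a"), score = c(5, 5, 1))
  expect_equal(select_top_pose(ties), "m")
  set.seed(74)
  for (rep in 1:5) {
    perm <- sample(3)
    expect_equal(select_top_pose(ties[perm, ]), "m")
  }
})

test_that("combined selection always returns the exact 1% budget", {
  mk <- function(N, overlap) {
    # overlap controls whether the two top sets coincide
    s1 <- seq(N, 1)
    s2 <- if (overlap) s1 else rev(s1)
    data.frame(ligand_id = sprintf("L%04d", 1:N), score1 = s1, score2 = s2)
  }
  # disjoint top sets: 2 + 2 = 4 selected, no augmentation needed
  sel <- combined_selection(mk(400, overlap = FALSE))
  expect_length(sel, 4L)
  expect_setequal(sel, c("L0001", "L0002", "L0399", "L0400"))
  # identical top sets: union of 2, augmented alternately to 4
  sel2 <- combined_selection(mk(400, overlap = TRUE))
  expect_length(sel2, 4L)
  expect_equal(sort(sel2), c("L0001", "L0002", "L0003", "L0004"))
  # the invariant holds across sizes and a random score pair
  set.seed(75)
  for (N in c(150, 201, 400, 1000)) {
    tb <- data.frame(ligand_id = sprintf("L%05d", 1:N),
                     score1 = rnorm(N), score2 = rnorm(N))
    expect_length(combined_selection(tb), ceiling(0.01 * N))
  }
})

test_that("ligand RMSD honors translations and graph symmetry", {
  bz <- benzene_pose()
  expect_equal(ligand_rmsd(bz$coords, bz$coords, bz$elements), 0)
  shifted <- sweep(bz$coords, 2, c(1, 0, 0), "+")
  expect_equal(ligand_rmsd(bz$coords, shifted, bz$elements), 1.0,
               tolerance = 1e-12)
  # rotate the ring by one position (60 degrees): zero only with symmetry
  perm <- c(2:6, 1, 8:12, 7)
  rotated <- bz$coords[perm, ]
  plain <- ligand_rmsd(bz$coords, rotated, bz$elements)
  expect_gt(plain, 0.5)
  sym <- ligand_rmsd(bz$coords, rotated, bz$elements, bonds = bz$bonds,
                     symmetry_aware = TRUE)
  expect_equal(sym, 0, tolerance = 1e-9)
})
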