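# Structure parsing and pair enumeration.

test_that("PDB loading finds residues and metals, honoring the metal list", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f)
  pr <- load_protein(f)
  expect_length(pr$residues, 2L)
  expect_equal(vapply(pr$residues, `[[`, character(1), "aa_code"), c("A", "G"))
  expect_equal(pr$metal_elements, "Zn")

  # excluding Zn from the metal list drops the ion but keeps residues
  pr2 <- load_protein(f, metal_list = c("Mg", "Ca"))
  expect_length(pr2$residues, 2L)
  expect_length(pr2$metal_elements, 0L)

  expect_error(load_protein(withr::local_tempfile(fileext = ".pdb")), "read")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f1, altloc = TRUE)
  write_toy_pdb(f2, altloc = FALSE)
  pr <- load_protein(f1)
  # residue count unchanged, one CB kept, and it is the occupancy-0.70 copy
  expect_length(pr$residues, 2L)
  ala <- pr$residues[[1]]
  expect_equal(nrow(ala$heavy_atom_coords), 3L)
  cb <- ala$heavy_atom_coords[3L, ]
  expect_equal(cb, c(2.0, 1.2, 0.0))
  expect_equal(nrow(load_protein(f2)$residues[[1]]$heavy_atom_coords), 3L)
})

test_that("SDF poses parse, normalize elements, and reject unsupported ones", {
  cx <- gen_complex(4, 5, seed = 21)
  f <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(list(cx, cx, cx), f)
  poses <- load_ligand_poses(f)
  expect_length(poses, 3L)
  expect_true(all(vapply(poses, function(p) length(p$elements), integer(1)) == 5L))
  expect_equal(poses[[1]]$coords, unname(cx$lig_coords), tolerance = 1e-4)

  # benzene: 6 C + 6 H
  fb <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(list(benzene_pose()), fb)
  pb <- load_ligand_poses(fb)[[1]]
  expect_equal(sum(pb$elements == "C"), 6L)
  expect_equal(sum(pb$elements == "H"), 6L)

  # a record containing Fe is rejected with a diagnostic naming it
  bad <- list(elements = c("C", "Fe", "O"), coords = matrix(rnorm(9), 3),
              title = "fe-ligand")
  ff <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(list(bad, benzene_pose()), ff)
  expect_warning(pf <- load_ligand_poses(ff), "Fe")
  expect_length(pf, 1L)
  expect_equal(attr(pf, "rejected")$record, 1L)

  # upper-case CL is normalized to Cl
  clp <- list(elements = c("C", "CL"), coords = matrix(c(0, 0, 0, 1.7, 0, 0.4),
                                                       2, byrow = TRUE))
  fc <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(list(clp), fc)
  expect_equal(load_ligand_poses(fc)[[1]]$elements, c("C", "Cl"))
})

test_that("flat records without z spread are flagged as 2D-only", {
  flat <- list(elements = rep("C", 5),
               coords = cbind(rnorm(5), rnorm(5), 0))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(list(flat), f)
  expect_error(load_ligand_poses(f), "2D")
})

test_that("V2000 parsing agrees with ChemmineR and V3000 records load", {
  cx <- gen_complex(3, 6, seed = 31)
  f <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(list(cx), f)
  mine <- load_ligand_poses(f)[[1]]
  sd <- suppressWarnings(ChemmineR::read.SDFset(f))
  ab <- ChemmineR::atomblock(sd[[1]])
  expect_equal(nrow(ab), length(mine$elements))
  expect_equal(unname(ab[, 1:3]), unname(mine$coords), tolerance = 1e-4)
  expect_equal(gsub("_\\d+$", "", rownames(ab)), mine$elements)

  # V3000 record with the same content
  v3 <- c("benzene", "  synthetic", "",
          "  0  0  0  0  0  0  0  0  0  0999 V3000",
          "M  V30 BEGIN CTAB", "M  V30 COUNTS 2 1 0 0 0",
          "M  V30 BEGIN ATOM",
          "M  V30 1 C 0.0 0.0 0.1 0", "M  V30 2 O 1.2 0.0 0.3 0",
          "M  V30 END ATOM",
          "M  V30 BEGIN BOND", "M  V30 1 2 1 2", "M  V30 END BOND",
          "M  V30 END CTAB", "M  END", "$$$$")
  f3 <- withr::local_tempfile(fileext = ".sdf")
  writeLines(v3, f3)
  p3 <- load_ligand_poses(f3)[[1]]
  expect_equal(p3$elements, c("C", "O"))
  expect_equal(p3$coords[2, ], c(1.2, 0.0, 0.3))
  expect_equal(p3$bonds[1, 1:2], c(atom1 = 1L, atom2 = 2L))
})

test_that("pair distances are residue-minimum distances within the cutoff", {
  res <- nmdn_residue("A", 1, "A", matrix(c(0, 0, 0), 1))
  cx <- nmdn_complex(list(res), "C", matrix(c(3, 4, 0), 1), pose_id = "t1")
  ps <- enumerate_pairs(cx, cutoff = 9)
  expect_equal(ps$pl$d, 5.0)
  expect_equal(nrow(enumerate_pairs(cx, cutoff = 4)$pl), 0L)

  # multi-atom residue: minimum over its atoms
  res2 <- nmdn_residue("A", 1, "A", rbind(c(0, 0, 0), c(2, 0, 0)))
  cx2 <- nmdn_complex(list(res2), "C", matrix(c(5, 0, 0), 1))
  expect_equal(enumerate_pairs(cx2, 9)$pl$d, 3.0)

  # ligand hydrogens excluded on request
  cxh <- nmdn_complex(list(res), c("C", "H"),
                      rbind(c(3, 0, 0), c(4, 0, 0)))
  expect_equal(nrow(enumerate_pairs(cxh, 9, include_hydrogens = TRUE)$pl), 2L)
  expect_equal(nrow(enumerate_pairs(cxh, 9, include_hydrogens = FALSE)$pl), 1L)
})

test_that("pair enumeration matches the brute-force double loop", {
  for (seed in 1:20) {
    cx <- gen_complex(5, 8, n_metals = 1, seed = seed, within_fraction = 0.6)
    ps <- enumerate_pairs(cx, cutoff = 9)
    brute <- NULL
    for (i in seq_along(cx$residues)) {
      for (j in seq_along(cx$lig_elements)) {
        ds <- apply(cx$residues[[i]]$heavy_atom_coords, 1L, function(a)
          sqrt(sum((a - cx$lig_coords[j, ])^2)))
        d <- min(ds)
        if (d <= 9 && d > 0) brute <- rbind(brute, c(i, j, d))
      }
    }
    if (is.null(brute)) {
      expect_equal(nrow(ps$pl), 0L)
    } else {
      expect_equal(nrow(ps$pl), nrow(brute))
      expect_equal(ps$pl$d, brute[order(brute[, 1], brute[, 2]), 3],
                   tolerance = 1e-12)
    }
    mb <- NULL
    for (k in seq_along(cx$metal_elements)) {
      for (j in seq_along(cx$lig_elements)) {
        d <- sqrt(sum((cx$metal_coords[k, ] - cx$lig_coords[j, ])^2))
        if (d <= 9 && d > 0) mb <- rbind(mb, d)
      }
    }
    expect_equal(nrow(ps$ml), if (is.null(mb)) 0L else nrow(mb))
  }
})

test_that("pair sets are rigid-motion invariant and nested across cutoffs", {
  set.seed(42)
  cx <- gen_complex(6, 6, n_metals = 1, seed = 50)
  ps <- enumerate_pairs(cx, 9)
  for (rep in 1:5) {
    cxr <- apply_rigid(cx, random_rigid_motion())
    psr <- enumerate_pairs(cxr, 9)
    expect_equal(psr$pl$d, ps$pl$d, tolerance = 1e-6)
    expect_equal(psr$ml$d, ps$ml$d, tolerance = 1e-6)
  }
  for (c1 in c(5, 6, 7, 8)) {
    small <- enumerate_pairs(cx, c1)$pl
    big <- enumerate_pairs(cx, 9)$pl
    key <- function(tb) paste(tb$i, tb$j)
    expect_true(all(key(small) %in% key(big)))
  }
})

test_that("pair sets export to TSV", {
  cx <- gen_complex(4, 4, n_metals = 1, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairset_tsv(enumerate_pairs(cx, 9), f)
  tab <- read.delim(f)
  expect_named(tab, c("pose_id", "kind", "i", "j", "d"))
  expect_true(all(tab$d <= 9))
})
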