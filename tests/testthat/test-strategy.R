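test_that("the protocol cascade follows the thresholds with strict boundaries", {
  cfg <- pipeline_config()
  expect_identical(choose_protocol(0.6, 2, cfg)$protocol, "TETHERED")
  expect_identical(choose_protocol(0.4, 6, cfg)$protocol, "PH4")
  expect_identical(choose_protocol(0.4, 3, cfg)$protocol, "FREE")
  ## equality at either boundary falls through
  expect_identical(choose_protocol(0.5, 0, cfg)$protocol, "FREE")
  expect_identical(choose_protocol(0.5, 5, cfg)$protocol, "FREE")
  expect_identical(choose_protocol(0.5, 6, cfg)$protocol, "PH4")
  ## the legacy development-phase preset raises the tether cutoff to 0.65
  legacy <- pipeline_config(preset = "legacy")
  expect_identical(legacy$tether_threshold, 0.65)
  expect_identical(choose_protocol(0.6, 2, legacy)$protocol, "FREE")
  expect_identical(choose_protocol(0.66, 2, legacy)$protocol, "TETHERED")
})

test_that("exactly one protocol is chosen everywhere on the decision plane", {
  cfg <- pipeline_config()
  eps <- 1e-9
  for (tm in c(0, 0.3, 0.5, 0.5 + eps, 0.65, 1)) {
    for (nd in c(0L, 5L, 6L, 20L)) {
      dec <- choose_protocol(tm, nd, cfg)
      expect_true(dec$protocol %in% c("TETHERED", "PH4", "FREE"))
      expected <- if (tm > 0.5) "TETHERED" else if (nd > 5L) "PH4" else "FREE"
      expect_identical(dec$protocol, expected,
                       info = sprintf("tmcss=%g n=%d", tm, nd))
    }
  }
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(99)
  pts <- matrix(rnorm(15, sd = 2), ncol = 3)
  ## identity
  fit <- kabsch_superpose(pts, pts)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$fit_rmsd, 0, tolerance = 1e-9)
  ## pure translation
  fit <- kabsch_superpose(sweep(pts, 2, c(3, 4, 0), "+"), pts)
  expect_equal(fit$translation, c(-3, -4, 0), tolerance = 1e-9)
  expect_equal(fit$fit_rmsd, 0, tolerance = 1e-9)
  ## known rotation + translation is recovered to 1e-6
  moved <- rigid_move(pts)
  fit <- kabsch_superpose(moved, pts)
  aligned <- sweep(moved %*% fit$rotation, 2, fit$translation, "+")
  expect_equal(aligned, pts, tolerance = 1e-6)
  expect_lt(fit$fit_rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  ## guard rails
  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "3 paired points")
  expect_error(kabsch_superpose(pts, pts[1:3, ]), "equal length")
  col <- cbind(1:4, 0, 0)
  expect_true(kabsch_superpose(col, col)$degenerate)
})

test_that("fit RMSD is invariant under a joint rigid move of both point sets", {
  set.seed(5)
  a <- matrix(rnorm(18), ncol = 3)
  b <- a + matrix(rnorm(18, sd = 0.3), ncol = 3)
  r0 <- kabsch_superpose(a, b)$fit_rmsd
  r1 <- kabsch_superpose(rigid_move(a), rigid_move(b))$fit_rmsd
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("tether preparation superposes the MCS and annotates 1-based indices", {
  tol <- mol_toluene()
  displaced <- tol
  displaced$coords <- rigid_move(tol$coords)
  teth <- prepare_tethered_ligand(displaced, tol, find_mcs(displaced, tol))
  expect_equal(teth$coords, tol$coords, tolerance = 1e-6)
  expect_identical(teth$properties[["TETHERED ATOMS"]], "1,2,3,4,5,6,7")

  ## toluene onto benzene: the ring lands on the ring
  benz <- mol_benzene()
  mcs <- find_mcs(tol, benz)
  expect_identical(mcs$n_ab, 6L)
  teth2 <- prepare_tethered_ligand(tol, benz, mcs)
  idx <- as.integer(strsplit(teth2$properties[["TETHERED ATOMS"]], ",")[[1L]])
  expect_identical(length(idx), 6L)
  expect_identical(idx, sort(idx))
  ring_rmsd <- sqrt(mean(rowSums((teth2$coords[mcs$atom_map[, 1L], ] -
                                    benz$coords[mcs$atom_map[, 2L], ])^2)))
  expect_lt(ring_rmsd, 1e-6)

  small <- structure(list(n_a = 7L, n_b = 6L, n_ab = 2L,
                          atom_map = cbind(a = 1:2, b = 1:2)),
                     class = "mcs_result")
  expect_error(prepare_tethered_ligand(tol, benz, small), "fall back")
})

test_that("tethering preserves internal geometry exactly (rigid transform only)", {
  for (seed in 1:10) {
    mol <- random_coords(random_small_molecule(seed, max_atoms = 8L), seed + 100L)
    ref <- mol
    ref$coords <- rigid_move(mol$coords, angles = c(0.1, 0.2, 0.3) * seed,
                             shift = c(seed, -seed, 2))
    if (length(mol$elements) < 3L) next
    teth <- prepare_tethered_ligand(mol, ref, find_mcs(mol, ref))
    expect_equal(as.matrix(dist(teth$coords)), as.matrix(dist(mol$coords)),
                 tolerance = 1e-6)
  }
})

test_that("the cavity parameter file uses the reference-ligand mapper and is byte-stable", {
  dir <- withr::local_tempdir()
  rec <- file.path(dir, "r.mol2"); lig <- file.path(dir, "l.sdf")
  writeLines("RECEPTOR", rec)
  write_sdf(list(mol_benzene()), lig)
  out1 <- file.path(dir, "cav1.prm"); out2 <- file.path(dir, "cav2.prm")
  write_cavity_prm(rec, lig, out1)
  lines <- readLines(out1)
  expect_true(any(grepl("RbtLigandSiteMapper", lines)))
  expect_true(any(grepl(paste("RECEPTOR_FILE", rec), lines, fixed = TRUE)))
  expect_true(any(grepl(paste("REF_MOL", lig), lines, fixed = TRUE)))
  write_cavity_prm(rec, lig, out2)
  expect_identical(readLines(out1), readLines(out2))

  cp <- consensus_v2(list(mol_benzene(), mol_benzene()))
  out3 <- file.path(dir, "cav3.prm")
  write_cavity_prm(rec, lig, out3, pharmacophore = cp)
  lines3 <- readLines(out3)
  expect_true(any(grepl("SECTION PHARMA", lines3)))
  expect_true(any(grepl("CONSTRAINTS_FILE", lines3)))
  expect_error(write_cavity_prm(file.path(dir, "nope.mol2"), lig, out1), "missing")
})
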