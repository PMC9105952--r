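test_that("feature perception follows the rule table", {
  benz <- mol_benzene()
  f <- perceive_features(benz)
  expect_identical(f$ftype, "AROM")
  expect_equal(unlist(f[1, c("x", "y", "z")], use.names = FALSE),
               colMeans(benz$coords), tolerance = 1e-9)

  meoh <- embed_molecule(read_smiles("CO methanol")[[1L]])
  f <- perceive_features(meoh)
  expect_setequal(f$ftype, c("HDON", "HACC"))
  o_pos <- meoh$coords[2L, ]
  for (k in seq_len(nrow(f)))
    expect_equal(unlist(f[k, c("x", "y", "z")], use.names = FALSE), o_pos)

  eth <- mol_ethane()
  f <- perceive_features(eth)
  expect_identical(f$ftype, "LIPO")
  expect_equal(unlist(f[1, c("x", "y", "z")], use.names = FALSE),
               colMeans(eth$coords))

  charged <- embed_molecule(read_smiles("[NH3+]CC(=O)[O-] glycine_zwit")[[1L]])
  f <- perceive_features(charged)
  expect_true("POSC" %in% f$ftype)
  expect_true("NEGC" %in% f$ftype)

  expect_error(perceive_features(read_smiles("CCO x")[[1L]]), "coordinates")
})

test_that("ligand clustering groups identical molecules and isolates dissimilar ones", {
  benz <- mol_benzene(); hex <- embed_molecule(read_smiles("CCCCCC hexane")[[1L]])
  copies <- c(lapply(1:5, function(k) { m <- benz; m$id <- paste0("b", k); m }),
              lapply(1:3, function(k) { m <- hex; m$id <- paste0("h", k); m }))
  cl <- cluster_ligands(copies, cutoff = 0.9)
  expect_length(cl$clusters, 2L)
  expect_length(cl$representatives, 2L)
  sizes <- sort(lengths(cl$clusters))
  expect_identical(sizes, c(3L, 5L))

  distinct <- list(mol_benzene(), hex,
                   embed_molecule(read_smiles("[NH3+]CC(=O)[O-] zwit")[[1L]]))
  cl2 <- cluster_ligands(distinct, cutoff = 0.9)
  expect_length(cl2$clusters, 3L)

  one <- cluster_ligands(list(benz))
  expect_identical(one$representatives, "benzene")
  expect_identical(one$clusters[[1L]], "benzene")
})

test_that("version-1 consensus keeps the two groups with most appearances", {
  ## four identical aligned ligands: every group has count 4
  benz <- mol_benzene()
  fsets <- lapply(1:4, function(k) perceive_features(benz))
  names(fsets) <- paste0("m", 1:4)
  ## add a second shared feature by hand so there are two groups
  for (k in seq_along(fsets))
    fsets[[k]] <- rbind(fsets[[k]],
                        data.frame(ftype = "HACC", x = 5, y = 0, z = 0,
                                   radius = 1, support = 1))
  cp <- consensus_v1(fsets)
  expect_s3_class(cp, "consensus_pharmacophore")
  expect_identical(nrow(cp$mandatory), 2L)
  expect_identical(nrow(cp$optional), 0L)
  expect_equal(cp$mandatory$support, c(1, 1))

  ## constructed group counts {AROM: 5, HACC: 3, LIPO: 2} -> top 2 kept
  mk <- function(id, types) {
    rows <- list(AROM = c(0, 0, 0), HACC = c(4, 0, 0), LIPO = c(-4, 0, 0))
    df <- do.call(rbind, lapply(types, function(tt)
      data.frame(ftype = tt, x = rows[[tt]][1], y = rows[[tt]][2],
                 z = rows[[tt]][3], radius = 1, support = 1)))
    df
  }
  fs <- list(a = mk("a", c("AROM", "HACC", "LIPO")),
             b = mk("b", c("AROM", "HACC", "LIPO")),
             c = mk("c", c("AROM", "HACC")),
             d = mk("d", c("AROM")),
             e = mk("e", c("AROM")))
  cp2 <- consensus_v1(fs)
  expect_setequal(cp2$mandatory$ftype, c("AROM", "HACC"))
  expect_equal(sort(cp2$mandatory$support, decreasing = TRUE), c(1, 3 / 5))

  ## only one shared group: emitted with a warning
  two <- list(p = data.frame(ftype = "HDON", x = 0, y = 0, z = 0, radius = 1, support = 1),
              q = data.frame(ftype = "HDON", x = 0.2, y = 0, z = 0, radius = 1, support = 1))
  expect_warning(cp3 <- consensus_v1(two), "shared")
  expect_identical(nrow(cp3$mandatory), 1L)
})

test_that("version-2 consensus applies the support brackets to planted features", {
  s <- gen_series(series_spec(seed = 42, n_ligands = 10,
                              planted_features = list(
                                list(ftype = "HDON", position = 1, fraction = 0.8),
                                list(ftype = "HACC", position = 3, fraction = 0.3),
                                list(ftype = "LIPO", position = 5, fraction = 0.1))))
  cp <- consensus_v2(s$ligands)
  expect_identical(cp$n_ligands_used, 10L)
  near <- function(df, ft, centre, tol = 0.75) {
    hit <- df$ftype == ft &
      sqrt((df$x - centre[1])^2 + (df$y - centre[2])^2 + (df$z - centre[3])^2) < tol
    df[hit, , drop = FALSE]
  }
  tr <- s$truth$features
  hdon <- near(cp$mandatory, "HDON", unlist(tr[tr$ftype == "HDON", c("x", "y", "z")]))
  expect_identical(nrow(hdon), 1L)
  expect_equal(hdon$support, 0.8)
  hacc <- near(cp$optional, "HACC", unlist(tr[tr$ftype == "HACC", c("x", "y", "z")]))
  expect_identical(nrow(hacc), 1L)
  expect_equal(hacc$support, 0.3)
  lipo_centre <- unlist(tr[tr$ftype == "LIPO", c("x", "y", "z")])
  expect_identical(nrow(near(cp$mandatory, "LIPO", lipo_centre)), 0L)
  expect_identical(nrow(near(cp$optional, "LIPO", lipo_centre)), 0L)
  ## supports are exact fractions of contributing ligands
  expect_true(all(cp$mandatory$support * cp$n_ligands_used ==
                    round(cp$mandatory$support * cp$n_ligands_used)))
  ## mandatory/optional lists respect the brackets and are disjoint
  expect_true(all(cp$mandatory$support > 0.45))
  expect_true(all(cp$optional$support >= 0.20 & cp$optional$support <= 0.44))
})

test_that("consensus is invariant to ligand input order", {
  s <- gen_series(series_spec(seed = 7, n_ligands = 8,
                              planted_features = list(
                                list(ftype = "HDON", position = 1, fraction = 0.5),
                                list(ftype = "HACC", position = 4, fraction = 0.25))))
  canon <- function(cp) {
    f <- function(df) {
      df <- df[order(df$ftype, round(df$x, 6), round(df$y, 6), round(df$z, 6)), ]
      rownames(df) <- NULL
      df[, c("ftype", "x", "y", "z", "support")]
    }
    list(m = f(cp$mandatory), o = f(cp$optional))
  }
  base <- canon(consensus_v2(s$ligands))
  set.seed(1)
  for (rep in 1:5) {
    shuffled <- sample(s$ligands)
    expect_equal(canon(consensus_v2(shuffled)), base)
  }
})

test_that("restraint files use the rDock sphere dialect and round-trip", {
  cp <- structure(list(
    mandatory = data.frame(ftype = "AROM", x = 1, y = 2, z = 3,
                           radius = 1, support = 1),
    optional = data.frame(ftype = character(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), radius = numeric(0), support = numeric(0)),
    protocol_version = 2L, n_ligands_used = 4L),
    class = "consensus_pharmacophore")
  mand <- withr::local_tempfile(fileext = ".const")
  opt <- withr::local_tempfile(fileext = ".const")
  write_restraint_files(cp, mand, opt)
  expect_identical(readLines(mand), "1.000 2.000 3.000 1.000 AROM")
  expect_false(file.exists(opt))    # optional file omitted when empty

  cp$optional <- data.frame(ftype = c("HACC", "LIPO"), x = c(-1.5, 0.25),
                            y = c(0, 1), z = c(2, -3), radius = c(1, 2),
                            support = c(0.3, 0.25))
  write_restraint_files(cp, mand, opt)
  got_m <- read_restraint_file(mand)
  got_o <- read_restraint_file(opt)
  expect_equal(got_m$x, cp$mandatory$x)
  expect_identical(got_o$ftype, cp$optional$ftype)
  expect_equal(got_o[, c("x", "y", "z", "radius")],
               cp$optional[, c("x", "y", "z", "radius")])
  expect_identical(PH4_NOPT, 1L)
})
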