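test_that("Tanimoto coefficient follows c / (a + b - c)", {
  mk <- function(on) { v <- integer(166); v[on] <- 1L; v }
  a <- mk(1:5); b <- mk(3:6)            # |a|=5, |b|=4, |a&b|=3 -> 3/6
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(mk(1:3), mk(10:12)), 0.0)
  expect_equal(tanimoto(integer(166), integer(166)), 0.0)   # all-zero pair
  expect_error(tanimoto(integer(166), integer(10)), "mismatch")
})

test_that("MACCS fingerprints are deterministic 166-bit keys with sensible content", {
  benz <- mol_benzene()
  f1 <- maccs_fingerprint(benz)
  f2 <- maccs_fingerprint(benz)
  expect_identical(unclass(f1), unclass(f2))
  expect_length(unclass(f1), 166L)
  ## ring / aromatic / six-ring keys of the published dictionary
  expect_true(all(unclass(f1)[c(162L, 163L, 165L)] == 1L))
  ## halogen key (number 134) must be unset for benzene
  expect_identical(unclass(f1)[134L], 0L)
  expect_identical(unclass(maccs_fingerprint(read_smiles("[Cl]c1ccccc1 cb")[[1L]]))[134L], 1L)
  ## degenerate single-atom molecule still fingerprints
  methane <- read_smiles("C methane")[[1L]]
  expect_length(unclass(maccs_fingerprint(methane)), 166L)
})

test_that("MCS of a molecule with itself is the identity", {
  tol <- mol_toluene()
  m <- find_mcs(tol, tol)
  expect_identical(m$n_ab, 7L)
  expect_identical(m$atom_map[order(m$atom_map[, 1L]), 1L],
                   m$atom_map[order(m$atom_map[, 1L]), 2L])
  expect_equal(tanimoto_mcss(m), 1.0)
})

test_that("benzene vs toluene share the aromatic ring (NAB = 6, Tanimoto 6/7)", {
  m <- find_mcs(mol_benzene(), mol_toluene())
  expect_identical(m$n_ab, 6L)
  expect_equal(tanimoto_mcss(m), 6 / 7)
  ## the ring-atoms-match-ring-atoms rule keeps chains out of rings
  m2 <- find_mcs(mol_ethane(), mol_benzene())
  expect_identical(m2$n_ab, 0L)
})

test_that("MCS equals the exhaustive oracle on random small molecules", {
  mols <- lapply(1:12, random_small_molecule, max_atoms = 7L)
  for (i in seq_along(mols)) {
    for (j in seq(i, length(mols))) {
      m <- find_mcs(mols[[i]], mols[[j]])
      expect_identical(m$n_ab, oracle_mcs_size(mols[[i]], mols[[j]]),
                       info = sprintf("pair %d-%d", i, j))
      ## symmetry of the similarity in its arguments
      expect_identical(m$n_ab, find_mcs(mols[[j]], mols[[i]])$n_ab)
    }
  }
})

test_that("the MCS atom map is a valid common-subgraph mapping", {
  a <- mol_toluene(); b <- embed_molecule(read_smiles("Cc1ccccc1Cl clt")[[1L]])
  m <- find_mcs(a, b)
  expect_identical(nrow(m$atom_map), m$n_ab)
  expect_false(anyDuplicated(m$atom_map[, 1L]) > 0)
  expect_false(anyDuplicated(m$atom_map[, 2L]) > 0)
  expect_identical(a$elements[m$atom_map[, 1L]], b$elements[m$atom_map[, 2L]])
  expect_true(m$n_ab <= min(m$n_a, m$n_b))
})

test_that("tanimoto_mcss is monotone in NAB and bounded", {
  for (nab in 0:6) {
    m <- structure(list(n_a = 6L, n_b = 8L, n_ab = nab), class = "mcs_result")
    v <- tanimoto_mcss(m)
    expect_true(v >= 0 && v <= 1)
    if (nab > 0) {
      prev <- tanimoto_mcss(structure(list(n_a = 6L, n_b = 8L, n_ab = nab - 1L),
                                      class = "mcs_result"))
      expect_true(v > prev)
    }
  }
})

test_that("similarity_table composes the scalar scores and keeps input order", {
  q <- mol_toluene()
  refs <- list(mol_benzene(), mol_toluene(), mol_ethane())
  tab <- similarity_table(q, refs)
  expect_identical(tab$ref_id, c("benzene", "toluene", "ethane"))
  expect_equal(tab$combined, tab$tanimoto_maccs + tab$tanimoto_mcss)
  ## agrees with independent calls of the scalar operations
  fq <- maccs_fingerprint(q)
  for (k in seq_along(refs)) {
    expect_equal(tab$tanimoto_maccs[k], tanimoto(fq, maccs_fingerprint(refs[[k]])))
    expect_equal(tab$tanimoto_mcss[k], tanimoto_mcss(find_mcs(q, refs[[k]])))
  }
  ## the query against itself is a perfect match
  self <- similarity_table(q, list(q))
  expect_equal(self$combined, 2.0)
  expect_error(similarity_table(q, list()), "no retrieved ligands")
})

test_that("reference-ligand selection maximizes the combined score with lexicographic ties", {
  tab <- data.frame(ref_id = c("A", "B", "C"), combined = c(1.2, 1.7, 0.4))
  expect_identical(select_reference_ligand(tab), "B")
  tie <- data.frame(ref_id = c("B", "A"), combined = c(1.5, 1.5))
  expect_identical(select_reference_ligand(tie), "A")
  single <- data.frame(ref_id = "Z", combined = 0.1)
  expect_identical(select_reference_ligand(single), "Z")
  expect_error(select_reference_ligand(data.frame()), "empty")
})

test_that("cavity ranking is descending by MCS score with stable lexicographic ties", {
  benz <- mol_benzene()
  cav <- function(id, s) cavity_candidate(id, list(benz), "benzene", s)
  got <- rank_cavities(list(cav("c1", 0.3), cav("c2", 0.8)))
  expect_identical(vapply(got, `[[`, character(1), "cavity_id"), c("c2", "c1"))
  one <- rank_cavities(list(cav("only", 0.5)))
  expect_identical(one[[1L]]$cavity_id, "only")
  tied <- rank_cavities(list(cav("b", 0.5), cav("a", 0.5)))
  expect_identical(vapply(tied, `[[`, character(1), "cavity_id"), c("a", "b"))
  expect_error(rank_cavities(list()), "no cavities")
})
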