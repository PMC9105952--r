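## Shared fixture builders: everything is constructed in code at test time.

mol_benzene <- function() embed_molecule(read_smiles("c1ccccc1 benzene")[[1L]])
mol_toluene <- function() embed_molecule(read_smiles("Cc1ccccc1 toluene")[[1L]])
mol_ethane  <- function() embed_molecule(read_smiles("CC ethane")[[1L]])

## a seeded random heavy-atom graph (no aromatic rings: any ring formed by
## the single extra edge has all-single bonds, so bond labels are literal
## orders for both the package and the oracles)
random_small_molecule <- function(seed, max_atoms = 8L, id = paste0("rnd_", seed)) {
  set.seed(seed)
  n <- sample(2:max_atoms, 1L)
  elements <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  bonds <- NULL
  for (k in seq(2L, n)) {
    anchor <- sample(seq_len(k - 1L), 1L)
    bonds <- rbind(bonds, c(anchor, k, 1L))
  }
  make_ring <- stats::runif(1) < 0.4 && n >= 3L
  if (make_ring) {
    pair <- sort(sample(n, 2L))
    present <- any(bonds[, 1L] == pair[1L] & bonds[, 2L] == pair[2L])
    if (!present && pair[2L] - pair[1L] > 1L)
      bonds <- rbind(bonds, c(pair[1L], pair[2L], 1L))
  } else {
    ## a couple of double bonds on tree edges
    k2 <- sample(nrow(bonds), min(nrow(bonds), sample(0:2, 1L)))
    bonds[k2, 3L] <- 2L
  }
  molecule_record(id, elements, coords = NULL, bonds = bonds)
}

random_coords <- function(mol, seed) {
  set.seed(seed)
  out <- mol
  out$coords <- matrix(stats::rnorm(3L * length(mol$elements), sd = 2), ncol = 3L)
  out
}

## apply a rigid rotation (Euler angles) + translation to a coordinate matrix
rigid_move <- function(coords, angles = c(0.3, -0.5, 0.9), shift = c(1, -2, 3)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  sweep(coords %*% t(rz %*% ry %*% rx), 2L, shift, "+")
}
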