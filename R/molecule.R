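#' Construct a molecule record
#'
#' The basic container used throughout the package: a heavy-atom-only small
#' molecule with an optional 3D conformer and an ordered map of SD data
#' fields. Hydrogens are never stored; similarity, maximum common
#' substructure and RMSD are all defined over heavy atoms, and hydrogen
#' counts are recovered from standard valences when needed (e.g. for
#' donor perception).
#'
#' @param id character label for the molecule.
#' @param elements character vector of element symbols, one per heavy atom.
#' @param coords numeric matrix with one `(x, y, z)` row per atom, in
#'   Angstrom, or `NULL` for connectivity-only input (e.g. SMILES).
#' @param bonds integer matrix with columns `i`, `j`, `order`; `i`, `j` are
#'   1-based atom indices, `order` is 1, 2, 3 or 4 (4 = aromatic as in the
#'   MDL dialect). Zero-row matrix for a single-atom molecule.
#' @param charges integer vector of formal charges, one per atom
#'   (default all zero).
#' @param properties named list of SD tag -> character value, order
#'   preserved on write.
#'
#' @return An object of class `molecule_record`.
#' @export
molecule_record <- function(id, elements, coords = NULL, bonds = NULL,
                            charges = NULL, properties = list()) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("molecule '", id, "': at least one heavy atom required")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 3L)
  bonds <- matrix(as.integer(bonds), ncol = 3L,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (nrow(bonds) > 0L) {
    if (any(bonds[, 1L] == bonds[, 2L]))
      stop("molecule '", id, "': self-bond")
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n))
      stop("molecule '", id, "': bond endpoint out of range")
  }
  if (!is.null(coords)) {
    coords <- matrix(as.numeric(coords), ncol = 3L)
    if (nrow(coords) != n)
      stop("molecule '", id, "': coords must have one row per atom")
  }
  if (is.null(charges)) charges <- integer(n)
  charges <- as.integer(charges)
  if (length(charges) != n)
    stop("molecule '", id, "': charges must have one entry per atom")
  stopifnot(is.list(properties))
  structure(list(id = as.character(id), elements = elements, coords = coords,
                 bonds = bonds, charges = charges, properties = properties),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record '%s': %d heavy atoms, %d bonds, %s, %d SD fields>\n",
              x$id, length(x$elements), nrow(x$bonds),
              if (is.null(x$coords)) "no coords" else "3D",
              length(x$properties)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

has_coords <- function(mol) !is.null(mol$coords)

## adjacency list: for each atom, matrix of (neighbour, bond order)
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[k, 1L]; j <- mol$bonds[k, 2L]; o <- mol$bonds[k, 3L]
    adj[[i]] <- rbind(adj[[i]], c(j, o, k))
    adj[[j]] <- rbind(adj[[j]], c(i, o, k))
  }
  adj
}

## connected components over an arbitrary neighbour list
graph_components <- function(n, nbrs) {
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nbrs[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

## Smallest ring through each bond, collected as a deduplicated ring list.
## BFS-based perception; adequate for the single- and fused-ring systems the
## pipeline handles (max ring size considered: 8).
ring_info <- function(mol, max_size = 8L) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  nbrs <- lapply(adj, function(a) if (is.null(a)) integer(0) else a[, 1L])
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[k, 1L]; j <- mol$bonds[k, 2L]
    ## shortest path i..j avoiding the direct bond
    prev <- integer(n); dist <- rep(NA_integer_, n)
    dist[i] <- 0L; queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nbrs[[v]]) {
        if (v == i && w == j) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[j]) || dist[j] + 1L > max_size) next
    path <- j
    while (path[[1L]] != i) path <- c(prev[path[[1L]]], path)
    key <- paste(sort(path), collapse = "-")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  in_ring <- rep(FALSE, n)
  for (r in rings) in_ring[r] <- TRUE
  list(rings = rings, in_ring = in_ring)
}

STD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                 F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L)

## Sum of bond orders at each atom; aromatic (order 4) counts 1.5.
bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  ords <- ifelse(mol$bonds[, 3L] == 4L, 1.5, as.numeric(mol$bonds[, 3L]))
  for (k in seq_len(nrow(mol$bonds))) {
    s[mol$bonds[k, 1L]] <- s[mol$bonds[k, 1L]] + ords[k]
    s[mol$bonds[k, 2L]] <- s[mol$bonds[k, 2L]] + ords[k]
  }
  s
}

#' Implicit hydrogen counts
#'
#' Recovered from standard valences (C4, N3, O2, S2, P3, halogens 1),
#' adjusted by formal charge (+1 raises the valence of N/O by one, -1
#' lowers it by one), minus the heavy-atom bond order sum with aromatic
#' bonds counted as 1.5. Negative results clamp to zero.
#'
#' @param mol a [molecule_record()].
#' @return integer vector, one count per atom.
#' @export
implicit_h <- function(mol) {
  val <- STD_VALENCE[mol$elements]
  val[is.na(val)] <- 0L
  val <- val + ifelse(mol$elements %in% c("N", "O", "S", "P"), mol$charges, 0L)
  h <- floor(val - bond_order_sum(mol) + 1e-9)
  as.integer(pmax(h, 0L))
}

## Aromatic ring perception over a possibly kekulized graph.
## A ring is aromatic if (a) any of its bonds is written with MDL order 4, or
## (b) it has 5 or 6 members, all C/N/O/S, and every atom is either part of an
## alternating single/double Kekule pattern within the ring or is a
## lone-pair-donating heteroatom (N/O/S with no ring double bond), with a
## pi-electron count of 6 (Hueckel for the single rings handled here).
aromatic_rings <- function(mol) {
  ri <- ring_info(mol)
  if (!length(ri$rings)) return(list(rings = list(), atom = rep(FALSE, n_atoms(mol)),
                                     bond = rep(FALSE, nrow(mol$bonds))))
  bkey <- paste(pmin(mol$bonds[, 1L], mol$bonds[, 2L]),
                pmax(mol$bonds[, 1L], mol$bonds[, 2L]))
  border <- mol$bonds[, 3L]
  arom <- list()
  for (r in ri$rings) {
    m <- length(r)
    ringb <- integer(m)
    for (t in seq_len(m)) {
      a <- r[t]; b <- r[if (t == m) 1L else t + 1L]
      ringb[t] <- match(paste(min(a, b), max(a, b)), bkey)
    }
    if (any(border[ringb] == 4L)) { arom[[length(arom) + 1L]] <- r; next }
    if (!(m %in% c(5L, 6L))) next
    if (!all(mol$elements[r] %in% c("C", "N", "O", "S"))) next
    ndl <- border[ringb] == 2L
    pi_e <- 0L; ok <- TRUE
    for (t in seq_len(m)) {
      a <- r[t]
      prevb <- ringb[if (t == 1L) m else t - 1L]
      has_dbl <- border[ringb[t]] == 2L || border[prevb] == 2L
      if (has_dbl) pi_e <- pi_e + 1L
      else if (mol$elements[a] %in% c("N", "O", "S")) pi_e <- pi_e + 2L
      else { ok <- FALSE; break }
    }
    if (ok && sum(ndl) >= 2L && pi_e == 6L) arom[[length(arom) + 1L]] <- r
  }
  atom <- rep(FALSE, n_atoms(mol))
  bond <- border == 4L
  for (r in arom) {
    atom[r] <- TRUE
    m <- length(r)
    for (t in seq_len(m)) {
      a <- r[t]; b <- r[if (t == m) 1L else t + 1L]
      bond[match(paste(min(a, b), max(a, b)), bkey)] <- TRUE
    }
  }
  list(rings = arom, atom = atom, bond = bond)
}

## Per-bond label used for matching: "ar" for bonds in aromatic rings,
## otherwise the integer order as character.
bond_labels <- function(mol, arom = aromatic_rings(mol)) {
  lab <- as.character(mol$bonds[, 3L])
  lab[arom$bond] <- "ar"
  lab
}

## Stable identity on the chemistry-bearing parts of a record (used by tests
## and round-trip checks): graph + coords to 4 decimals + properties.
mol_signature <- function(mol) {
  b <- mol$bonds
  if (nrow(b)) {
    swap <- b[, 1L] > b[, 2L]
    b[swap, 1:2] <- b[swap, 2:1]
    b <- b[order(b[, 1L], b[, 2L]), , drop = FALSE]
  }
  list(id = mol$id, elements = mol$elements,
       coords = if (has_coords(mol)) round(mol$coords, 4L),
       bonds = b, charges = mol$charges, properties = mol$properties)
}
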