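## Independent oracles used to validate the package's search algorithms.
## They share only the match-rule *definitions* (element equality, ring
## membership, literal bond order) and use exhaustive enumeration instead
## of the package's branch-and-bound / backtracking code paths.

## independent ring-membership: edge (i,j) lies on a cycle iff j is still
## reachable from i after removing that edge; an atom is in a ring iff it
## is an endpoint of such an edge
oracle_in_ring <- function(mol) {
  n <- length(mol$elements)
  bonds <- mol$bonds
  reach <- function(from, to, skip) {
    seen <- rep(FALSE, n); seen[from] <- TRUE; queue <- from
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(bonds))) {
        if (k == skip) next
        w <- if (bonds[k, 1L] == v) bonds[k, 2L] else if (bonds[k, 2L] == v)
          bonds[k, 1L] else next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen[to]
  }
  in_ring <- rep(FALSE, n)
  for (k in seq_len(nrow(bonds))) {
    if (reach(bonds[k, 1L], bonds[k, 2L], k)) in_ring[bonds[k, 1:2]] <- TRUE
  }
  in_ring
}

## exhaustive connected-common-subgraph size. Enumerates the connected atom
## subsets of A (largest first; a common connected subgraph uses A-bonds, so
## its atom set must be connected in A) and, for each, all element/ring-
## compatible injections into B; a subset counts if its matched bonds (same
## literal order on both sides) connect it. Intended for <= 8 heavy atoms.
oracle_mcs_size <- function(a, b) {
  na <- length(a$elements); nb <- length(b$elements)
  ring_a <- oracle_in_ring(a); ring_b <- oracle_in_ring(b)
  order_matrix <- function(mol, n) {
    M <- matrix(NA_integer_, n, n)
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1L]; j <- mol$bonds[k, 2L]
      M[i, j] <- M[j, i] <- mol$bonds[k, 3L]
    }
    M
  }
  Oa <- order_matrix(a, na); Ob <- order_matrix(b, nb)
  compat <- outer(seq_len(na), seq_len(nb), Vectorize(function(i, j) {
    a$elements[i] == b$elements[j] && ring_a[i] == ring_b[j]
  }))
  ## all connected subsets of A's bond graph, grown one neighbour at a time
  ## and deduplicated by sorted-key
  nbra <- lapply(seq_len(na), function(i) which(!is.na(Oa[i, ])))
  seen <- new.env(parent = emptyenv())
  subsets <- list()
  push <- function(S) {
    key <- paste(sort(S), collapse = ",")
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      subsets[[length(subsets) + 1L]] <<- sort(S)
      TRUE
    } else FALSE
  }
  expand <- function(S) {
    for (w in setdiff(unique(unlist(nbra[S])), S)) {
      if (push(c(S, w))) expand(c(S, w))
    }
  }
  for (i in seq_len(na)) { push(i); expand(i) }
  sizes <- lengths(subsets)
  ord <- order(-sizes)
  matched_connected <- function(S, map) {
    m <- length(S)
    if (m == 1L) return(TRUE)
    seen2 <- rep(FALSE, m); seen2[1L] <- TRUE; queue <- 1L
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (q in seq_len(m)) {
        if (seen2[q]) next
        oa <- Oa[S[p], S[q]]
        if (!is.na(oa) && !is.na(Ob[map[p], map[q]]) && Ob[map[p], map[q]] == oa) {
          seen2[q] <- TRUE; queue <- c(queue, q)
        }
      }
    }
    all(seen2)
  }
  embeds <- function(S) {
    m <- length(S)
    ## order positions by image scarcity
    ncomp <- vapply(S, function(u) sum(compat[u, ]), integer(1))
    if (any(ncomp == 0L)) return(FALSE)
    S <- S[order(ncomp)]
    try_map <- function(pos, map, used) {
      if (pos > m) return(matched_connected(S, map))
      for (v in which(compat[S[pos], ] & !used)) {
        used[v] <- TRUE
        if (try_map(pos + 1L, c(map, v), used)) return(TRUE)
        used[v] <- FALSE
      }
      FALSE
    }
    try_map(1L, integer(0), rep(FALSE, nb))
  }
  best <- 0L
  for (k in ord) {
    S <- subsets[[k]]
    if (length(S) <= best || length(S) > nb) next
    if (embeds(S)) best <- length(S)
  }
  best
}

## all permutations of a vector (tiny n)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (rest in all_perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
  }
  out
}

## brute-force symmetry-corrected RMSD: minimum over all element-preserving
## permutations whose permuted bond set (with literal orders) equals the
## original. Intended for element classes of <= 6 atoms, non-aromatic input.
brute_symmetry_rmsd <- function(pred, ref) {
  n <- length(ref$elements)
  canon_bonds <- function(bonds) {
    if (!nrow(bonds)) return(character(0))
    sort(paste(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]),
               bonds[, 3L]))
  }
  target <- canon_bonds(ref$bonds)
  classes <- split(seq_len(n), ref$elements)
  class_perms <- lapply(classes, all_perms)
  grids <- expand.grid(lapply(class_perms, seq_along))
  best <- Inf
  for (g in seq_len(nrow(grids))) {
    perm <- integer(n)
    for (ci in seq_along(classes))
      perm[classes[[ci]]] <- class_perms[[ci]][[grids[g, ci]]]
    pb <- ref$bonds
    pb[, 1L] <- perm[pb[, 1L]]; pb[, 2L] <- perm[pb[, 2L]]
    if (!identical(canon_bonds(pb), target)) next
    d <- pred$coords - ref$coords[perm, , drop = FALSE]
    best <- min(best, sqrt(mean(rowSums(d^2))))
  }
  best
}

## the 12 symmetry operations of a hexagonal ring, as atom permutations
hexagon_symmetries <- function() {
  rots <- lapply(0:5, function(s) ((seq_len(6L) - 1L + s) %% 6L) + 1L)
  refls <- lapply(rots, rev)
  c(rots, refls)
}
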