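## Fingerprint and maximum-common-substructure similarity between the query
## ligand and ligands retrieved from similar binding pockets.

#' MACCS 166-key structural fingerprint
#'
#' Computes the published 166 MACCS structural keys through Open Babel's
#' implementation (\pkg{ChemmineOB}); the padded 256-bit vector returned by
#' Open Babel is trimmed to the 166 defined keys.
#'
#' @param mol a [molecule_record()].
#' @return object of class `maccs_fp`: an integer 0/1 vector of length 166.
#' @export
maccs_fingerprint <- function(mol) {
  obm <- ChemmineOB::forEachMol("SDF", sdf_text(mol), identity)
  fp <- ChemmineOB::fingerprint_OB(obm, "MACCS")
  bits <- if (is.null(dim(fp))) fp[seq_len(166L)] else fp[1L, seq_len(166L)]
  structure(as.integer(bits), class = "maccs_fp")
}

#' Tanimoto coefficient between two bit sets
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both fingerprints are all-zero.
#'
#' @param a,b equal-length 0/1 vectors (e.g. from [maccs_fingerprint()]).
#' @return numeric in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(unclass(a)); b <- as.integer(unclass(b))
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  both <- sum(a & b)
  either <- sum(a | b)
  if (either == 0L) 0 else both / either
}

#' MCS match options
#'
#' Atom/bond matching rules for [find_mcs()]: atoms match by element, ring
#' atoms only match ring atoms, bonds match by order with aromatic treated
#' as its own order, and the common substructure must be connected.
#'
#' @param ring_matches_ring require equal ring membership for matched atoms.
#' @param timeout seconds per molecule pair before the search stops and the
#'   best mapping found so far is returned flagged partial.
#' @param max_steps backstop on search-tree extensions, for the same purpose.
#' @return list of options for [find_mcs()].
#' @export
mcs_params <- function(ring_matches_ring = TRUE, timeout = 60, max_steps = 5e6) {
  list(ring_matches_ring = ring_matches_ring, timeout = timeout,
       max_steps = max_steps)
}

#' Maximum common substructure of two molecules
#'
#' Finds the largest connected common subgraph under the match rules of
#' [mcs_params()], by branch-and-bound extension of partial atom mappings
#' (McGregor-style search). The enumeration order is canonical, so the
#' result is deterministic for fixed inputs; when several maximum mappings
#' exist the first found is kept and the multiplicity is recorded.
#'
#' @param mol_a,mol_b [molecule_record()]s.
#' @param params see [mcs_params()].
#' @return object of class `mcs_result`: list with `n_a`, `n_b`, `n_ab`,
#'   `atom_map` (an `n_ab` x 2 matrix of paired 1-based indices, A then B),
#'   `partial` (logical: search hit its cap), `multiplicity`.
#' @export
find_mcs <- function(mol_a, mol_b, params = mcs_params()) {
  na <- n_atoms(mol_a); nb <- n_atoms(mol_b)
  ring_a <- ring_info(mol_a)$in_ring
  ring_b <- ring_info(mol_b)$in_ring
  lab_a <- bond_labels(mol_a)
  lab_b <- bond_labels(mol_b)
  adj_a <- adjacency(mol_a)
  adj_b <- adjacency(mol_b)
  compat <- outer(seq_len(na), seq_len(nb), Vectorize(function(i, j) {
    mol_a$elements[i] == mol_b$elements[j] &&
      (!params$ring_matches_ring || ring_a[i] == ring_b[j])
  }))

  best <- new.env(parent = emptyenv())
  best$map <- matrix(integer(0), ncol = 2L)
  best$size <- 0L
  best$mult <- 0L
  best$steps <- 0L
  best$partial <- FALSE
  deadline <- Sys.time() + params$timeout

  ## Frontier atoms of A: unmapped, not excluded, connected to the mapped set
  ## through at least one bond whose label matches a bond to an unmapped,
  ## compatible atom of B. Returns the smallest such atom and its partners.
  frontier_choice <- function(mapped_a, mapped_b, map_ab, avail_a) {
    for (u in seq_len(na)) {
      if (!avail_a[u]) next
      aa <- adj_a[[u]]
      if (is.null(aa)) next
      vs <- integer(0)
      for (r in seq_len(nrow(aa))) {
        u2 <- aa[r, 1L]
        if (is.na(map_ab[u2])) next
        lu <- lab_a[aa[r, 3L]]
        bb <- adj_b[[map_ab[u2]]]
        if (is.null(bb)) next
        for (s in seq_len(nrow(bb))) {
          v <- bb[s, 1L]
          if (v %in% mapped_b || !compat[u, v]) next
          if (lab_b[bb[s, 3L]] == lu) vs <- c(vs, v)
        }
      }
      if (length(vs)) return(list(u = u, vs = sort(unique(vs))))
    }
    NULL
  }

  ## Canonical enumeration: at each node branch on the smallest extendable
  ## frontier atom of A (map it to each feasible partner, or exclude it for
  ## the rest of the subtree). Each connected mapping is visited exactly once,
  ## so `multiplicity` counts distinct maximum mappings.
  recurse <- function(mapped_a, mapped_b, map_ab, avail_a) {
    best$steps <- best$steps + 1L
    if (best$steps %% 2048L == 0L && Sys.time() > deadline) {
      best$partial <- TRUE
      return()
    }
    if (best$steps > params$max_steps) { best$partial <- TRUE; return() }
    size <- length(mapped_a)
    if (size > best$size) {
      best$size <- size
      best$map <- cbind(mapped_a, mapped_b)
      best$mult <- 1L
    } else if (size == best$size && size > 0L) {
      best$mult <- best$mult + 1L
    }
    if (size + min(sum(avail_a), nb - size) <= best$size) return()
    ch <- frontier_choice(mapped_a, mapped_b, map_ab, avail_a)
    if (is.null(ch)) return()
    u <- ch$u
    avail_a[u] <- FALSE
    for (v in ch$vs) {
      map_ab[u] <- v
      recurse(c(mapped_a, u), c(mapped_b, v), map_ab, avail_a)
      map_ab[u] <- NA_integer_
      if (best$partial) return()
    }
    ## branch: u permanently excluded below this node
    recurse(mapped_a, mapped_b, map_ab, avail_a)
  }

  map_ab <- rep(NA_integer_, na)
  seeds <- which(compat, arr.ind = TRUE)
  if (nrow(seeds)) {
    seeds <- seeds[order(seeds[, 1L], seeds[, 2L]), , drop = FALSE]
    for (k in seq_len(nrow(seeds))) {
      i <- seeds[k, 1L]; j <- seeds[k, 2L]
      if (1L + min(na - 1L, nb - 1L) <= best$size) break
      ## seed (i, j): i is the smallest A atom of every mapping in this
      ## subtree (smaller A atoms are pre-excluded), so no mapping is
      ## generated from two different seeds.
      avail_a <- rep(TRUE, na)
      avail_a[seq_len(i)] <- FALSE
      map_ab[i] <- j
      recurse(i, j, map_ab, avail_a)
      map_ab[i] <- NA_integer_
      if (best$partial) break
    }
  }
  if (best$partial)
    warning("MCS search for '", mol_a$id, "' vs '", mol_b$id,
            "' hit its cap; returning largest mapping found so far")
  structure(list(n_a = na, n_b = nb, n_ab = best$size,
                 atom_map = matrix(as.integer(best$map), ncol = 2L,
                                   dimnames = list(NULL, c("a", "b"))),
                 partial = best$partial, multiplicity = best$mult),
            class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("<mcs_result: NA=%d NB=%d NAB=%d%s>\n", x$n_a, x$n_b, x$n_ab,
              if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Size-aware Tanimoto similarity built on the MCS
#'
#' `NAB / (NA + NB - NAB)` where `NA`, `NB` are the heavy-atom counts of the
#' two molecules and `NAB` the heavy-atom count of their maximum common
#' substructure; 1 exactly when the molecules are identical.
#'
#' @param mcs an `mcs_result` from [find_mcs()].
#' @return numeric in `[0, 1]`.
#' @export
tanimoto_mcss <- function(mcs) {
  stopifnot(inherits(mcs, "mcs_result"))
  mcs$n_ab / (mcs$n_a + mcs$n_b - mcs$n_ab)
}

#' Similarity table between a query and retrieved ligands
#'
#' One row per reference ligand, in input order: MACCS Tanimoto, MCS-based
#' Tanimoto, their sum (the combined score used to pick the docking
#' reference ligand), and the MCS sizes.
#'
#' @param query a [molecule_record()].
#' @param refs non-empty list of [molecule_record()]s.
#' @param params MCS options, see [mcs_params()].
#' @return data.frame with columns `query_id`, `ref_id`, `tanimoto_maccs`,
#'   `tanimoto_mcss`, `combined`, `n_a`, `n_b`, `n_ab`.
#' @export
similarity_table <- function(query, refs, params = mcs_params()) {
  if (!length(refs))
    stop("no retrieved ligands: similarity analysis impossible (free docking applies)")
  fq <- maccs_fingerprint(query)
  rows <- lapply(refs, function(ref) {
    mcs <- find_mcs(query, ref, params)
    tm <- tanimoto(fq, maccs_fingerprint(ref))
    ts <- tanimoto_mcss(mcs)
    data.frame(query_id = query$id, ref_id = ref$id,
               tanimoto_maccs = tm, tanimoto_mcss = ts, combined = tm + ts,
               n_a = mcs$n_a, n_b = mcs$n_b, n_ab = mcs$n_ab,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the docking reference ligand
#'
#' The retrieved ligand with the maximum combined score (MACCS Tanimoto +
#' MCS Tanimoto); ties broken by lexicographically smallest `ref_id`.
#'
#' @param table data.frame from [similarity_table()].
#' @return the selected `ref_id` (character scalar).
#' @export
select_reference_ligand <- function(table) {
  if (is.null(table) || !nrow(table)) stop("empty similarity table")
  ord <- order(-table$combined, table$ref_id)
  table$ref_id[ord[1L]]
}

#' Construct a cavity candidate
#'
#' A candidate binding site carrying the aligned ligands found in it, the
#' reference ligand chosen for it, and that ligand's MCS Tanimoto score to
#' the query (the score cavities are ranked by).
#'
#' @param cavity_id character label.
#' @param ligands list of aligned 3D [molecule_record()]s.
#' @param reference_ligand_id id of one of `ligands`.
#' @param mcss_score the reference ligand's `tanimoto_mcss` to the query.
#' @return object of class `cavity_candidate`.
#' @export
cavity_candidate <- function(cavity_id, ligands, reference_ligand_id, mcss_score) {
  ids <- vapply(ligands, function(m) m$id, character(1))
  if (!(reference_ligand_id %in% ids))
    stop("reference ligand '", reference_ligand_id, "' not among cavity ligands")
  stopifnot(mcss_score >= 0, mcss_score <= 1)
  structure(list(cavity_id = as.character(cavity_id), ligands = ligands,
                 reference_ligand_id = reference_ligand_id,
                 mcss_score = mcss_score),
            class = "cavity_candidate")
}

#' Rank cavities by MCS score
#'
#' Descending by each cavity's reference-ligand MCS Tanimoto score; ties by
#' lexicographic `cavity_id` (stable, documented).
#'
#' @param cavities non-empty list of [cavity_candidate()]s.
#' @return the list reordered.
#' @export
rank_cavities <- function(cavities) {
  if (!length(cavities)) stop("no cavities to rank")
  scores <- vapply(cavities, function(cv) cv$mcss_score, numeric(1))
  ids <- vapply(cavities, function(cv) cv$cavity_id, character(1))
  cavities[order(-scores, ids)]
}
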