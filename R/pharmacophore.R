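## Pharmacophore feature perception on aligned 3D ligands and consensus
## restraint elucidation (two protocol versions).

PH4_TYPES <- c("AROM", "HDON", "HACC", "LIPO", "POSC", "NEGC")

ph4_point <- function(ftype, center, radius = 1.0, support = 1.0) {
  stopifnot(ftype %in% PH4_TYPES, radius > 0, support > 0, support <= 1)
  list(ftype = ftype, center = as.numeric(center), radius = radius,
       support = support)
}

ph4_df <- function(points) {
  if (!length(points)) {
    return(data.frame(ftype = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), radius = numeric(0), support = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(points, function(p) {
    data.frame(ftype = p$ftype, x = p$center[1], y = p$center[2],
               z = p$center[3], radius = p$radius, support = p$support,
               stringsAsFactors = FALSE)
  }))
}

#' Perceive pharmacophore feature points on a 3D molecule
#'
#' The rule table (normative for this package, an approximation of the
#' Align-it feature definitions):
#' * `AROM` at the centroid of each aromatic ring;
#' * `HDON` at N/O atoms bearing at least one (implicit) hydrogen;
#' * `HACC` at N/O atoms with a free lone pair (formal charge <= 0; aromatic
#'   N only when it bears no hydrogen);
#' * `LIPO` at the centroid of each connected group of >= 2 apolar carbons
#'   (non-aromatic C not bonded to N, O or a charged atom);
#' * `POSC`/`NEGC` at atoms with positive/negative formal charge.
#'
#' @param mol a [molecule_record()] with 3D coordinates.
#' @param radius sphere radius assigned to every emitted point (Angstrom).
#' @return data.frame with columns `ftype`, `x`, `y`, `z`, `radius`,
#'   `support` (always 1 for a single molecule).
#' @export
perceive_features <- function(mol, radius = 1.0) {
  if (!has_coords(mol)) stop("feature perception requires 3D coordinates")
  arom <- aromatic_rings(mol)
  hcnt <- implicit_h(mol)
  adj <- adjacency(mol)
  pts <- list()
  for (r in arom$rings) {
    pts[[length(pts) + 1L]] <- ph4_point("AROM", colMeans(mol$coords[r, , drop = FALSE]),
                                         radius)
  }
  for (k in seq_len(n_atoms(mol))) {
    el <- mol$elements[k]
    if (el %in% c("N", "O")) {
      if (hcnt[k] >= 1L)
        pts[[length(pts) + 1L]] <- ph4_point("HDON", mol$coords[k, ], radius)
      acceptor <- mol$charges[k] <= 0L &&
        !(el == "N" && arom$atom[k] && hcnt[k] >= 1L)
      if (acceptor)
        pts[[length(pts) + 1L]] <- ph4_point("HACC", mol$coords[k, ], radius)
    }
    if (mol$charges[k] > 0L)
      pts[[length(pts) + 1L]] <- ph4_point("POSC", mol$coords[k, ], radius)
    if (mol$charges[k] < 0L)
      pts[[length(pts) + 1L]] <- ph4_point("NEGC", mol$coords[k, ], radius)
  }
  ## lipophilic groups: components of apolar carbons with >= 2 members
  apolar <- vapply(seq_len(n_atoms(mol)), function(k) {
    if (mol$elements[k] != "C" || arom$atom[k] || mol$charges[k] != 0L) return(FALSE)
    nb <- adj[[k]]
    if (is.null(nb)) return(TRUE)
    nbe <- mol$elements[nb[, 1L]]
    !any(nbe %in% c("N", "O")) && !any(mol$charges[nb[, 1L]] != 0L)
  }, logical(1))
  if (any(apolar)) {
    idx <- which(apolar)
    nbrs <- lapply(idx, function(k) {
      nb <- adj[[k]]
      if (is.null(nb)) return(integer(0))
      match(intersect(nb[, 1L], idx), idx)
    })
    comp <- graph_components(length(idx), nbrs)
    for (cpt in unique(comp)) {
      members <- idx[comp == cpt]
      if (length(members) >= 2L)
        pts[[length(pts) + 1L]] <- ph4_point("LIPO",
                                             colMeans(mol$coords[members, , drop = FALSE]),
                                             radius)
    }
  }
  ph4_df(pts)
}

#' Cluster ligands by MACCS fingerprint similarity
#'
#' Single-linkage clusters where an edge joins two ligands iff their
#' pairwise MACCS Tanimoto similarity is at least `cutoff`. The
#' representative (centroid) of each cluster is the member with the highest
#' mean similarity to its cluster, ties broken by lexicographic id.
#'
#' @param ligands non-empty list of [molecule_record()]s.
#' @param cutoff Tanimoto similarity threshold (default 0.9).
#' @return list with `clusters` (list of character id vectors),
#'   `representatives` (character vector, one id per cluster), and
#'   `representative_mols` (the corresponding records).
#' @export
cluster_ligands <- function(ligands, cutoff = 0.9) {
  stopifnot(length(ligands) >= 1L)
  ids <- vapply(ligands, function(m) m$id, character(1))
  n <- length(ligands)
  fps <- lapply(ligands, maccs_fingerprint)
  sim <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      sim[i, j] <- sim[j, i] <- tanimoto(fps[[i]], fps[[j]])
    }
  }
  nbrs <- lapply(seq_len(n), function(i) setdiff(which(sim[i, ] >= cutoff), i))
  comp <- graph_components(n, nbrs)
  clusters <- list(); reps <- character(0); rep_mols <- list()
  for (cpt in sort(unique(comp))) {
    members <- which(comp == cpt)
    mean_sim <- vapply(members, function(i) mean(sim[i, members]), numeric(1))
    ord <- order(-mean_sim, ids[members])
    rep_i <- members[ord[1L]]
    clusters[[length(clusters) + 1L]] <- ids[members]
    reps <- c(reps, ids[rep_i])
    rep_mols[[length(rep_mols) + 1L]] <- ligands[[rep_i]]
  }
  list(clusters = clusters, representatives = reps,
       representative_mols = rep_mols)
}

## Greedy spatial grouping of per-ligand feature points.
## Points (rows of rbind-ed perceive_features outputs, plus a ligand column)
## are first put in canonical order (ftype, x, y, z, ligand) so grouping is
## invariant to ligand input order; groups are then seeded from the point
## with the most same-type neighbours within `tol`.
group_points <- function(pts, tol) {
  if (!nrow(pts)) return(list())
  ord <- order(pts$ftype, round(pts$x, 6), round(pts$y, 6), round(pts$z, 6),
               pts$ligand)
  pts <- pts[ord, , drop = FALSE]
  n <- nrow(pts)
  coords <- as.matrix(pts[, c("x", "y", "z")])
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    same <- pts$ftype == pts$ftype[i]
    d2 <- rowSums((coords - matrix(coords[i, ], n, 3, byrow = TRUE))^2)
    nbr[[i]] <- which(same & d2 <= tol^2)
  }
  assigned <- rep(FALSE, n)
  groups <- list()
  repeat {
    sizes <- vapply(seq_len(n), function(i) {
      if (assigned[i]) -1L else length(nbr[[i]][!assigned[nbr[[i]]]])
    }, integer(1))
    if (all(sizes < 1L)) break
    seed <- which.max(sizes)   # ties: first in canonical order
    members <- nbr[[seed]][!assigned[nbr[[seed]]]]
    assigned[members] <- TRUE
    groups[[length(groups) + 1L]] <- pts[members, , drop = FALSE]
  }
  groups
}

consensus_result <- function(mandatory, optional, protocol_version, n_ligands_used) {
  structure(list(mandatory = mandatory, optional = optional,
                 protocol_version = protocol_version,
                 n_ligands_used = n_ligands_used),
            class = "consensus_pharmacophore")
}

#' @export
print.consensus_pharmacophore <- function(x, ...) {
  cat(sprintf("<consensus_pharmacophore v%d: %d mandatory, %d optional (from %d ligands)>\n",
              x$protocol_version, nrow(x$mandatory), nrow(x$optional),
              x$n_ligands_used))
  invisible(x)
}

#' Consensus pharmacophore, protocol version 1
#'
#' Features common between molecules are spatially grouped (same type,
#' centers within `tol`), ranked by the number of distinct ligands in which
#' they appear, and the two highest-ranked shared groups become mandatory
#' restraints. No optional restraints are produced in this protocol.
#'
#' @param feature_sets named list: ligand id -> data.frame from
#'   [perceive_features()]. At least 2 ligands.
#' @param tol same-type center distance tolerance in Angstrom.
#' @param radius restraint sphere radius in Angstrom.
#' @return a `consensus_pharmacophore` (protocol_version 1).
#' @export
consensus_v1 <- function(feature_sets, tol = 1.5, radius = 1.0) {
  stopifnot(length(feature_sets) >= 2L)
  pts <- do.call(rbind, lapply(names(feature_sets), function(id) {
    fs <- feature_sets[[id]]
    if (!nrow(fs)) return(NULL)
    fs$ligand <- id
    fs
  }))
  n <- length(feature_sets)
  groups <- group_points(pts, tol)
  counts <- vapply(groups, function(g) length(unique(g$ligand)), integer(1))
  shared <- which(counts >= 2L)
  if (length(shared) < 2L)
    warning("only ", length(shared),
            " feature group(s) shared by >= 2 ligands; emitting those")
  take <- shared[order(-counts[shared])][seq_len(min(2L, length(shared)))]
  mandatory <- do.call(rbind, lapply(take, function(k) {
    g <- groups[[k]]
    data.frame(ftype = g$ftype[1L], x = mean(g$x), y = mean(g$y), z = mean(g$z),
               radius = radius, support = counts[k] / n,
               stringsAsFactors = FALSE)
  }))
  if (is.null(mandatory)) mandatory <- ph4_df(list())
  consensus_result(mandatory, ph4_df(list()), 1L, n)
}

#' Consensus pharmacophore, protocol version 2
#'
#' Feature points are perceived per ligand (the inputs should be cluster
#' representatives from [cluster_ligands()], so redundancy is already
#' removed), spatially grouped, and each group's support is the fraction of
#' ligands contributing to it. Groups with support above `mandatory_support`
#' (strict) become mandatory restraints; groups with support inside the
#' closed optional bracket become optional restraints; anything below is
#' dropped. Supports falling in the gap between the optional bracket and
#' the mandatory cutoff are dropped with a message rather than silently
#' bridged.
#'
#' @param ligands non-empty list of 3D [molecule_record()]s (representatives).
#' @param tol grouping tolerance in Angstrom.
#' @param radius restraint sphere radius in Angstrom.
#' @param mandatory_support strict lower bound for mandatory (default 0.45).
#' @param optional_lo,optional_hi closed support bracket for optional
#'   (defaults 0.20 and 0.44).
#' @return a `consensus_pharmacophore` (protocol_version 2). Both lists
#'   empty signals that the pipeline should fall back to free docking.
#' @export
consensus_v2 <- function(ligands, tol = 1.5, radius = 1.0,
                         mandatory_support = 0.45,
                         optional_lo = 0.20, optional_hi = 0.44) {
  stopifnot(length(ligands) >= 1L)
  n <- length(ligands)
  pts <- do.call(rbind, lapply(ligands, function(m) {
    fs <- perceive_features(m, radius)
    if (!nrow(fs)) return(NULL)
    fs$ligand <- m$id
    fs
  }))
  groups <- if (is.null(pts)) list() else group_points(pts, tol)
  mand <- list(); opt <- list()
  for (g in groups) {
    support <- length(unique(g$ligand)) / n
    row <- data.frame(ftype = g$ftype[1L], x = mean(g$x), y = mean(g$y),
                      z = mean(g$z), radius = radius, support = support,
                      stringsAsFactors = FALSE)
    if (support > mandatory_support) {
      mand[[length(mand) + 1L]] <- row
    } else if (support >= optional_lo && support <= optional_hi) {
      opt[[length(opt) + 1L]] <- row
    } else if (support > optional_hi && support <= mandatory_support) {
      message(sprintf("feature %s support %.3f falls between the optional bracket and the mandatory cutoff; dropped",
                      row$ftype, support))
    }
  }
  bind <- function(lst) if (length(lst)) do.call(rbind, lst) else ph4_df(list())
  consensus_result(bind(mand), bind(opt), 2L, n)
}

#' Write rDock-dialect pharmacophore restraint files
#'
#' One sphere per line, `x y z radius TYPE`, coordinates in Angstrom with 3
#' decimals. Mandatory and optional points go to separate files; the
#' optional file is only created when there are optional points. The
#' docking-engine semantic for optional restraints is "at least one must be
#' satisfied" (see [PH4_NOPT]).
#'
#' @param cp a `consensus_pharmacophore`.
#' @param mandatory_path output path for mandatory restraints.
#' @param optional_path output path for optional restraints.
#' @return character vector of the paths actually written, invisibly.
#' @export
write_restraint_files <- function(cp, mandatory_path, optional_path) {
  stopifnot(inherits(cp, "consensus_pharmacophore"))
  if (!nrow(cp$mandatory) && !nrow(cp$optional))
    stop("empty consensus pharmacophore: nothing to write")
  fmt <- function(df) sprintf("%.3f %.3f %.3f %.3f %s",
                              df$x, df$y, df$z, df$radius, df$ftype)
  written <- character(0)
  writeLines(fmt(cp$mandatory), mandatory_path)
  written <- mandatory_path
  if (nrow(cp$optional)) {
    writeLines(fmt(cp$optional), optional_path)
    written <- c(written, optional_path)
  }
  invisible(written)
}

#' Number of optional pharmacophore restraints that must be satisfied
#'
#' Configuration constant handed to the docking engine together with the
#' optional restraint file ("at least one of them needed to be fulfilled").
#' @export
PH4_NOPT <- 1L

#' Read a restraint file written by [write_restraint_files()]
#'
#' @param path restraint file path.
#' @return data.frame with columns `ftype`, `x`, `y`, `z`, `radius`.
#' @export
read_restraint_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  do.call(rbind, lapply(parts, function(p) {
    data.frame(ftype = p[5L], x = as.numeric(p[1L]), y = as.numeric(p[2L]),
               z = as.numeric(p[3L]), radius = as.numeric(p[4L]),
               stringsAsFactors = FALSE)
  }))
}
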