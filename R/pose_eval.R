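## Scored docked poses: parsing, submission selection, symmetry-corrected
## RMSD and per-method summary statistics.

#' Parse docked poses from an SD file
#'
#' Each record must carry a numeric score data field (by default
#' `SCORE.INTER`, the intermolecular score; lower is better in the rDock
#' energy-like convention).
#'
#' @param sdf_path SD file of docked poses.
#' @param score_tag name of the SD field holding the score.
#' @param cavity_id,method,receptor_category optional labels attached to
#'   every pose.
#' @return list of `pose` objects: `mol`, `score_inter`, `cavity_id`,
#'   `method`, `receptor_category`.
#' @export
parse_poses <- function(sdf_path, score_tag = "SCORE.INTER",
                        cavity_id = NA_character_, method = NA_character_,
                        receptor_category = "synthetic") {
  mols <- read_sdf(sdf_path)
  lapply(seq_along(mols), function(k) {
    val <- mols[[k]]$properties[[score_tag]]
    if (is.null(val))
      stop("record ", k, " ('", mols[[k]]$id, "'): missing score field <",
           score_tag, ">", call. = FALSE)
    score <- suppressWarnings(as.numeric(trimws(val)))
    if (is.na(score) || !is.finite(score))
      stop("record ", k, " ('", mols[[k]]$id, "'): score field <", score_tag,
           "> is not numeric: '", val, "'", call. = FALSE)
    pose(mols[[k]], score, cavity_id, method, receptor_category)
  })
}

#' Construct a pose object
#'
#' @param mol [molecule_record()] with coordinates.
#' @param score_inter finite numeric docking score (lower = better).
#' @param cavity_id,method,receptor_category labels.
#' @return object of class `pose`.
#' @export
pose <- function(mol, score_inter, cavity_id = NA_character_,
                 method = NA_character_, receptor_category = "synthetic") {
  stopifnot(inherits(mol, "molecule_record"), is.finite(score_inter))
  structure(list(mol = mol, score_inter = as.numeric(score_inter),
                 cavity_id = cavity_id, method = method,
                 receptor_category = receptor_category),
            class = "pose")
}

#' Best pose by intermolecular score
#'
#' Minimum `score_inter` (most negative); ties broken by earliest position.
#'
#' @param poses non-empty list of [pose()] objects.
#' @return the winning pose.
#' @export
best_pose <- function(poses) {
  if (!length(poses)) stop("no poses to select from")
  scores <- vapply(poses, function(p) p$score_inter, numeric(1))
  poses[[which.min(scores)]]
}

#' Select the submission pose across cavities
#'
#' Cavities are consulted in the supplied ranking order (highest MCS score
#' first, from [rank_cavities()]); the best-scoring pose of the first
#' cavity that produced any pose is submitted, regardless of scores in
#' lower-ranked cavities.
#'
#' @param per_cavity_poses named list: cavity_id -> list of [pose()]s.
#' @param ranked_cavities ordered list of [cavity_candidate()]s, or a
#'   character vector of cavity ids in rank order.
#' @return the selected pose, with attribute `cavity_id`.
#' @export
select_submission <- function(per_cavity_poses, ranked_cavities) {
  ids <- if (is.character(ranked_cavities)) ranked_cavities else
    vapply(ranked_cavities, function(cv) cv$cavity_id, character(1))
  for (k in seq_along(ids)) {
    poses <- per_cavity_poses[[ids[k]]]
    if (length(poses)) {
      if (k > 1L)
        warning("top-ranked cavit", if (k == 2L) "y" else "ies",
                " produced no poses; falling back to cavity '", ids[k], "'")
      out <- best_pose(poses)
      out$cavity_id <- ids[k]
      return(out)
    }
  }
  stop("no cavity produced any pose")
}

## All graph automorphisms of a molecule (element + ring + bond-label
## preserving permutations), by backtracking with element/degree pruning.
## Enumeration stops at `cap` automorphisms.
graph_automorphisms <- function(mol, cap = 10000L) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  lab <- bond_labels(mol)
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  ## neighbour signature: sorted element:bondlabel multiset
  nsig <- vapply(seq_len(n), function(i) {
    a <- adj[[i]]
    if (is.null(a)) return("")
    paste(sort(paste(mol$elements[a[, 1L]], lab[a[, 3L]])), collapse = "|")
  }, character(1))
  compat <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    mol$elements[i] == mol$elements[j] && deg[i] == deg[j] && nsig[i] == nsig[j]
  }))
  perms <- list()
  capped <- FALSE
  perm <- integer(n)
  used <- rep(FALSE, n)
  bkey <- function(i, j) paste(min(i, j), max(i, j))
  bmap <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(mol$bonds)))
    assign(bkey(mol$bonds[k, 1L], mol$bonds[k, 2L]), lab[k], envir = bmap)
  edge_label <- function(i, j) {
    key <- bkey(i, j)
    if (exists(key, envir = bmap, inherits = FALSE)) get(key, envir = bmap) else NA_character_
  }
  recurse <- function(pos) {
    if (capped) return()
    if (pos > n) {
      if (length(perms) >= cap) { capped <<- TRUE; return() }
      perms[[length(perms) + 1L]] <<- perm
      return()
    }
    for (cand in seq_len(n)) {
      if (used[cand] || !compat[pos, cand]) next
      ok <- TRUE
      for (prev in seq_len(pos - 1L)) {
        l1 <- edge_label(pos, prev)
        l2 <- edge_label(cand, perm[prev])
        if (!identical(l1, l2) && !(is.na(l1) && is.na(l2))) { ok <- FALSE; break }
      }
      if (!ok) next
      perm[pos] <<- cand
      used[cand] <<- TRUE
      recurse(pos + 1L)
      used[cand] <<- FALSE
      if (capped) return()
    }
  }
  recurse(1L)
  list(perms = perms, capped = capped)
}

## Same heavy-atom multiset and bond structure, atom-for-atom?
same_graph <- function(a, b) {
  if (n_atoms(a) != n_atoms(b)) return(FALSE)
  if (!identical(a$elements, b$elements)) return(FALSE)
  norm <- function(m) {
    bd <- m$bonds
    if (!nrow(bd)) return(bd)
    swap <- bd[, 1L] > bd[, 2L]
    bd[swap, 1:2] <- bd[swap, 2:1]
    bd[order(bd[, 1L], bd[, 2L]), , drop = FALSE]
  }
  identical(norm(a), norm(b))
}

#' Symmetry-corrected RMSD between two poses
#'
#' Minimum over the graph automorphisms of the reference of the heavy-atom
#' root-mean-square deviation, with no re-superposition: docked and
#' reference poses are assumed to share the receptor frame. Topologically
#' equivalent atoms (e.g. the carbons of a benzene ring) are thereby
#' matched optimally, as the `sdrmsd` utility does.
#'
#' @param pred,ref [molecule_record()]s with identical heavy-atom graphs
#'   (same atom order) and coordinates.
#' @param cap maximum number of automorphisms enumerated; beyond it the
#'   identity mapping is used with a warning.
#' @return RMSD in Angstrom.
#' @export
symmetry_rmsd <- function(pred, ref, cap = 10000L) {
  if (!has_coords(pred) || !has_coords(ref)) stop("both poses need coordinates")
  if (!same_graph(pred, ref))
    stop("molecular graphs differ between '", pred$id, "' and '", ref$id, "'")
  aut <- graph_automorphisms(ref, cap)
  rmsd_for <- function(perm) {
    d <- pred$coords - ref$coords[perm, , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }
  if (aut$capped || !length(aut$perms)) {
    if (aut$capped)
      warning("automorphism count exceeds cap (", cap,
              "); falling back to identity atom order")
    return(rmsd_for(seq_len(n_atoms(ref))))
  }
  min(vapply(aut$perms, rmsd_for, numeric(1)))
}

#' Is a predicted pose a success?
#'
#' Strictly below the configured RMSD threshold (default 2 Angstrom). Set
#' `inclusive = TRUE` to count RMSD equal to the threshold as success.
#'
#' @param rmsd RMSD in Angstrom (>= 0).
#' @param cfg a [pipeline_config()].
#' @param inclusive use `<=` instead of the default strict `<`.
#' @return logical.
#' @export
classify_success <- function(rmsd, cfg = pipeline_config(), inclusive = FALSE) {
  stopifnot(all(rmsd >= 0))
  if (inclusive) rmsd <= cfg$success_rmsd else rmsd < cfg$success_rmsd
}

#' Per-group RMSD summary statistics
#'
#' For each group (docking method or receptor category): n, mean, standard
#' deviation (0 for a single value), min, quartiles Q1/Q2/Q3 (linear
#' interpolation between closest ranks, R's default type 7), max, and the
#' percentage of cases whose RMSD is strictly below the success threshold.
#'
#' @param results data.frame with columns `group` and `rmsd` (Angstrom).
#' @param cfg a [pipeline_config()] supplying the success threshold.
#' @param inclusive passed to [classify_success()].
#' @return data.frame with one row per group: `group`, `n`, `mean`, `std`,
#'   `min`, `q1`, `q2`, `q3`, `max`, `pct_success`.
#' @export
summarize_rmsd <- function(results, cfg = pipeline_config(), inclusive = FALSE) {
  stopifnot(nrow(results) >= 1L, all(c("group", "rmsd") %in% names(results)))
  out <- lapply(split(results$rmsd, results$group), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), mean = mean(v),
               std = if (length(v) < 2L) 0 else stats::sd(v),
               min = min(v), q1 = q[1L], q2 = q[2L], q3 = q[3L], max = max(v),
               pct_success = 100 * mean(classify_success(v, cfg, inclusive)))
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}
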