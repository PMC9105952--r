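## Synthetic fixture generators: congeneric aligned ligand series with
## planted scaffolds and feature points, scored pose sets with known RMSD
## ground truth, and multi-cavity scenarios. Everything is a pure function
## of its spec (same seed -> byte-identical files).

## run code under a local RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

BOND_LENGTH <- list("C C ar" = 1.39, "C N ar" = 1.34, "C C 1" = 1.54,
                    "C C 2" = 1.34, "C O 1" = 1.43, "C O 2" = 1.22,
                    "C N 1" = 1.47, "C F 1" = 1.35, "C Cl 1" = 1.77,
                    "C Br 1" = 1.94, "C S 1" = 1.81)

ideal_length <- function(e1, e2, label) {
  key1 <- paste(e1, e2, label); key2 <- paste(e2, e1, label)
  if (!is.null(BOND_LENGTH[[key1]])) return(BOND_LENGTH[[key1]])
  if (!is.null(BOND_LENGTH[[key2]])) return(BOND_LENGTH[[key2]])
  1.5
}

#' Deterministic template 3D embedding
#'
#' Assigns idealized planar coordinates to a small molecule: rings become
#' regular polygons (single and pendant rings; fused ring systems are not
#' supported), chains grow in the plane with substituent directions chosen
#' to maximize angular separation, and bond lengths come from a small
#' idealized table. The embedding is a pure function of the molecular
#' graph, so generated fixtures are platform-independent and byte-stable —
#' it is a layout template, not a conformer generator.
#'
#' @param mol a [molecule_record()] (coordinates, if any, are ignored).
#' @return the record with `coords` filled in.
#' @export
embed_molecule <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  lab <- bond_labels(mol)
  ri <- ring_info(mol)
  rings <- ri$rings
  ring_of <- rep(NA_integer_, n)
  for (k in seq_along(rings)) {
    if (any(!is.na(ring_of[rings[[k]]])))
      stop("embed_molecule supports single and pendant rings only (fused/spiro systems are not)")
    ring_of[rings[[k]]] <- k
  }
  coords <- matrix(NA_real_, n, 3L)
  placed <- rep(FALSE, n)

  ring_bond_length <- function(r) {
    m <- length(r)
    ls <- numeric(m)
    for (t in seq_len(m)) {
      a <- r[t]; b <- r[if (t == m) 1L else t + 1L]
      k <- which((mol$bonds[, 1L] == a & mol$bonds[, 2L] == b) |
                   (mol$bonds[, 1L] == b & mol$bonds[, 2L] == a))[1L]
      ls[t] <- ideal_length(mol$elements[a], mol$elements[b], lab[k])
    }
    mean(ls)
  }

  place_ring <- function(r, start_atom, start_xy, inward) {
    ## regular polygon; `start_atom` sits at start_xy, ring centre at
    ## start_xy + inward * circumradius
    m <- length(r)
    L <- ring_bond_length(r)
    R <- L / (2 * sin(pi / m))
    centre <- start_xy + inward * R
    ## order ring path to start at start_atom
    s <- match(start_atom, r)
    path <- r[((seq_len(m) + s - 2L) %% m) + 1L]
    a0 <- atan2(start_xy[2L] - centre[2L], start_xy[1L] - centre[1L])
    for (t in seq_len(m)) {
      ang <- a0 + (t - 1L) * 2 * pi / m
      coords[path[t], 1:2] <<- centre + R * c(cos(ang), sin(ang))
      coords[path[t], 3L] <<- 0
      placed[path[t]] <<- TRUE
    }
  }

  pick_direction <- function(anchor) {
    nb <- adj[[anchor]]
    dirs <- NULL
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1L]
        if (placed[w])
          dirs <- c(dirs, atan2(coords[w, 2L] - coords[anchor, 2L],
                                coords[w, 1L] - coords[anchor, 1L]))
      }
    }
    cand <- seq(0, 2 * pi - 1e-9, by = pi / 6)
    if (is.null(dirs)) return(cand[1L])
    sep <- vapply(cand, function(a) {
      d <- abs(((a - dirs + pi) %% (2 * pi)) - pi)
      min(d)
    }, numeric(1))
    cand[which.max(sep)]
  }

  place_atom <- function(w, anchor, bond_lab) {
    L <- ideal_length(mol$elements[anchor], mol$elements[w], bond_lab)
    ang <- pick_direction(anchor)
    xy <- coords[anchor, 1:2] + L * c(cos(ang), sin(ang))
    if (!is.na(ring_of[w])) {
      place_ring(rings[[ring_of[w]]], w, xy, c(cos(ang), sin(ang)))
    } else {
      coords[w, ] <<- c(xy, 0)
      placed[w] <<- TRUE
    }
  }

  ## seed: atom 1 (and its ring, if cyclic) at the origin
  if (!is.na(ring_of[1L])) {
    place_ring(rings[[ring_of[1L]]], 1L, c(0, 0), c(0, 1))
  } else {
    coords[1L, ] <- c(0, 0, 0)
    placed[1L] <- TRUE
  }
  queue <- which(placed)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1L]
      if (placed[w]) next
      place_atom(w, v, lab[nb[r, 3L]])
      newly <- if (!is.na(ring_of[w])) rings[[ring_of[w]]] else w
      queue <- c(queue, newly)
    }
  }
  if (!all(placed)) stop("disconnected molecule: embedding incomplete")
  out <- mol
  out$coords <- coords
  out
}

## substituent used to plant each pharmacophore feature type, and the
## substituent atoms whose centroid is the planted feature centre
PLANT_GROUPS <- list(
  HDON = list(smiles = "O",        feature_atoms = 1L),
  HACC = list(smiles = "OC",       feature_atoms = 1L),
  LIPO = list(smiles = "CC",       feature_atoms = c(1L, 2L)),
  AROM = list(smiles = "c1ccccc1", feature_atoms = 1:6),
  POSC = list(smiles = "[NH3+]",   feature_atoms = 1L),
  NEGC = list(smiles = "[O-]",     feature_atoms = 1L)
)

## attach `sub` (a molecule_record) to `base` with a single bond from
## base atom `pos` to sub atom 1; returns list(mol, sub_index_offset)
attach_group <- function(base, sub, pos) {
  off <- n_atoms(base)
  bonds <- rbind(base$bonds,
                 c(pos, off + 1L, 1L),
                 if (nrow(sub$bonds)) cbind(sub$bonds[, 1L] + off,
                                            sub$bonds[, 2L] + off,
                                            sub$bonds[, 3L]))
  mol <- molecule_record(base$id, c(base$elements, sub$elements),
                         coords = NULL, bonds = bonds,
                         charges = c(base$charges, sub$charges),
                         properties = base$properties)
  list(mol = mol, offset = off)
}

#' Specification of a synthetic congeneric series
#'
#' @param seed integer RNG seed; the series is a pure function of the spec.
#' @param n_ligands number of ligands to generate.
#' @param scaffold SMILES of the shared scaffold.
#' @param decoration_pool substituent SMILES drawn at random for the
#'   non-planted open positions (defaults are feature-silent groups).
#' @param planted_features list of `list(ftype=, position=, fraction=)`:
#'   feature type from `AROM/HDON/HACC/LIPO/POSC/NEGC`, 1-based scaffold
#'   atom the feature group is attached to, and the fraction of ligands
#'   that carry it (carrier count = `round(fraction * n_ligands)`).
#' @param jitter per-coordinate Gaussian noise in Angstrom applied to the
#'   embedded template (emulating pocket-alignment error).
#' @return object of class `series_spec`.
#' @export
series_spec <- function(seed, n_ligands, scaffold = "c1ccccc1",
                        decoration_pool = c("C", "F", "Cl"),
                        planted_features = list(), jitter = 0.05) {
  stopifnot(n_ligands >= 1L, jitter >= 0)
  for (pf in planted_features) {
    stopifnot(pf$ftype %in% names(PLANT_GROUPS),
              pf$fraction >= 0, pf$fraction <= 1)
  }
  structure(list(seed = as.integer(seed), n_ligands = as.integer(n_ligands),
                 scaffold = scaffold, decoration_pool = decoration_pool,
                 planted_features = planted_features, jitter = jitter),
            class = "series_spec")
}

#' Generate a congeneric aligned ligand series
#'
#' Emulates "ligands retrieved from the aligned pockets of similar
#' proteins": every ligand shares the scaffold subgraph, embedded at fixed
#' template coordinates (plus jitter) in a common frame, decorated from the
#' pool, with pharmacophore feature groups planted in a controlled fraction
#' of ligands at fixed scaffold positions.
#'
#' @param spec a [series_spec()].
#' @return list with `ligands` (list of 3D [molecule_record()]s) and
#'   `truth`: `scaffold_atoms` (indices of the scaffold atoms, identical in
#'   every ligand), `features` (data.frame: `ftype`, `x`, `y`, `z` template
#'   centre, `fraction` requested, `n_carriers`) and `carriers` (list of
#'   carrier ligand ids per planted feature).
#' @export
gen_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  scaffold <- read_smiles(paste(spec$scaffold, "scaffold"))[[1L]]
  n_sc <- n_atoms(scaffold)
  open <- which(implicit_h(scaffold) >= 1L)
  planted_pos <- vapply(spec$planted_features, function(pf) as.integer(pf$position),
                        integer(1))
  if (length(planted_pos)) {
    if (any(!(planted_pos %in% open)))
      stop("planted feature position without a free valence on the scaffold")
    if (anyDuplicated(planted_pos)) stop("duplicate planted positions")
  }
  free_pos <- setdiff(open, planted_pos)
  subs <- lapply(PLANT_GROUPS, function(g) read_smiles(paste(g$smiles, "sub"))[[1L]])
  deco <- lapply(spec$decoration_pool, function(s) read_smiles(paste(s, "deco"))[[1L]])

  with_seed(spec$seed, {
    carriers <- lapply(spec$planted_features, function(pf) {
      k <- round(pf$fraction * spec$n_ligands)
      sort(sample(spec$n_ligands, k))
    })
    feat_centres <- vector("list", length(spec$planted_features))
    ligands <- vector("list", spec$n_ligands)
    for (li in seq_len(spec$n_ligands)) {
      id <- sprintf("lig_%02d", li)
      mol <- scaffold
      mol$id <- id
      feat_atoms <- vector("list", length(spec$planted_features))
      for (fi in seq_along(spec$planted_features)) {
        if (!(li %in% carriers[[fi]])) next
        pf <- spec$planted_features[[fi]]
        res <- attach_group(mol, subs[[pf$ftype]], as.integer(pf$position))
        mol <- res$mol
        feat_atoms[[fi]] <- res$offset + PLANT_GROUPS[[pf$ftype]]$feature_atoms
      }
      ## random decorations on the remaining open positions
      if (length(free_pos) && length(deco)) {
        k <- sample(0:min(2L, length(free_pos)), 1L)
        if (k > 0L) {
          at <- sample(free_pos, k)
          for (p in at) {
            res <- attach_group(mol, deco[[sample(length(deco), 1L)]], p)
            mol <- res$mol
          }
        }
      }
      mol <- embed_molecule(mol)
      for (fi in seq_along(spec$planted_features)) {
        if (is.null(feat_atoms[[fi]]) || !is.null(feat_centres[[fi]])) next
        feat_centres[[fi]] <-
          colMeans(mol$coords[feat_atoms[[fi]], , drop = FALSE])
      }
      if (spec$jitter > 0)
        mol$coords <- mol$coords +
          matrix(stats::rnorm(length(mol$coords), 0, spec$jitter),
                 ncol = 3L)
      ligands[[li]] <- mol
    }
    features <- do.call(rbind, lapply(seq_along(spec$planted_features), function(fi) {
      pf <- spec$planted_features[[fi]]
      ctr <- feat_centres[[fi]]
      data.frame(ftype = pf$ftype,
                 x = if (is.null(ctr)) NA_real_ else ctr[1L],
                 y = if (is.null(ctr)) NA_real_ else ctr[2L],
                 z = if (is.null(ctr)) NA_real_ else ctr[3L],
                 fraction = pf$fraction, n_carriers = length(carriers[[fi]]),
                 stringsAsFactors = FALSE)
    }))
    list(ligands = ligands,
         truth = list(scaffold_atoms = seq_len(n_sc),
                      features = features,
                      carriers = lapply(carriers, function(ix) sprintf("lig_%02d", ix))))
  })
}

#' Specification of a synthetic scored pose set
#'
#' @param seed integer RNG seed.
#' @param target_rmsds vector of requested symmetry-corrected RMSDs to the
#'   reference pose, in Angstrom (one pose per entry).
#' @param score_noise standard deviation of Gaussian noise added to the
#'   score model `score = -25 + 3 * rmsd` (only the monotone relation
#'   between planted RMSD and score is contractual).
#' @return object of class `pose_spec`.
#' @export
pose_spec <- function(seed, target_rmsds, score_noise = 0) {
  stopifnot(all(target_rmsds >= 0), score_noise >= 0)
  structure(list(seed = as.integer(seed), n_poses = length(target_rmsds),
                 target_rmsds = as.numeric(target_rmsds),
                 score_noise = score_noise),
            class = "pose_spec")
}

#' Generate a scored pose set with known RMSD ground truth
#'
#' Each pose is the reference conformer under a seeded rigid transform
#' (rotation about the centroid plus translation) whose magnitude is
#' root-solved so the measured symmetry-corrected RMSD to the reference
#' equals the requested target within 1e-3 Angstrom. Scores follow
#' `-25 + 3 * rmsd` plus seeded noise. For a single-atom molecule the
#' perturbation is a pure translation.
#'
#' @param ref_pose [molecule_record()] with coordinates (the reference pose
#'   in the receptor frame).
#' @param spec a [pose_spec()].
#' @return list of [pose()]s; each pose's record carries `SCORE.INTER` and
#'   `PLANTED.RMSD` SD fields.
#' @export
gen_pose_set <- function(ref_pose, spec) {
  stopifnot(inherits(spec, "pose_spec"), has_coords(ref_pose))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_poses), function(k) {
      target <- spec$target_rmsds[k]
      mol <- ref_pose
      mol$id <- sprintf("%s_pose_%02d", ref_pose$id, k)
      if (target > 0) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        theta0 <- 0.3
        ctr <- colMeans(ref_pose$coords)
        transform <- function(s) {
          th <- theta0 * s
          K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                      3, 3, byrow = TRUE)
          R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
          sweep(sweep(ref_pose$coords, 2L, ctr) %*% t(R), 2L, ctr + s * u, "+")
        }
        f <- function(s) {
          m2 <- mol; m2$coords <- transform(s)
          symmetry_rmsd(m2, ref_pose) - target
        }
        hi <- max(1, 2 * target)
        while (f(hi) < 0) hi <- hi * 2
        s <- stats::uniroot(f, c(0, hi), tol = 1e-7)$root
        mol$coords <- transform(s)
      }
      rmsd <- symmetry_rmsd(mol, ref_pose)
      score <- -25 + 3 * target +
        if (spec$score_noise > 0) stats::rnorm(1, 0, spec$score_noise) else 0
      mol$properties[["SCORE.INTER"]] <- sprintf("%.6f", score)
      mol$properties[["PLANTED.RMSD"]] <- sprintf("%.6f", rmsd)
      pose(mol, score)
    })
  })
}

#' Generate a multi-cavity scenario
#'
#' Emulates targets where several candidate pockets were detected: the
#' "correct" cavity holds a congeneric series sharing the query's scaffold
#' (high MCS Tanimoto), while decoy cavities hold dissimilar acyclic
#' ligands (low MCS Tanimoto, by construction). Reference ligands and MCS
#' scores are computed with the package's own similarity operations.
#'
#' @param seed integer RNG seed.
#' @param n_cavities number of cavities.
#' @param which_correct 1-based index of the correct cavity.
#' @param n_ligands ligands per cavity.
#' @return list with `query` (a 3D [molecule_record()]) and `cavities`
#'   (named list of [cavity_candidate()]s, ids `cavity_1` ...).
#' @export
gen_cavity_scenario <- function(seed, n_cavities, which_correct, n_ligands = 4L) {
  stopifnot(n_cavities >= 1L, which_correct >= 1L, which_correct <= n_cavities)
  query <- embed_molecule(read_smiles("Cc1ccccc1Cl query")[[1L]])
  decoy_smiles <- c("CCCCCC", "CCCCC", "CCCCCCC", "CC(C)CC", "CCC(C)CC",
                    "CCCC(C)C")
  cavities <- list()
  for (ci in seq_len(n_cavities)) {
    cav_id <- paste0("cavity_", ci)
    if (ci == which_correct) {
      ligands <- gen_series(series_spec(seed = seed + ci, n_ligands = n_ligands,
                                        scaffold = "c1ccccc1",
                                        jitter = 0.02))$ligands
    } else {
      ligands <- with_seed(seed + ci, {
        picks <- sample(decoy_smiles, n_ligands, replace = n_ligands > length(decoy_smiles))
        lapply(seq_along(picks), function(k) {
          m <- embed_molecule(read_smiles(paste(picks[k], sprintf("decoy_%d_%02d", ci, k)))[[1L]])
          m
        })
      })
    }
    tab <- similarity_table(query, ligands)
    ref_id <- select_reference_ligand(tab)
    cavities[[cav_id]] <- cavity_candidate(
      cav_id, ligands, ref_id,
      tab$tanimoto_mcss[tab$ref_id == ref_id][1L])
  }
  list(query = query, cavities = cavities)
}
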