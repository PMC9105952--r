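## End-to-end orchestration for one target: similarity analysis, strategy
## decision and restraint/tether artifacts per cavity, then pose selection
## and submission formatting, with a machine-readable JSON decision report.

#' Construct a target bundle
#'
#' Everything the pipeline needs for one target: the query ligand, the
#' candidate cavities with their retrieved aligned ligands, and opaque
#' receptor files keyed by category.
#'
#' @param target_id character label.
#' @param query_ligand a [molecule_record()] (SMILES-derived records
#'   without coordinates are embedded on demand for tethering).
#' @param cavities list of [cavity_candidate()]s (possibly empty: the
#'   target then falls to free docking with a warning).
#' @param receptor_paths named list: receptor category -> file path
#'   (pass-through, never parsed).
#' @return object of class `target_bundle`.
#' @export
target_bundle <- function(target_id, query_ligand, cavities = list(),
                          receptor_paths = list()) {
  stopifnot(inherits(query_ligand, "molecule_record"))
  for (cv in cavities) stopifnot(inherits(cv, "cavity_candidate"))
  structure(list(target_id = as.character(target_id),
                 query_ligand = query_ligand, cavities = cavities,
                 receptor_paths = receptor_paths),
            class = "target_bundle")
}

#' Load a target bundle from a directory
#'
#' Directory contract (this package's own): `query.smi` (single SMILES
#' line) or `query.sdf`; one sub-directory per cavity under `cavities/`,
#' each holding a `ligands.sdf` of aligned 3D ligands; optional receptor
#' files under `receptors/` (kept opaque). Reference ligands and MCS
#' scores are computed on load.
#'
#' @param dir bundle directory.
#' @param params MCS options for the similarity analysis.
#' @return a [target_bundle()].
#' @export
load_target_bundle <- function(dir, params = mcs_params()) {
  if (!dir.exists(dir)) stop("no such bundle directory: ", dir)
  qsmi <- file.path(dir, "query.smi"); qsdf <- file.path(dir, "query.sdf")
  query <- if (file.exists(qsmi)) read_smiles(qsmi)[[1L]] else if (file.exists(qsdf))
    read_sdf(qsdf)[[1L]] else stop("bundle has neither query.smi nor query.sdf")
  cav_dirs <- sort(list.dirs(file.path(dir, "cavities"), recursive = FALSE))
  cavities <- list()
  for (cd in cav_dirs) {
    ligands <- read_sdf(file.path(cd, "ligands.sdf"))
    tab <- similarity_table(query, ligands, params)
    ref_id <- select_reference_ligand(tab)
    cavities[[basename(cd)]] <- cavity_candidate(
      basename(cd), ligands, ref_id,
      tab$tanimoto_mcss[tab$ref_id == ref_id][1L])
  }
  rec_files <- if (dir.exists(file.path(dir, "receptors")))
    list.files(file.path(dir, "receptors"), full.names = TRUE) else character(0)
  receptor_paths <- as.list(rec_files)
  names(receptor_paths) <- sub("\\.[^.]*$", "", basename(rec_files))
  target_bundle(basename(dir), query, cavities, receptor_paths)
}

#' Run restraint generation for one target
#'
#' For every cavity: similarity table, reference-ligand selection, ligand
#' clustering, strategy decision, and the protocol's artifact — a tethered
#' SDF (MCS superposed onto the reference, `TETHERED ATOMS` annotated),
#' version-2 consensus restraint files, or nothing for free docking. A
#' cavity whose MCS is too small for tethering falls through the remaining
#' cascade; per-cavity failures are isolated and recorded. The JSON report
#' written to `out_dir` records every decision together with the
#' thresholds used, sufficient to reproduce the run.
#'
#' @param bundle a [target_bundle()].
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the report, invisibly (also written to
#'   `out_dir/<target>_report.json`).
#' @export
run_target <- function(bundle, cfg = pipeline_config(), out_dir = ".") {
  stopifnot(inherits(bundle, "target_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  query <- bundle$query_ligand
  cav_reports <- list()
  if (!length(bundle$cavities))
    warning("target '", bundle$target_id,
            "': no cavities retrieved; free docking without restraints")
  for (cv in bundle$cavities) {
    cav_reports[[cv$cavity_id]] <- tryCatch(
      run_cavity(query, cv, cfg, file.path(out_dir, cv$cavity_id)),
      error = function(e) {
        warning("cavity '", cv$cavity_id, "' failed: ", conditionMessage(e))
        list(cavity_id = cv$cavity_id, status = "failed",
             error = conditionMessage(e))
      })
  }
  ranked <- if (length(bundle$cavities))
    unname(vapply(rank_cavities(bundle$cavities), function(cv) cv$cavity_id,
                  character(1))) else character(0)
  report <- list(
    target_id = bundle$target_id,
    config = unclass(cfg),
    n_cavities = length(bundle$cavities),
    ranked_cavities = ranked,
    cavities = cav_reports,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report,
                       file.path(out_dir, paste0(bundle$target_id, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

run_cavity <- function(query, cv, cfg, cav_dir) {
  dir.create(cav_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- similarity_table(query, cv$ligands)
  ref_id <- select_reference_ligand(tab)
  ref_mol <- cv$ligands[[match(ref_id, vapply(cv$ligands, function(m) m$id,
                                              character(1)))]]
  best_tmcss <- tab$tanimoto_mcss[tab$ref_id == ref_id][1L]
  clus <- cluster_ligands(cv$ligands, cfg$cluster_cutoff)
  n_diverse <- length(clus$representatives)
  decision <- choose_protocol(best_tmcss, n_diverse, cfg)
  artifacts <- list()
  notes <- character(0)

  if (decision$protocol == "TETHERED") {
    q3d <- if (has_coords(query)) query else embed_molecule(query)
    mcs <- find_mcs(q3d, ref_mol)
    if (mcs$n_ab >= 3L) {
      teth <- prepare_tethered_ligand(q3d, ref_mol, mcs)
      path <- file.path(cav_dir, "tethered.sdf")
      write_sdf(list(teth), path)
      artifacts$tethered_sdf <- path
      artifacts$tether_fit_rmsd <- attr(teth, "fit_rmsd")
    } else {
      notes <- c(notes, sprintf("MCS has %d atoms (< 3): tether impossible, cascading",
                                mcs$n_ab))
      decision <- choose_protocol(0, n_diverse, cfg)
    }
  }
  if (decision$protocol == "PH4") {
    cp <- consensus_v2(clus$representative_mols, tol = cfg$ph4_tol,
                       radius = cfg$ph4_radius,
                       mandatory_support = cfg$mandatory_support,
                       optional_lo = cfg$optional_support_lo,
                       optional_hi = cfg$optional_support_hi)
    if (nrow(cp$mandatory) || nrow(cp$optional)) {
      paths <- write_restraint_files(cp, file.path(cav_dir, "mandatory.const"),
                                     file.path(cav_dir, "optional.const"))
      artifacts$restraint_files <- paths
      artifacts$n_mandatory <- nrow(cp$mandatory)
      artifacts$n_optional <- nrow(cp$optional)
    } else {
      notes <- c(notes, "empty consensus pharmacophore: falling back to free docking")
      decision <- choose_protocol(0, 0, cfg)
    }
  }
  ## reference ligand + cavity definition are written for every protocol
  ref_path <- file.path(cav_dir, "reference_ligand.sdf")
  write_sdf(list(ref_mol), ref_path)
  artifacts$reference_ligand_sdf <- ref_path

  list(cavity_id = cv$cavity_id, status = "ok",
       similarity = tab, reference_ligand = ref_id,
       best_tanimoto_mcss = best_tmcss, n_diverse = n_diverse,
       clusters = clus$clusters, decision = unclass(decision),
       artifacts = artifacts, notes = notes)
}

#' Select and format the submission pose for a target
#'
#' Parses the per-cavity docked pose SD files, picks the best-scoring pose
#' of the highest-ranked cavity that produced poses, writes it in MOL
#' format, byte-copies the receptor to a `.pdb`-named file, and appends
#' the selection trace to the target's JSON report.
#'
#' @param pose_sdfs named list: cavity_id -> SD file of scored poses.
#' @param report report list from [run_target()] (or the path to its JSON).
#' @param out_dir output directory.
#' @param receptor_path optional receptor file to pass through.
#' @param score_tag SD field holding the docking score.
#' @return list with `pose` (the selected [pose()]), `submission_mol`,
#'   `receptor_pdb` (or NULL).
#' @export
run_selection <- function(pose_sdfs, report, out_dir = ".",
                          receptor_path = NULL, score_tag = "SCORE.INTER") {
  if (is.character(report)) report <- jsonlite::read_json(report, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_cavity <- lapply(pose_sdfs, parse_poses, score_tag = score_tag)
  sel <- select_submission(per_cavity, as.character(report$ranked_cavities))
  mol_path <- file.path(out_dir, paste0(report$target_id, "_submission.mol"))
  write_mol(sel$mol, mol_path)
  pdb_path <- NULL
  if (!is.null(receptor_path)) {
    pdb_path <- file.path(out_dir, paste0(report$target_id, "_receptor.pdb"))
    file.copy(receptor_path, pdb_path, overwrite = TRUE)
  }
  trace <- list(selected_cavity = sel$cavity_id,
                selected_pose = sel$mol$id,
                score_inter = sel$score_inter,
                submission_mol = mol_path)
  report$selection <- trace
  jsonlite::write_json(report,
                       file.path(out_dir, paste0(report$target_id, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(pose = sel, submission_mol = mol_path, receptor_pdb = pdb_path)
}
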