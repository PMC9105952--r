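## Docking-strategy selection, tether preparation and rDock system
## definition files.

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline, each surfaced under a named key.
#' Defaults follow the validated protocol: tethered docking applies when
#' the best MCS Tanimoto score is strictly above 0.5; pharmacophore-guided
#' docking when there are strictly more than 5 diverse ligands; the
#' earlier, more conservative tether cutoff of 0.65 (used during protocol
#' development) is available as the `"legacy"` preset.
#'
#' @param preset `"validation"` (tether cutoff 0.5, the default) or
#'   `"legacy"` (0.65).
#' @param tether_threshold MCS Tanimoto cutoff for tethered docking
#'   (strict `>`).
#' @param min_diverse_ligands cluster-representative count cutoff for
#'   pharmacophore docking (strict `>`).
#' @param success_rmsd success threshold in Angstrom (strict `<`).
#' @param cluster_cutoff MACCS Tanimoto cutoff for ligand clustering.
#' @param mandatory_support,optional_support_lo,optional_support_hi consensus
#'   support brackets (version-2 protocol).
#' @param ph4_tol spatial grouping tolerance in Angstrom.
#' @param ph4_radius restraint sphere radius in Angstrom.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(preset = c("validation", "legacy"),
                            tether_threshold = NULL,
                            min_diverse_ligands = 5L,
                            success_rmsd = 2.0,
                            cluster_cutoff = 0.9,
                            mandatory_support = 0.45,
                            optional_support_lo = 0.20,
                            optional_support_hi = 0.44,
                            ph4_tol = 1.5,
                            ph4_radius = 1.0) {
  preset <- match.arg(preset)
  if (is.null(tether_threshold))
    tether_threshold <- if (preset == "legacy") 0.65 else 0.5
  stopifnot(tether_threshold > 0, min_diverse_ligands >= 0,
            success_rmsd > 0, cluster_cutoff > 0,
            optional_support_lo <= optional_support_hi)
  structure(list(preset = preset,
                 tether_threshold = tether_threshold,
                 legacy_tether_threshold = 0.65,
                 min_diverse_ligands = as.integer(min_diverse_ligands),
                 success_rmsd = success_rmsd,
                 cluster_cutoff = cluster_cutoff,
                 mandatory_support = mandatory_support,
                 optional_support_lo = optional_support_lo,
                 optional_support_hi = optional_support_hi,
                 ph4_tol = ph4_tol, ph4_radius = ph4_radius),
            class = "pipeline_config")
}

#' Choose the docking protocol
#'
#' The decision cascade: tethered docking if the best MCS Tanimoto score is
#' strictly above the tether threshold; otherwise pharmacophore-guided
#' docking if the number of diverse ligands (cluster representatives) is
#' strictly above the minimum; otherwise free docking. Equality at either
#' boundary falls through.
#'
#' @param best_tmcss best MCS Tanimoto score among retrieved ligands, in
#'   `[0, 1]` (0 when nothing was retrieved).
#' @param n_diverse number of cluster representatives.
#' @param cfg a [pipeline_config()].
#' @return object of class `strategy_decision`: list with `protocol` (one of
#'   `"TETHERED"`, `"PH4"`, `"FREE"`), `best_tanimoto_mcss`, `n_diverse`,
#'   `rationale`.
#' @export
choose_protocol <- function(best_tmcss, n_diverse, cfg = pipeline_config()) {
  stopifnot(best_tmcss >= 0, best_tmcss <= 1, n_diverse >= 0)
  if (best_tmcss > cfg$tether_threshold) {
    protocol <- "TETHERED"
    rationale <- sprintf("best TanimotoMCSS %.3f > %.2f: tether the MCS to the reference ligand",
                         best_tmcss, cfg$tether_threshold)
  } else if (n_diverse > cfg$min_diverse_ligands) {
    protocol <- "PH4"
    rationale <- sprintf("TanimotoMCSS %.3f <= %.2f but %d diverse ligands > %d: pharmacophore restraints",
                         best_tmcss, cfg$tether_threshold, n_diverse,
                         cfg$min_diverse_ligands)
  } else {
    protocol <- "FREE"
    rationale <- sprintf("TanimotoMCSS %.3f <= %.2f and %d diverse ligands <= %d: free docking",
                         best_tmcss, cfg$tether_threshold, n_diverse,
                         cfg$min_diverse_ligands)
  }
  structure(list(protocol = protocol, best_tanimoto_mcss = best_tmcss,
                 n_diverse = as.integer(n_diverse), rationale = rationale),
            class = "strategy_decision")
}

#' @export
print.strategy_decision <- function(x, ...) {
  cat(sprintf("<strategy_decision %s: %s>\n", x$protocol, x$rationale))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD
#' of `mobile` onto `target` over paired points. The aligned coordinates
#' are `mobile %*% rotation + translation` (row-vector convention).
#'
#' @param mobile,target numeric n x 3 matrices of paired coordinates,
#'   n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3),
#'   `fit_rmsd` (Angstrom) and `degenerate` (TRUE when the point sets are
#'   collinear or coincident; the transform is still valid).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- matrix(as.numeric(mobile), ncol = 3L)
  target <- matrix(as.numeric(target), ncol = 3L)
  if (nrow(mobile) != nrow(target)) stop("paired coordinate lists must have equal length")
  if (nrow(mobile) < 3L) stop("at least 3 paired points are required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm); B <- sweep(target, 2L, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  tr <- ct - as.numeric(cm %*% R)
  aligned <- sweep(mobile %*% R, 2L, tr, "+")
  fit_rmsd <- sqrt(mean(rowSums((aligned - target)^2)))
  ## collinear/coincident point sets leave a rotation axis unconstrained
  degenerate <- sum(sv$d > max(sv$d) * 1e-8) < 2L
  list(rotation = R, translation = tr, fit_rmsd = fit_rmsd,
       degenerate = degenerate)
}

#' Prepare a ligand for tethered docking
#'
#' Rigidly transforms the query conformer so its MCS atoms best fit the
#' corresponding atoms of the reference ligand (which sits in the receptor
#' frame), and annotates the record with the `TETHERED ATOMS` SD field: the
#' comma-separated, ascending, 1-based indices of the query atoms in the
#' MCS — the dialect consumed by rDock's tethered docking mode.
#'
#' @param query [molecule_record()] with a 3D conformer.
#' @param reference [molecule_record()] with coordinates, aligned in the
#'   receptor frame.
#' @param mcs `mcs_result` from [find_mcs()] computed between `query` (A)
#'   and `reference` (B), with at least 3 mapped atoms.
#' @return the transformed, annotated [molecule_record()].
#' @export
prepare_tethered_ligand <- function(query, reference, mcs) {
  stopifnot(inherits(mcs, "mcs_result"))
  if (!has_coords(query)) stop("query has no 3D conformer")
  if (!has_coords(reference)) stop("reference has no coordinates")
  if (mcs$n_ab < 3L)
    stop("MCS has only ", mcs$n_ab,
         " atoms (< 3): tethering impossible; fall back to pharmacophore or free docking")
  qi <- mcs$atom_map[, 1L]; ri <- mcs$atom_map[, 2L]
  fit <- kabsch_superpose(query$coords[qi, , drop = FALSE],
                          reference$coords[ri, , drop = FALSE])
  out <- query
  out$coords <- sweep(query$coords %*% fit$rotation, 2L, fit$translation, "+")
  out$properties[["TETHERED ATOMS"]] <- paste(sort(qi), collapse = ",")
  attr(out, "fit_rmsd") <- fit$fit_rmsd
  out
}

#' Write an rDock system-definition (cavity parameter) file
#'
#' Emits the reference-ligand site-mapper configuration with the engine's
#' documented default numeric parameters, pointing at the given receptor
#' and reference-ligand files. When a consensus pharmacophore is supplied,
#' a pharmacophore scoring section referencing the restraint files is
#' appended. Output is byte-stable for identical inputs.
#'
#' @param receptor_path receptor structure file (opaque pass-through).
#' @param reference_ligand_path reference ligand SD file defining the site.
#' @param out_path output parameter file path.
#' @param pharmacophore optional `consensus_pharmacophore`; when given,
#'   `mandatory_file`/`optional_file` name the restraint files in the
#'   emitted section.
#' @param mandatory_file,optional_file restraint file names referenced from
#'   the pharmacophore section.
#' @param title title line of the parameter file.
#' @return `out_path`, invisibly.
#' @export
write_cavity_prm <- function(receptor_path, reference_ligand_path, out_path,
                             pharmacophore = NULL,
                             mandatory_file = "pharma.const",
                             optional_file = "pharma.optional.const",
                             title = "poseprep reference-ligand cavity") {
  if (!file.exists(receptor_path)) stop("missing receptor file: ", receptor_path)
  if (!file.exists(reference_ligand_path))
    stop("missing reference ligand file: ", reference_ligand_path)
  lines <- c("RBT_PARAMETER_FILE_V1.00",
             paste("TITLE", title),
             "",
             paste("RECEPTOR_FILE", receptor_path),
             "RECEPTOR_FLEX 3.0",
             "",
             "SECTION MAPPER",
             "    SITE_MAPPER RbtLigandSiteMapper",
             paste("    REF_MOL", reference_ligand_path),
             "    RADIUS 6.0",
             "    SMALL_SPHERE 1.0",
             "    MIN_VOLUME 100",
             "    MAX_CAVITIES 1",
             "    VOL_INCR 0.0",
             "    GRIDSTEP 0.5",
             "END_SECTION",
             "",
             "SECTION CAVITY",
             "    SCORING_FUNCTION RbtCavityGridSF",
             "    WEIGHT 1.0",
             "END_SECTION")
  if (!is.null(pharmacophore)) {
    stopifnot(inherits(pharmacophore, "consensus_pharmacophore"))
    ph <- c("",
            "SECTION PHARMA",
            "    SCORING_FUNCTION RbtPharmaSF",
            "    WEIGHT 1.0",
            paste("    CONSTRAINTS_FILE", mandatory_file))
    if (nrow(pharmacophore$optional)) {
      ph <- c(ph,
              paste("    OPTIONAL_FILE", optional_file),
              paste("    NOPT", PH4_NOPT))
    }
    lines <- c(lines, ph, "END_SECTION")
  }
  writeLines(lines, out_path)
  invisible(out_path)
}
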