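## MDL V2000 SDF/MOL reading and writing with verbatim SD data fields.
## Hand-rolled (rather than delegated) because the pipeline's tethered-SDF
## dialect needs bit-exact data-field round trips and byte-stable output
## for golden-file comparisons; ChemmineR cross-checks the parser in tests.

HYDROGEN_SYMBOLS <- c("H", "D", "T")

#' Read an SD file
#'
#' Parses MDL V2000 molecule blocks. Explicit hydrogens are dropped and
#' atom indices compacted; all SD data fields are preserved verbatim, in
#' file order, as character values (multi-line values joined with `\n`).
#'
#' @param path path to an SD file (a single MOL block without the `$$$$`
#'   terminator is also accepted).
#' @return list of [molecule_record()], one per molecule block; an empty
#'   file yields an empty list.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  parse_sdf_lines(readLines(path, warn = FALSE))
}

parse_sdf_lines <- function(lines) {
  ## strip trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) return(list())
  recs <- list()
  pos <- 1L
  ordinal <- 0L
  while (pos <= length(lines)) {
    ordinal <- ordinal + 1L
    ends <- which(lines == "$$$$" & seq_along(lines) >= pos)
    end <- if (length(ends)) ends[1L] - 1L else length(lines)
    block <- lines[pos:end]
    recs[[ordinal]] <- parse_mol_block(block, ordinal)
    pos <- end + 2L
  }
  recs
}

parse_mol_block <- function(block, ordinal) {
  oops <- function(...) stop("molecule ", ordinal, ": ", ..., call. = FALSE)
  if (length(block) < 4L) oops("truncated molecule block")
  id <- trimws(block[1L])
  counts <- block[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb) || na < 0L || nb < 0L)
    oops("malformed counts line: '", counts, "'")
  if (length(block) < 4L + na + nb) oops("atom/bond block shorter than counts line claims")
  elements <- character(na)
  coords <- matrix(0, nrow = na, ncol = 3L)
  for (k in seq_len(na)) {
    ln <- block[4L + k]
    x <- suppressWarnings(as.numeric(substr(ln, 1L, 10L)))
    y <- suppressWarnings(as.numeric(substr(ln, 11L, 20L)))
    z <- suppressWarnings(as.numeric(substr(ln, 21L, 30L)))
    el <- trimws(substr(ln, 31L, 34L))
    if (anyNA(c(x, y, z)) || !nzchar(el)) oops("malformed atom line ", k)
    elements[k] <- el
    coords[k, ] <- c(x, y, z)
  }
  bonds <- matrix(integer(0), ncol = 3L)
  for (k in seq_len(nb)) {
    ln <- block[4L + na + k]
    i <- suppressWarnings(as.integer(substr(ln, 1L, 3L)))
    j <- suppressWarnings(as.integer(substr(ln, 4L, 6L)))
    o <- suppressWarnings(as.integer(substr(ln, 7L, 9L)))
    if (anyNA(c(i, j, o)) || i < 1L || j < 1L || i > na || j > na)
      oops("malformed bond line ", k)
    bonds <- rbind(bonds, c(i, j, o))
  }
  charges <- integer(na)
  rest <- if (length(block) > 4L + na + nb) block[(5L + na + nb):length(block)] else character(0)
  mend <- which(rest == "M  END")
  props_from <- if (length(mend)) mend[1L] + 1L else 1L
  if (length(mend)) {
    for (ln in rest[seq_len(mend[1L] - 1L)]) {
      if (startsWith(ln, "M  CHG")) {
        f <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "\\s+")[[1L]])
        ncg <- f[1L]
        for (t in seq_len(ncg)) charges[f[2L * t]] <- f[2L * t + 1L]
      }
    }
  }
  properties <- parse_sd_fields(rest[seq_len(length(rest))[seq_along(rest) >= props_from]])
  ## strip explicit hydrogens, compact indices
  keep <- !(elements %in% HYDROGEN_SYMBOLS)
  if (!any(keep)) oops("no heavy atoms")
  remap <- cumsum(keep)
  if (nrow(bonds)) {
    bkeep <- keep[bonds[, 1L]] & keep[bonds[, 2L]]
    bonds <- bonds[bkeep, , drop = FALSE]
    if (nrow(bonds)) {
      bonds[, 1L] <- remap[bonds[, 1L]]
      bonds[, 2L] <- remap[bonds[, 2L]]
    }
  }
  molecule_record(id = if (nzchar(id)) id else paste0("mol_", ordinal),
                  elements = elements[keep],
                  coords = coords[keep, , drop = FALSE],
                  bonds = bonds, charges = charges[keep],
                  properties = properties)
}

parse_sd_fields <- function(lines) {
  props <- list()
  k <- 1L
  while (k <= length(lines)) {
    ln <- lines[k]
    if (startsWith(ln, ">")) {
      tag <- sub(".*<([^>]+)>.*", "\\1", ln)
      vals <- character(0)
      k <- k + 1L
      while (k <= length(lines) && nzchar(lines[k]) && !startsWith(lines[k], ">")) {
        vals <- c(vals, lines[k])
        k <- k + 1L
      }
      props[[tag]] <- paste(vals, collapse = "\n")
    }
    k <- k + 1L
  }
  props
}

mol_block_lines <- function(mol) {
  if (!has_coords(mol))
    stop("record '", mol$id, "' has no coordinates; cannot write V2000 block")
  na <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  out <- c(mol$id, "  poseprep          3D", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (k in seq_len(na)) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          mol$coords[k, 1L], mol$coords[k, 2L], mol$coords[k, 3L],
                          mol$elements[k]))
  }
  for (k in seq_len(nb)) {
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          mol$bonds[k, 1L], mol$bonds[k, 2L], mol$bonds[k, 3L]))
  }
  chg <- which(mol$charges != 0L)
  while (length(chg)) {
    take <- chg[seq_len(min(8L, length(chg)))]
    chg <- chg[-seq_len(min(8L, length(chg)))]
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(take)),
                         paste0(sprintf("%4d%4d", take, mol$charges[take]),
                                collapse = "")))
  }
  c(out, "M  END")
}

#' Write molecule records to an SD file
#'
#' Emits V2000 blocks with each record's SD properties as `> <TAG>` data
#' fields in stored order. Output is byte-stable for identical inputs (no
#' timestamps), so golden-file comparisons are meaningful.
#'
#' @param mols list of [molecule_record()]; all must carry coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule_record")) mols <- list(mols)
  out <- character(0)
  for (mol in mols) {
    out <- c(out, mol_block_lines(mol))
    for (tag in names(mol$properties)) {
      out <- c(out, paste0(">  <", tag, ">"),
               strsplit(mol$properties[[tag]], "\n", fixed = TRUE)[[1L]], "")
    }
    out <- c(out, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a single molecule as a MOL file
#'
#' V2000 block only, no data fields (the format required for challenge-style
#' pose submission).
#'
#' @param mol a [molecule_record()] with coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mol <- function(mol, path) {
  stopifnot(inherits(mol, "molecule_record"))
  writeLines(mol_block_lines(mol), path)
  invisible(path)
}

#' Read molecules from SMILES
#'
#' Accepts a file path or literal text, one molecule per line in the form
#' `SMILES [id]`. Parsing and aromatic perception are delegated to Open
#' Babel (via \pkg{ChemmineOB}); the resulting records carry no
#' coordinates. Molecules without an id are named `mol_<line>`.
#'
#' @param x path to a SMILES file, or a character scalar/vector of
#'   SMILES lines.
#' @return list of [molecule_record()] without coordinates.
#' @export
read_smiles <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else
    unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1L]]
    smi <- parts[1L]
    id <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else paste0("mol_", k)
    sdf <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"))),
      error = function(e) "")
    blocks <- tryCatch(parse_sdf_lines(strsplit(sdf, "\n", fixed = TRUE)[[1L]]),
                       error = function(e) list())
    if (!length(blocks))
      stop("line ", k, ": cannot parse SMILES '", smi, "'", call. = FALSE)
    mol <- blocks[[1L]]
    mol$id <- id
    mol$coords <- NULL   # Open Babel emits a 2D sketch; connectivity only
    recs[[k]] <- mol
  }
  recs
}

## A molecule record -> SDF text (used to hand molecules to Open Babel).
sdf_text <- function(mol) {
  m <- mol
  if (!has_coords(m)) m$coords <- matrix(0, nrow = n_atoms(m), ncol = 3L)
  m$properties <- list()
  paste(c(mol_block_lines(m), "$$$$", ""), collapse = "\n")
}
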