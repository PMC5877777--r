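## Structure and trajectory containers.
##
## A structure is the ordered list of residues of one PDB model together with
## per-atom coordinates; a trajectory is an ordered set of frames (one per
## MODEL record) over a fixed atom selection.  Multi-model PDB is the
## interchange format for trajectories: it is plain text, universally
## writable, and carries exactly the per-frame node coordinates the analyses
## consume.  Reading and writing go through bio3d.

new_structure <- function(atom) {
  stopifnot(is.data.frame(atom),
            all(c("chain", "resno", "resid", "elety", "x", "y", "z") %in%
                  names(atom)))
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite coordinates in structure")
  res <- unique(atom[, c("chain", "resno", "resid")])
  rownames(res) <- NULL
  for (ch in unique(res$chain)) {
    rn <- res$resno[res$chain == ch]
    if (anyDuplicated(rn) || any(diff(rn) <= 0))
      stop("residue numbers must be unique and strictly increasing within ",
           "chain ", ch)
  }
  structure(list(atom = atom, residues = res),
            class = "pdb_structure")
}

n_residues <- function(x) nrow(x$residues)

residue_labels <- function(x) {
  paste0(x$residues$chain, x$residues$resno)
}

## Scan a PDB file into per-model ATOM line blocks.  Used only to validate
## model consistency before handing the file to bio3d (which assumes it).
scan_models <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  "
  model_starts <- grepl("^MODEL", lines)
  if (!any(model_starts)) return(list(which(is_atom)))
  idx <- cumsum(model_starts)
  split(which(is_atom), idx[is_atom])
}

atom_keys <- function(lines) {
  ## chain(22) resno(23-26) insert(27) atom-name(13-16) altloc(17)
  paste(substr(lines, 22L, 27L), substr(lines, 13L, 17L))
}

parse_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (any(!is.finite(pdb$xyz)))
    stop("malformed ATOM record (non-numeric coordinates) in ", path)
  pdb
}

## Shared ATOM-record filtering: protein atoms only, first altloc kept,
## hydrogens dropped (only CA/CB are ever consumed downstream).
select_atoms <- function(pdb) {
  at <- pdb$atom
  elety <- trimws(at$elety)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, elety)
  which(at$type == "ATOM" &
          !grepl("^[0-9]*H", elety) &   # hydrogens never consumed
          !duplicated(key))             # first altloc kept
}

#' Read a protein structure from a PDB file
#'
#' Returns one model of a (possibly multi-model) PDB file as a
#' `pdb_structure`: the ordered residue list plus per-atom coordinates.
#' HETATM records are ignored, only the first alternate location is kept and
#' hydrogens are dropped.
#'
#' @param path PDB file path.
#' @param model 1-based model number (default 1).
#' @return a `pdb_structure` object with elements `atom` (data frame of
#'   chain, resno, resid, elety, x, y, z) and `residues`.
#' @export
read_structure <- function(path, model = 1L) {
  pdb <- parse_pdb(path)
  nm <- nrow(pdb$xyz)
  if (model < 1L || model > nm)
    stop("model absent: requested model ", model, " of ", nm, " in ", path)
  sel <- select_atoms(pdb)
  at <- pdb$atom[sel, , drop = FALSE]
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)[sel, , drop = FALSE]
  atom <- data.frame(chain = at$chain, resno = at$resno,
                     resid = trimws(at$resid), elety = trimws(at$elety),
                     x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                     stringsAsFactors = FALSE)
  rownames(atom) <- NULL
  new_structure(atom)
}

#' Write a structure to a single-model PDB file
#'
#' The writer is deterministic: writing, re-reading and writing again gives
#' byte-identical files (coordinates carry the format's 3-decimal precision).
#'
#' @param x a `pdb_structure`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "pdb_structure"))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(x$atom[, c("x", "y", "z")]))),
                   resno = x$atom$resno, resid = x$atom$resid,
                   chain = x$atom$chain, elety = x$atom$elety)
  invisible(path)
}

#' Read a conformational trajectory from a multi-model PDB file
#'
#' One frame per MODEL record, in file order.  All models must share the
#' same atom list; a mismatch is an error ("inconsistent topology").
#'
#' @param path multi-model PDB file path.
#' @param selection atom selection: `"all"` (default), `"CA"`, or `"CB"`
#'   (Cbeta with Calpha substituted for glycine).
#' @param frame_spacing time between frames in ps (metadata only).
#' @return a `pdb_trajectory` with elements `xyz` (F x 3A coordinate matrix),
#'   `atom`, `residues`, `n_frames`, `frame_spacing`.
#' @export
read_trajectory <- function(path, selection = c("all", "CA", "CB"),
                            frame_spacing = NA_real_) {
  selection <- match.arg(selection)
  if (!file.exists(path)) stop("file not found: ", path)
  blocks <- scan_models(path)
  if (length(blocks) > 1L) {
    lines <- readLines(path)
    keys <- lapply(blocks, function(i) atom_keys(lines[i]))
    ref <- keys[[1L]]
    same <- vapply(keys, function(k) identical(k, ref), logical(1L))
    if (!all(same))
      stop("inconsistent topology: models differ in atom/residue list ",
           "(first mismatch at model ", which(!same)[1L], ")")
  }
  pdb <- parse_pdb(path)
  sel <- select_atoms(pdb)
  at <- pdb$atom[sel, , drop = FALSE]
  atom <- data.frame(chain = at$chain, resno = at$resno,
                     resid = trimws(at$resid), elety = trimws(at$elety),
                     stringsAsFactors = FALSE)
  rownames(atom) <- NULL
  cols <- as.vector(rbind(3L * sel - 2L, 3L * sel - 1L, 3L * sel))
  xyz <- pdb$xyz[, cols, drop = FALSE]
  traj <- new_trajectory(xyz, atom, frame_spacing)
  if (selection != "all") traj <- trajectory_nodes(traj, selection)
  traj
}

new_trajectory <- function(xyz, atom, frame_spacing = NA_real_) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3L * nrow(atom))
  res <- unique(atom[, c("chain", "resno", "resid")])
  rownames(res) <- NULL
  structure(list(xyz = xyz, atom = atom, residues = res,
                 n_frames = nrow(xyz), frame_spacing = frame_spacing),
            class = "pdb_trajectory")
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `pdb_trajectory`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   resno = traj$atom$resno, resid = traj$atom$resid,
                   chain = traj$atom$chain, elety = traj$atom$elety)
  invisible(path)
}

## Atom-row index of the node atom of each residue under a scheme.
node_atom_indices <- function(atom, residues, scheme = c("CA", "CB")) {
  scheme <- match.arg(scheme)
  key <- paste(atom$chain, atom$resno)
  rkey <- paste(residues$chain, residues$resno)
  vapply(seq_len(nrow(residues)), function(i) {
    rows <- which(key == rkey[i])
    elety <- atom$elety[rows]
    if (scheme == "CA") {
      j <- rows[match("CA", elety)]
    } else {
      j <- rows[match("CB", elety)]
      if (is.na(j)) {
        ## Calpha stands in for glycine, which has no Cbeta.
        if (residues$resid[i] == "GLY") {
          j <- rows[match("CA", elety)]
        } else {
          stop("residue ", residues$chain[i], residues$resno[i], " (",
               residues$resid[i], ") has no CB atom (and is not glycine)")
        }
      }
    }
    if (is.na(j))
      stop("residue ", residues$chain[i], residues$resno[i], " (",
           residues$resid[i], ") has no ", scheme, " atom")
    j
  }, integer(1L))
}

#' Node coordinates of a structure
#'
#' Each residue maps to exactly one node atom: its Calpha (`scheme = "CA"`)
#' or its Cbeta with Calpha substituted for glycine (`scheme = "CB"`).
#'
#' @param x a `pdb_structure`.
#' @param scheme `"CA"` or `"CB"`.
#' @return an N x 3 coordinate matrix (rows named by chain + residue number).
#' @export
node_coordinates <- function(x, scheme = c("CA", "CB")) {
  stopifnot(inherits(x, "pdb_structure"))
  scheme <- match.arg(scheme)
  idx <- node_atom_indices(x$atom, x$residues, scheme)
  m <- as.matrix(x$atom[idx, c("x", "y", "z")])
  dimnames(m) <- list(residue_labels(x), c("x", "y", "z"))
  m
}

#' Reduce a trajectory to one node per residue
#'
#' @param traj a `pdb_trajectory` (any selection that still contains the
#'   needed atoms).
#' @param scheme `"CA"` or `"CB"` (Calpha for glycine).
#' @return a `pdb_trajectory` whose frames hold N node coordinates.
#' @export
trajectory_nodes <- function(traj, scheme = c("CA", "CB")) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  scheme <- match.arg(scheme)
  idx <- node_atom_indices(traj$atom, traj$residues, scheme)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  new_trajectory(traj$xyz[, cols, drop = FALSE],
                 traj$atom[idx, , drop = FALSE], traj$frame_spacing)
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("pdb_structure:", n_residues(x), "residues,", nrow(x$atom), "atoms\n")
  invisible(x)
}

#' @export
print.pdb_trajectory <- function(x, ...) {
  cat("pdb_trajectory:", x$n_frames, "frames x", nrow(x$atom), "atoms (",
      n_residues(x), "residues )\n")
  invisible(x)
}
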