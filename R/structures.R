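#' Molecular structure model
#'
#' One model (one coordinate set) of a molecule: an atom-metadata table
#' plus an `n x 3` coordinate matrix in Angstrom. Atom order is
#' significant and is preserved by all readers/writers.
#'
#' @param atoms Data frame with columns `atom_name`, `residue_index`
#'   (1-based, as deposited), `residue_name`, and optionally `element` and
#'   `insert` (insertion code).
#' @param xyz Numeric matrix, `nrow(atoms) x 3`, Angstrom.
#' @param model_id Integer model identifier (MODEL serial in a
#'   multi-model file).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz, model_id = 1L) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom_name", "residue_index", "residue_name")
  if (!all(need %in% names(atoms)))
    stop_("atoms needs columns atom_name, residue_index, residue_name")
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != nrow(atoms))
    stop_("xyz must be a numeric nrow(atoms) x 3 matrix")
  if (any(!is.finite(xyz))) stop_("non-finite coordinate")
  if (any(atoms$residue_index < 1L)) stop_("residue_index must be >= 1")
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(trimws(atoms$atom_name), 1L, 1L))
  if (is.null(atoms$insert)) atoms$insert <- ""
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, model_id = as.integer(model_id)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model %d: %d atoms, %d residues\n", x$model_id,
              nrow(x$atoms), length(unique(x$atoms$residue_index))))
  invisible(x)
}

#' Trajectory ensemble
#'
#' Frames x atoms x 3 coordinates (Angstrom) plus the shared atom
#' metadata. All frames have identical atom count and order.
#'
#' @param coords A `frames x atoms x 3` numeric array, or a list of
#'   `atoms x 3` matrices.
#' @param atoms Atom-metadata data frame as in [structure_model()].
#' @param frame_times Optional numeric vector of frame times (ns).
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(coords, atoms, frame_times = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    nat <- unique(vapply(coords, nrow, integer(1)))
    if (length(nat) != 1L) stop_("all frames must share one atom count")
    arr <- array(0, dim = c(length(coords), nat, 3L))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  if (dim(coords)[2L] != nrow(atoms))
    stop_("atom metadata does not match frame atom count")
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1L])
    stop_("frame_times length must equal the number of frames")
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(trimws(atoms$atom_name), 1L, 1L))
  if (is.null(atoms$insert)) atoms$insert <- ""
  structure(list(coords = coords, atoms = atoms, frame_times = frame_times),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n", n_frames(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory_ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  dim(traj$coords)[1L]
}

#' Extract one frame of a trajectory as a coordinate matrix
#' @param traj A [trajectory_ensemble()].
#' @param i Frame index (1-based).
#' @return An `atoms x 3` matrix.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (i < 1L || i > n_frames(traj)) stop_("frame index out of range")
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Extract one frame as a structure model
#' @inheritParams get_frame
#' @return A [structure_model()].
#' @export
frame_structure <- function(traj, i) {
  structure_model(traj$atoms, get_frame(traj, i), model_id = i)
}

#' Stack structure models into a trajectory ensemble
#'
#' @param models List of [structure_model()]s with identical atom order
#'   (e.g. the output of [read_multimodel_pdb()]).
#' @return A [trajectory_ensemble()].
#' @export
as_trajectory <- function(models) {
  if (inherits(models, "structure_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "structure_model")))
  trajectory_ensemble(lapply(models, `[[`, "xyz"), models[[1L]]$atoms)
}

#' Resolve an atom selection to indices
#'
#' Deterministic selection over the atom-metadata table: the returned
#' indices are the atoms matching *all* supplied filters, in table order.
#' Residue indices are 1-based as deposited. For the usual
#' "backbone of the central six base pairs" selection of an 8+8 duplex,
#' pass `residue_index = c(2:7, 10:15)` together with the backbone atom
#' names used by your topology.
#'
#' @param atoms Atom-metadata data frame (or a [structure_model()] /
#'   [trajectory_ensemble()], whose metadata is used).
#' @param atom_name,residue_index,residue_name Optional filters; `NULL`
#'   means no constraint.
#' @param predicate Optional `function(atom_name, residue_index,
#'   residue_name)` returning a logical vector, applied on top of the
#'   filters.
#' @return Integer vector of atom indices (1-based); errors when empty.
#' @export
select_atoms <- function(atoms, atom_name = NULL, residue_index = NULL,
                         residue_name = NULL, predicate = NULL) {
  if (inherits(atoms, "structure_model") || inherits(atoms, "trajectory_ensemble"))
    atoms <- atoms$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(atom_name)) keep <- keep & atoms$atom_name %in% atom_name
  if (!is.null(residue_index)) keep <- keep & atoms$residue_index %in% residue_index
  if (!is.null(residue_name)) keep <- keep & atoms$residue_name %in% residue_name
  if (!is.null(predicate))
    keep <- keep & predicate(atoms$atom_name, atoms$residue_index, atoms$residue_name)
  idx <- which(keep)
  if (length(idx) == 0L) stop_("selection resolves to no atoms")
  idx
}
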