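# Multi-model PDB reading/writing (PDB v3.x fixed columns).
# Occupancy/B-factor are ignored on read and written as 1.00/0.00; the
# coordinate fields use the standard 8.3 columns, so coordinates survive a
# round trip to 3 decimals.

parse_atom_line <- function(line, lineno) {
  f <- function(a, b) substr(line, a, b)
  xyz <- suppressWarnings(as.numeric(c(f(31, 38), f(39, 46), f(47, 54))))
  if (any(is.na(xyz)))
    stop_(sprintf("unparseable coordinate field at line %d: '%s'", lineno, line))
  resid <- suppressWarnings(as.integer(trimws(f(23, 26))))
  if (is.na(resid))
    stop_(sprintf("unparseable residue number at line %d", lineno))
  list(atom_name = trimws(f(13, 16)),
       residue_name = trimws(f(18, 20)),
       residue_index = resid,
       insert = trimws(f(27, 27)),
       element = trimws(f(77, 78)),
       xyz = xyz)
}

#' Read a multi-model PDB file
#'
#' Parses ATOM/HETATM records of a PDB v3.x file into one
#' [structure_model()] per MODEL block (a file without MODEL records
#' yields exactly one model). Atom names are whitespace-stripped;
#' insertion codes are kept in the `insert` metadata column. All models
#' in one file must have identical atom count and ordering; a mismatch is
#' a hard error naming the offending model, and an unparseable coordinate
#' field is a hard error with the line number.
#'
#' @param path Path to the PDB file.
#' @return List of [structure_model()]s.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop_(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur <- list(); cur_id <- NA_integer_; seen_model <- FALSE
  flush_model <- function() {
    if (length(cur) == 0L) return()
    atoms <- data.frame(
      atom_name = vapply(cur, `[[`, character(1), "atom_name"),
      residue_index = vapply(cur, `[[`, integer(1), "residue_index"),
      residue_name = vapply(cur, `[[`, character(1), "residue_name"),
      element = vapply(cur, `[[`, character(1), "element"),
      insert = vapply(cur, `[[`, character(1), "insert"))
    blank <- !nzchar(atoms$element)
    atoms$element[blank] <- toupper(substr(atoms$atom_name[blank], 1L, 1L))
    xyz <- do.call(rbind, lapply(cur, `[[`, "xyz"))
    id <- if (is.na(cur_id)) length(models) + 1L else cur_id
    models[[length(models) + 1L]] <<- structure_model(atoms, xyz, model_id = id)
  }
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (rec == "MODEL ") {
      flush_model(); cur <- list(); seen_model <- TRUE
      cur_id <- suppressWarnings(as.integer(trimws(substr(lines[i], 11, 14))))
    } else if (rec == "ENDMDL") {
      flush_model(); cur <- list(); cur_id <- NA_integer_
    } else if (rec == "ATOM  " || rec == "HETATM") {
      cur[[length(cur) + 1L]] <- parse_atom_line(lines[i], i)
    }
  }
  flush_model()
  if (length(models) == 0L) stop_(sprintf("no ATOM/HETATM records in %s", path))
  ref <- models[[1L]]
  for (m in models[-1L]) {
    if (nrow(m$atoms) != nrow(ref$atoms))
      stop_(sprintf("model %d has %d atoms but model %d has %d: inconsistent multi-model file",
                    m$model_id, nrow(m$atoms), ref$model_id, nrow(ref$atoms)))
    if (!identical(m$atoms$atom_name, ref$atoms$atom_name) ||
        !identical(m$atoms$residue_index, ref$atoms$residue_index))
      stop_(sprintf("model %d atom ordering differs from model %d",
                    m$model_id, ref$model_id))
  }
  if (!seen_model && length(models) != 1L)
    stop_("internal: MODEL-less file produced multiple models")
  models
}

format_atom_line <- function(serial, name, resname, resid, insert, xyz, element) {
  # atom-name column convention: names of < 4 chars start in column 14
  name4 <- if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %-4s %-3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name4, substr(resname, 1, 3), "A", resid,
          if (nzchar(insert)) insert else " ",
          xyz[1], xyz[2], xyz[3], 1, 0, substr(element, 1, 2))
}

#' Write structure models to a multi-model PDB file
#'
#' Inverse of [read_multimodel_pdb()]: preserves atom count, order, names
#' and coordinates to the 3-decimal PDB precision. A single model is
#' written without MODEL/ENDMDL wrappers; occupancy and B-factor are
#' written as 1.00 and 0.00.
#'
#' @param models A [structure_model()], a list of them, or a
#'   [trajectory_ensemble()] (every frame becomes a model).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(models, path) {
  if (inherits(models, "trajectory_ensemble"))
    models <- lapply(seq_len(n_frames(models)), function(i) frame_structure(models, i))
  if (inherits(models, "structure_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "structure_model")))
  out <- character(0)
  multi <- length(models) > 1L
  for (j in seq_along(models)) {
    m <- models[[j]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", j))
    for (i in seq_len(nrow(m$atoms)))
      out <- c(out, format_atom_line(i, m$atoms$atom_name[i], m$atoms$residue_name[i],
                                     m$atoms$residue_index[i], m$atoms$insert[i],
                                     m$xyz[i, ], m$atoms$element[i]))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
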