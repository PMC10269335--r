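# Delimited scan tables, charge tables, and the CHARMM parameter-stream
# DIHEDRALS stanza. Delimiters (tab/comma/whitespace) are autodetected;
# '#' and '!' comment lines are tolerated.

read_delim_numeric <- function(path, ncol_min) {
  if (!file.exists(path)) stop_(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#!]", lines)]
  if (length(lines) == 0L) stop_(sprintf("no data rows in %s", path))
  parts <- strsplit(lines, "[,\t ]+")
  n <- vapply(parts, length, integer(1))
  if (any(n < ncol_min))
    stop_(sprintf("row %d has fewer than %d columns", which(n < ncol_min)[1L], ncol_min))
  parts
}

#' Read a torsional scan table
#'
#' Reads a two-column delimited text table (angle in degrees, relative
#' energy in kcal/mol; tab/comma/whitespace autodetected, `#`/`!` comment
#' lines skipped) into an [energy_profile()]. With the default
#' `wrap = TRUE`, angles are wrapped into `[0, 360)` and rows sorted by
#' angle; a duplicate angle after wrapping (including a 360 row colliding
#' with a 0 row) is a hard error. Use `wrap = FALSE` to keep a pre-wrap
#' full-turn scan containing both the 0 and 360 endpoints, as needed by
#' [check_scan_periodicity()].
#'
#' @param path Path to the table.
#' @param wrap Wrap angles into `[0, 360)` (default `TRUE`).
#' @param normalize Shift energies so the minimum is 0 (default `TRUE`).
#' @return An [energy_profile()].
#' @export
read_scan_table <- function(path, wrap = TRUE, normalize = TRUE) {
  parts <- read_delim_numeric(path, 2L)
  vals <- suppressWarnings(lapply(parts, function(p) as.numeric(p[1:2])))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop_(sprintf("non-numeric cell in data row %d of %s", bad[1L], path))
  m <- do.call(rbind, vals)
  angles <- m[, 1L]; energies <- m[, 2L]
  if (wrap) angles <- wrap360(angles)
  o <- order(angles)
  angles <- angles[o]; energies <- energies[o]
  dup <- which(diff(angles) < 1e-9)
  if (length(dup))
    stop_(sprintf("duplicate scan angle %.6g deg%s", angles[dup[1L]],
                  if (wrap) " (after wrapping to [0, 360))" else ""))
  energy_profile(angles, energies, normalize = normalize)
}

#' Write a torsional scan table
#'
#' Tab-separated two-column table (angle deg, energy kcal/mol) written at
#' full double precision so that write-then-read is the identity.
#'
#' @param profile An [energy_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scan_table <- function(profile, path) {
  stopifnot(inherits(profile, "energy_profile"))
  writeLines(c("# angle_deg\tenergy_kcal_mol",
               sprintf("%.17g\t%.17g", profile$angles, profile$energies)), path)
  invisible(path)
}

#' Read a charge table
#'
#' Two-column delimited table: atom name, partial charge (e).
#'
#' @param path Path to the table.
#' @param group_id Optional group label for the resulting set.
#' @return A [charge_set()].
#' @export
read_charge_table <- function(path, group_id = "") {
  parts <- read_delim_numeric(path, 2L)
  atoms <- vapply(parts, `[[`, character(1), 1L)
  ch <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(ch)) stop_(sprintf("non-numeric charge in data row %d", which(is.na(ch))[1L]))
  charge_set(stats::setNames(ch, atoms), group_id = group_id)
}

#' Write a charge table
#'
#' Tab-separated `atom_name`, `charge`. Default full precision (so that
#' write-then-read is the identity); pass `digits = 2` for the
#' fixed-decimal CHARMM-style output.
#'
#' @param set A [charge_set()].
#' @param path Output path.
#' @param digits `NULL` for full precision, or an integer number of
#'   decimals.
#' @return Invisibly, `path`.
#' @export
write_charge_table <- function(set, path, digits = NULL) {
  stopifnot(inherits(set, "charge_set"))
  fmt <- if (is.null(digits)) "%.17g" else paste0("%.", digits, "f")
  writeLines(c("# atom_name\tcharge_e",
               sprintf(paste0("%s\t", fmt), set$atom, set$charge)), path)
  invisible(path)
}

#' Write a CHARMM parameter-stream DIHEDRALS stanza
#'
#' Emits one DIHEDRALS stanza line per torsion term: four atom types,
#' force constant (kcal/mol, 4 decimals), multiplicity and phase offset
#' (degrees, 2 decimals), delimited by whitespace, between `DIHEDRALS`
#' and `END` markers. The file is re-readable by
#' [read_parameter_stream()], which recovers the values exactly at the
#' written precision.
#'
#' @param series Non-empty [dihedral_series()].
#' @param atom_types Character vector of the four atom types of the
#'   torsion, all non-blank.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_parameter_stream <- function(series, atom_types, path) {
  stopifnot(inherits(series, "dihedral_series"))
  if (length(series$terms) == 0L) stop_("refusing to write an empty torsion series")
  atom_types <- as.character(atom_types)
  if (length(atom_types) != 4L || any(!nzchar(trimws(atom_types))))
    stop_("atom_types must be 4 non-blank strings")
  for (t in series$terms) {
    if (t$n <= 0) stop_("multiplicity must be positive")
    if (t$delta < -180 || t$delta >= 360) stop_("offset outside [-180, 360)")
  }
  lines <- c("* torsion parameters written by pnadyn", "*", "", "DIHEDRALS")
  for (t in series$terms)
    lines <- c(lines, sprintf("%-6s %-6s %-6s %-6s %10.4f %2d %8.2f",
                              atom_types[1], atom_types[2], atom_types[3],
                              atom_types[4], t$k, t$n, t$delta))
  lines <- c(lines, "", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a CHARMM parameter-stream DIHEDRALS stanza
#'
#' Companion reader for [write_parameter_stream()].
#'
#' @param path Path to the stream file.
#' @return List with `series` (a [dihedral_series()]) and `atom_types`
#'   (character matrix, one row per term).
#' @export
read_parameter_stream <- function(path) {
  if (!file.exists(path)) stop_(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  i0 <- which(lines == "DIHEDRALS")
  if (length(i0) != 1L) stop_("no single DIHEDRALS stanza found")
  body <- lines[seq(i0 + 1L, length(lines))]
  stop_at <- which(body %in% c("END") | grepl("^[A-Z]+$", body) & body != "")
  if (length(stop_at)) body <- body[seq_len(stop_at[1L] - 1L)]
  body <- body[nzchar(body) & !grepl("^[*!]", body)]
  if (length(body) == 0L) stop_("empty DIHEDRALS stanza")
  terms <- list(); types <- NULL
  for (ln in body) {
    f <- strsplit(ln, "[ \t]+")[[1L]]
    if (length(f) < 7L) stop_(sprintf("malformed stanza line: '%s'", ln))
    k <- as.numeric(f[5L]); n <- as.integer(f[6L]); delta <- as.numeric(f[7L])
    if (anyNA(c(k, n, delta))) stop_(sprintf("non-numeric parameter in line: '%s'", ln))
    terms[[length(terms) + 1L]] <- dihedral_term(k, n, delta)
    types <- rbind(types, f[1:4])
  }
  list(series = dihedral_series(terms), atom_types = types)
}
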