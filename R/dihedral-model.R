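#' Periodic torsion term
#'
#' One term of a CHARMM-style torsion Fourier series,
#' \eqn{E(\phi) = k_\chi (1 + \cos(n\phi - \delta))}, with force constant
#' `k` (kcal/mol, non-negative), integer multiplicity `n` and phase offset
#' `delta` (degrees).
#'
#' @param k Force constant \eqn{k_\chi} in kcal/mol; must be finite and
#'   `>= 0` (phases of 0/180 degrees absorb the sign, the usual CHARMM
#'   convention).
#' @param n Multiplicity, a positive integer (1--6 under the default
#'   policy).
#' @param delta Phase offset in degrees, in `[-180, 360)`.
#' @return An object of class `dihedral_term`.
#' @seealso [dihedral_series()], [dihedral_energy()]
#' @export
#' @examples
#' dihedral_term(2.40, 3, 0)
dihedral_term <- function(k, n, delta = 0) {
  if (!is.finite(k) || k < 0) stop_("force constant k must be finite and >= 0")
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 1)
    stop_("multiplicity n must be a positive integer")
  if (n > 6) stop_("multiplicity n must be in 1..6 under the default policy")
  if (!is.finite(delta) || delta < -180 || delta >= 360)
    stop_("offset delta must lie in [-180, 360) degrees")
  structure(list(k = as.numeric(k), n = as.integer(n), delta = as.numeric(delta)),
            class = "dihedral_term")
}

#' Torsion Fourier series
#'
#' An ordered collection of [dihedral_term()]s summed into one torsion
#' energy function. No two terms may share the same `(n, delta)` pair.
#'
#' @param ... `dihedral_term` objects, or a single list of them.
#' @return An object of class `dihedral_series` (a list with element
#'   `terms`).
#' @export
#' @examples
#' s <- dihedral_series(dihedral_term(2.40, 3, 0), dihedral_term(0.5, 1, 180))
#' dihedral_energy(60, s)
dihedral_series <- function(...) {
  terms <- list(...)
  if (length(terms) == 1L && !inherits(terms[[1L]], "dihedral_term") && is.list(terms[[1L]]))
    terms <- terms[[1L]]
  ok <- vapply(terms, inherits, logical(1), "dihedral_term")
  if (length(terms) && !all(ok)) stop_("all arguments must be dihedral_term objects")
  key <- vapply(terms, function(t) paste(t$n, t$delta), character(1))
  if (anyDuplicated(key)) stop_("duplicate (n, delta) pair in series")
  structure(list(terms = terms), class = "dihedral_series")
}

#' @export
length.dihedral_series <- function(x) length(x$terms)

#' @export
format.dihedral_term <- function(x, ...) {
  sprintf("k_chi = %.4f kcal/mol, n = %d, delta = %.2f deg", x$k, x$n, x$delta)
}

#' @export
print.dihedral_term <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("Torsion series with %d term(s)\n", length(x$terms)))
  for (t in x$terms) cat("  ", format(t), "\n", sep = "")
  invisible(x)
}

#' Evaluate a torsion Fourier series
#'
#' Computes \eqn{E(\phi) = \sum_i k_i (1 + \cos(n_i \phi - \delta_i))} in
#' kcal/mol. Total function: defined for every angle, 360-degree periodic,
#' and non-negative whenever all force constants are non-negative.
#'
#' @param phi Dihedral angle(s) in degrees (vectorized).
#' @param series A [dihedral_series()].
#' @return Numeric vector of energies, kcal/mol.
#' @export
#' @examples
#' dihedral_energy(0, dihedral_series(dihedral_term(1, 1, 0)))   # 2
#' dihedral_energy(60, dihedral_series(dihedral_term(2.4, 3, 0))) # 0
dihedral_energy <- function(phi, series) {
  stopifnot(inherits(series, "dihedral_series"))
  e <- numeric(length(phi))
  for (t in series$terms)
    e <- e + t$k * (1 + cos(deg2rad(t$n * phi - t$delta)))
  e
}

#' Torsional energy profile
#'
#' Ordered (angle, relative energy) samples of a torsional scan. Angles
#' are degrees, strictly increasing within `[0, 360]`; energies are
#' kcal/mol and are shifted so that the minimum is exactly 0 when
#' `normalize = TRUE` (the default), since relative energetics are only
#' defined up to a constant.
#'
#' @param angles Strictly increasing numeric vector of scan angles
#'   (degrees). The 360 endpoint is permitted so that pre-wrap scans can
#'   be checked for periodicity; see [check_scan_periodicity()].
#' @param energies Numeric vector of relative energies (kcal/mol), same
#'   length as `angles`.
#' @param normalize Shift energies so `min(energies) == 0`.
#' @return An object of class `energy_profile`.
#' @export
energy_profile <- function(angles, energies, normalize = TRUE) {
  angles <- as.numeric(angles); energies <- as.numeric(energies)
  if (length(angles) != length(energies)) stop_("angles and energies differ in length")
  if (length(angles) < 3L) stop_("an energy profile needs at least 3 points")
  if (any(!is.finite(angles)) || any(!is.finite(energies)))
    stop_("non-finite angle or energy")
  if (is.unsorted(angles, strictly = TRUE)) stop_("angles must be strictly increasing")
  if (angles[1L] < 0 || angles[length(angles)] > 360)
    stop_("angles must lie in [0, 360] degrees")
  if (normalize) energies <- energies - min(energies)
  structure(list(angles = angles, energies = energies), class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("Energy profile: %d points, %.1f..%.1f deg, max %.3f kcal/mol\n",
              length(x$angles), min(x$angles), max(x$angles), max(x$energies)))
  invisible(x)
}

#' Torsional scan grid specification
#'
#' Records the scan protocol: grid limits and step in degrees, scan
#' direction, and the harmonic restraint force constant used to hold the
#' scanned torsion during the constrained minimizations that produced the
#' profile (provenance metadata only; this package never evaluates a full
#' force field). The default grid is every 15 degrees over a full turn
#' with the endpoint deduplicated, and the default restraint is
#' 1e4 kcal/mol.radian^2.
#'
#' @param start,stop,step Grid in degrees; `step` must divide
#'   `stop - start`.
#' @param direction `"forward"` or `"backward"`. A backward re-scan is the
#'   standard remedy when a forward scan ends in a different, lower-energy
#'   conformer (a nonperiodic profile).
#' @param restraint_k Harmonic restraint force constant,
#'   kcal/mol.radian^2, `> 0`.
#' @return An object of class `scan_spec`.
#' @export
scan_spec <- function(start = 0, stop = 345, step = 15,
                      direction = c("forward", "backward"), restraint_k = 1e4) {
  direction <- match.arg(direction)
  if (step <= 0) stop_("step must be positive")
  if (abs((stop - start) / step - round((stop - start) / step)) > 1e-9)
    stop_("step must divide stop - start")
  if (restraint_k <= 0) stop_("restraint_k must be positive")
  structure(list(start = start, stop = stop, step = step,
                 direction = direction, restraint_k = restraint_k),
            class = "scan_spec")
}

#' @export
print.scan_spec <- function(x, ...) {
  cat(sprintf("Scan %g..%g deg, step %g (%s), restraint %g kcal/mol.rad^2\n",
              x$start, x$stop, x$step, x$direction, x$restraint_k))
  invisible(x)
}

scan_angles <- function(grid) {
  a <- seq(grid$start, grid$stop, by = grid$step)
  if (grid$direction == "backward") a <- rev(a)
  a
}

#' Evaluate a torsion series on a scan grid
#'
#' @param series A [dihedral_series()].
#' @param grid A [scan_spec()] or a numeric vector of angles (degrees).
#' @return An [energy_profile()] on the grid, min-shifted to 0.
#' @export
profile_from_series <- function(series, grid = scan_spec()) {
  angles <- if (inherits(grid, "scan_spec")) scan_angles(grid) else as.numeric(grid)
  if (length(angles) == 0L) stop_("empty scan grid")
  angles <- sort(angles)
  energy_profile(angles, dihedral_energy(angles, series), normalize = TRUE)
}

#' Check a torsional scan for end-point periodicity
#'
#' A full-turn scan of a well-behaved torsion must return to its starting
#' energy: a gap between E(0) and E(360) means the final structure relaxed
#' into a different conformer and the scan is nonperiodic. The standard
#' remedy is to re-scan backward from 360 to 0 starting from the ending
#' geometry; a nonperiodic verdict carries that recommendation.
#'
#' @param profile An [energy_profile()] that still contains both the 0 and
#'   360 degree endpoints (read the table with `wrap = FALSE`; see
#'   [read_scan_table()]).
#' @param tol Gap tolerance in kcal/mol (default 0.1).
#' @return A list with elements `periodic` (logical), `gap` (kcal/mol,
#'   `|E(0) - E(360)|`) and `rescan_backward` (logical recommendation).
#' @export
check_scan_periodicity <- function(profile, tol = 0.1) {
  stopifnot(inherits(profile, "energy_profile"))
  i0 <- which(abs(profile$angles - 0) < 1e-9)
  i1 <- which(abs(profile$angles - 360) < 1e-9)
  if (length(i0) != 1L || length(i1) != 1L)
    stop_("profile must contain both the 0 and 360 degree endpoints (pre-wrap)")
  gap <- abs(profile$energies[i0] - profile$energies[i1])
  periodic <- gap <= tol
  structure(list(periodic = periodic, gap = gap, rescan_backward = !periodic),
            class = "scan_periodicity")
}

#' @export
print.scan_periodicity <- function(x, ...) {
  cat(sprintf("Scan is %s (|E(0) - E(360)| = %.4f kcal/mol)%s\n",
              if (x$periodic) "periodic" else "NONPERIODIC", x$gap,
              if (x$rescan_backward) "; recommend a backward re-scan from 360 to 0" else ""))
  invisible(x)
}
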