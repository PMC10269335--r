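# Classical per-frame trajectory metrics: Kabsch superposition, RMSD,
# RMSF, hydrogen-bond occupancy and torsion distributions.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' the selected atoms of `mobile` and `reference`. The rotation is
#' computed from the SVD of the cross-covariance with the determinant
#' sign fixed to +1 (no reflections). Coordinates transform as row
#' vectors: `moved = mobile %*% rotation + translation`.
#'
#' @param mobile,reference `atoms x 3` coordinate matrices with matching
#'   atom order.
#' @param selection Optional integer atom indices the fit (and the
#'   returned RMSD) are computed over; default all atoms. At least 3
#'   non-collinear atoms are required.
#' @return List with `rotation` (3x3), `translation` (length 3), and
#'   `rmsd` (Angstrom, over the selection after the fit).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  sel <- selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3L) stop_("superposition needs at least 3 selected atoms")
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2L, pc); Q0 <- sweep(Q, 2L, qc)
  # collinearity check: rank of the centered reference must exceed 1
  sv_ref <- svd(Q0, nu = 0, nv = 0)$d
  if (sv_ref[2L] < 1e-8 * max(sv_ref[1L], 1))
    stop_("degenerate selection: selected atoms are (near-)collinear")
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  translation <- qc - as.numeric(pc %*% R)
  moved <- P %*% R + matrix(translation, nrow(P), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

apply_rigid <- function(xyz, fit) {
  xyz %*% fit$rotation + matrix(fit$translation, nrow(xyz), 3L, byrow = TRUE)
}

raw_rmsd <- function(a, b, sel) sqrt(mean(rowSums((a[sel, , drop = FALSE] - b[sel, , drop = FALSE])^2)))

#' Per-frame RMSD against a reference frame
#'
#' Root-mean-square deviation of each frame from a chosen reference
#' frame, over a selection, by default after least-squares superposition
#' on that same selection (the usual convention; set `fit = FALSE` for
#' raw RMSD in the laboratory frame). The series is exactly 0 at the
#' reference frame.
#'
#' @param traj A [trajectory_ensemble()].
#' @param reference Reference frame index (default 1, typically the first
#'   frame after equilibration).
#' @param selection Integer atom indices (see [select_atoms()]); default
#'   all atoms.
#' @param fit Superpose each frame before measuring (default `TRUE`).
#' @return Numeric vector, Angstrom, one value per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (reference < 1L || reference > n_frames(traj)) stop_("invalid reference frame index")
  sel <- selection %||% seq_len(nrow(traj$atoms))
  ref <- get_frame(traj, reference)
  vapply(seq_len(n_frames(traj)), function(i) {
    fr <- get_frame(traj, i)
    if (fit) superpose(fr, ref, sel)$rmsd else raw_rmsd(fr, ref, sel)
  }, numeric(1))
}

#' Per-atom RMSF about the windowed mean structure
#'
#' Frames in the window are first superposed (over the selection) onto
#' the window's first frame, averaged, then re-superposed onto that
#' average and re-averaged -- one iteration of the usual
#' align-to-running-average scheme. The RMSF of each selected atom is the
#' root-mean-square deviation of its position from the final mean
#' coordinates.
#'
#' @param traj A [trajectory_ensemble()].
#' @param selection Integer atom indices; default all atoms.
#' @param window Integer vector of frame indices to average over (e.g.
#'   the frames where the RMSD stayed steady); default all frames.
#' @return Numeric vector, Angstrom, one value per selected atom (named
#'   by atom index).
#' @export
rmsf <- function(traj, selection = NULL, window = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  sel <- selection %||% seq_len(nrow(traj$atoms))
  window <- window %||% seq_len(n_frames(traj))
  if (length(window) == 0L) stop_("empty frame window")
  frames <- lapply(window, function(i) get_frame(traj, i)[sel, , drop = FALSE])
  align_to <- function(frames, ref) lapply(frames, function(f) {
    fit <- superpose(f, ref)
    apply_rigid(f, fit)
  })
  mean_of <- function(frames) Reduce(`+`, frames) / length(frames)
  aligned <- align_to(frames, frames[[1L]])
  aligned <- align_to(aligned, mean_of(aligned))
  mu <- mean_of(aligned)
  dev2 <- lapply(aligned, function(f) rowSums((f - mu)^2))
  out <- sqrt(Reduce(`+`, dev2) / length(dev2))
  names(out) <- as.character(sel)
  out
}

#' Hydrogen-bond geometric criterion
#'
#' A donor--hydrogen...acceptor contact counts as a hydrogen bond in a
#' frame iff the donor--acceptor distance is at most `distance_cutoff`
#' and the D-H-A angle is within `linearity_deviation` of linear, i.e.
#' `angle(D-H-A) >= 180 - linearity_deviation`. Note the angle measured
#' is at the hydrogen (D-H-A), not H-D-A.
#'
#' @param distance_cutoff Donor--acceptor cutoff, Angstrom (default 3.5).
#' @param linearity_deviation Allowed deviation from linearity, degrees,
#'   in (0, 90) (default 30).
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(distance_cutoff = 3.5, linearity_deviation = 30) {
  if (distance_cutoff <= 0) stop_("distance_cutoff must be positive")
  if (linearity_deviation <= 0 || linearity_deviation >= 90)
    stop_("linearity_deviation must lie in (0, 90) degrees")
  structure(list(distance_cutoff = distance_cutoff,
                 linearity_deviation = linearity_deviation),
            class = "hbond_criterion")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For every (donor, acceptor) combination, the fraction of frames in
#' which the geometric criterion holds (see [hbond_criterion()]).
#'
#' @param traj A [trajectory_ensemble()].
#' @param donors Two-column integer matrix (or data frame) of atom
#'   indices: column 1 the donor heavy atom D, column 2 its bonded
#'   hydrogen H.
#' @param acceptors Integer vector of acceptor atom indices.
#' @param criterion An [hbond_criterion()].
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom indices) and `occupancy` (fraction in \[0, 1\]).
#' @export
hbond_occupancy <- function(traj, donors, acceptors, criterion = hbond_criterion()) {
  stopifnot(inherits(traj, "trajectory_ensemble"), inherits(criterion, "hbond_criterion"))
  donors <- as.matrix(donors)
  if (nrow(donors) == 0L || length(acceptors) == 0L)
    stop_("donor and acceptor lists must be non-empty")
  if (ncol(donors) != 2L) stop_("donors must be a 2-column (D, H) matrix")
  nf <- n_frames(traj)
  min_angle <- 180 - criterion$linearity_deviation
  out <- expand.grid(pair = seq_len(nrow(donors)), acceptor = acceptors,
                     KEEP.OUT.ATTRS = FALSE)
  counts <- numeric(nrow(out))
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    for (r in seq_len(nrow(out))) {
      D <- fr[donors[out$pair[r], 1L], ]
      H <- fr[donors[out$pair[r], 2L], ]
      A <- fr[out$acceptor[r], ]
      if (sqrt(sum((D - A)^2)) > criterion$distance_cutoff) next
      v1 <- D - H; v2 <- A - H
      ang <- rad2deg(acos(clamp1(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
      if (ang >= min_angle) counts[r] <- counts[r] + 1
    }
  }
  data.frame(donor = donors[out$pair, 1L], hydrogen = donors[out$pair, 2L],
             acceptor = out$acceptor, occupancy = counts / nf)
}

# signed dihedral (degrees, IUPAC convention: cis = 0) of 4 points
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Torsion angle of four atoms along a trajectory
#'
#' Signed dihedral angle via the standard atan2 construction, IUPAC sign
#' convention (cis = 0 degrees, clockwise positive viewed from the first
#' atom), reported in `(-180, 180]`.
#'
#' @param traj A [trajectory_ensemble()].
#' @param atoms Integer vector of four distinct atom indices, in bonded
#'   order.
#' @return Numeric vector of angles (degrees), one per frame.
#' @export
torsion_series <- function(traj, atoms) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  atoms <- as.integer(atoms)
  if (length(atoms) != 4L || anyDuplicated(atoms))
    stop_("atoms must be four distinct atom indices")
  vapply(seq_len(n_frames(traj)), function(i) {
    fr <- get_frame(traj, i)
    dihedral_angle(fr[atoms[1L], ], fr[atoms[2L], ], fr[atoms[3L], ], fr[atoms[4L], ])
  }, numeric(1))
}

#' Probability histogram of torsion values
#'
#' Bins covering `(-180, 180]`; `bin_width` must divide 360. Values of
#' exactly -180 are mapped to 180 first. Probabilities sum to 1.
#'
#' @param series Numeric vector of torsion angles, degrees.
#' @param bin_width Bin width in degrees (default 10).
#' @return Data frame with columns `lower`, `upper`, `mid` (degrees) and
#'   `probability`.
#' @export
torsion_histogram <- function(series, bin_width = 10) {
  if (length(series) == 0L) stop_("empty torsion series")
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9)
    stop_("bin_width must divide 360")
  x <- wrap180(series)
  breaks <- seq(-180, 180, by = bin_width)
  # (lower, upper] bins
  idx <- findInterval(x, breaks, left.open = TRUE, rightmost.closed = FALSE)
  idx[idx == 0L] <- 1L  # x == -180 mapped to 180 by wrap180; guard anyway
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L],
             mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             probability = counts / length(x))
}
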