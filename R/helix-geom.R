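# Helical-bend estimator from base-pair-plane normals. PNA duplexes are
# not handled by the usual DNA helicoidal-parameter programs, so the bend
# is estimated directly from the geometry of two designated base pairs:
# the angle between the best-fit plane normals through the N1/N3 ring
# nitrogens of each pair.

#' Base-pair specification for bend analysis
#'
#' Identifies one base pair by the residue index on each strand plus the
#' per-base anchor atom names whose positions define the pair plane
#' (default the ring nitrogens N1 and N3, present in both purines and
#' pyrimidines as deposited).
#'
#' @param strand1_res,strand2_res Distinct 1-based residue indices.
#' @param anchors Character vector of anchor atom names per base
#'   (default `c("N1", "N3")`).
#' @return An object of class `base_pair_spec`.
#' @export
#' @examples
#' base_pair_spec(2, 15)  # G2-C15 of an 8+8 duplex
base_pair_spec <- function(strand1_res, strand2_res, anchors = c("N1", "N3")) {
  if (strand1_res == strand2_res) stop_("the two residues must be distinct")
  if (length(anchors) < 1L || any(!nzchar(anchors)))
    stop_("anchors must be non-blank atom names")
  structure(list(strand1_res = as.integer(strand1_res),
                 strand2_res = as.integer(strand2_res),
                 anchors = as.character(anchors)),
            class = "base_pair_spec")
}

pair_anchor_xyz <- function(atoms, xyz, pair) {
  rows <- integer(0)
  for (res in c(pair$strand1_res, pair$strand2_res))
    for (an in pair$anchors) {
      i <- which(atoms$residue_index == res & atoms$atom_name == an)
      if (length(i) == 0L)
        stop_(sprintf("anchor atom %s of residue %d not found", an, res))
      rows <- c(rows, i[1L])
    }
  xyz[rows, , drop = FALSE]
}

plane_normal <- function(pts) {
  ctr <- colMeans(pts)
  P <- sweep(pts, 2L, ctr)
  e <- eigen(crossprod(P), symmetric = TRUE)
  # collinear anchors: the two smallest eigenvalues both ~ 0
  if (e$values[2L] < 1e-10 * max(e$values[1L], 1e-12))
    stop_("anchor atoms are (near-)collinear: no unique plane")
  list(normal = unit(e$vectors[, 3L]), centroid = ctr)
}

#' Best-fit plane normal of a base pair
#'
#' Unit normal of the least-squares plane through the pair's anchor
#' atoms (the smallest-variance principal direction of the anchor
#' points), plus the anchor centroid for diagnostics. The normal's sign
#' is arbitrary.
#'
#' @param structure A [structure_model()].
#' @param pair A [base_pair_spec()].
#' @return List with `normal` (unit 3-vector) and `centroid`.
#' @export
pair_plane_normal <- function(structure, pair) {
  stopifnot(inherits(structure, "structure_model"), inherits(pair, "base_pair_spec"))
  pts <- pair_anchor_xyz(structure$atoms, structure$xyz, pair)
  plane_normal(pts)
}

pair_axis_vector <- function(atoms, xyz, pair) {
  # alternative two-point reading: vector between the per-base midpoints
  # of the anchor atoms
  mid <- function(res) {
    rows <- vapply(pair$anchors, function(an) {
      i <- which(atoms$residue_index == res & atoms$atom_name == an)
      if (length(i) == 0L) stop_(sprintf("anchor atom %s of residue %d not found", an, res))
      i[1L]
    }, integer(1))
    colMeans(xyz[rows, , drop = FALSE])
  }
  unit(mid(pair$strand2_res) - mid(pair$strand1_res))
}

angle_between_folded <- function(u, v) rad2deg(acos(clamp1(abs(sum(u * v)))))

#' Helical bend between two base pairs
#'
#' Angle between the plane normals of two designated base pairs (by
#' default the second and second-to-last pairs of a duplex), folded into
#' `[0, 90]` degrees because plane normals carry an arbitrary sign. The
#' measure is invariant under global rigid motion and under swapping the
#' two pairs. `method = "midpoint"` switches to the alternative
#' two-point reading -- the angle between the vectors joining each
#' base's anchor-atom midpoints -- for sensitivity analysis.
#'
#' @param structure A [structure_model()].
#' @param pair_a,pair_b [base_pair_spec()]s.
#' @param method `"plane"` (default) or `"midpoint"`.
#' @return Bend angle in degrees, in `[0, 90]`.
#' @export
#' @examples
#' d <- build_duplex(duplex_recipe(programmed_bend = 23))
#' helical_bend(d, base_pair_spec(2, 15), base_pair_spec(7, 10))
helical_bend <- function(structure, pair_a, pair_b,
                         method = c("plane", "midpoint")) {
  method <- match.arg(method)
  stopifnot(inherits(structure, "structure_model"))
  if (method == "plane") {
    na <- pair_plane_normal(structure, pair_a)$normal
    nb <- pair_plane_normal(structure, pair_b)$normal
  } else {
    na <- pair_axis_vector(structure$atoms, structure$xyz, pair_a)
    nb <- pair_axis_vector(structure$atoms, structure$xyz, pair_b)
  }
  angle_between_folded(na, nb)
}

#' Helical bend along a trajectory
#'
#' Per-frame [helical_bend()] plus its mean and sample standard
#' deviation, the usual reporting convention for a simulation's bend.
#'
#' @param traj A [trajectory_ensemble()] (or a list of
#'   [structure_model()]s, e.g. an NMR ensemble).
#' @param pair_a,pair_b [base_pair_spec()]s.
#' @param method Passed to [helical_bend()].
#' @return List with `bend` (degrees per frame), `mean`, `sd`.
#' @export
bend_series <- function(traj, pair_a, pair_b, method = c("plane", "midpoint")) {
  method <- match.arg(method)
  if (is.list(traj) && !inherits(traj, "trajectory_ensemble") &&
      all(vapply(traj, inherits, logical(1), "structure_model")))
    traj <- as_trajectory(traj)
  stopifnot(inherits(traj, "trajectory_ensemble"))
  vals <- vapply(seq_len(n_frames(traj)), function(i)
    helical_bend(frame_structure(traj, i), pair_a, pair_b, method = method),
    numeric(1))
  list(bend = vals, mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else 0)
}
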