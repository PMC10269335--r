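# Synthetic generators: torsional scans with planted series, idealized
# duplexes with controllable rise/twist/bend and satisfiable hydrogen-bond
# geometry, and multi-basin frame ensembles. Every generator is
# deterministic under a fixed seed and emits its ground truth alongside
# the data (as the "truth" attribute), which is what recovery tests
# assert against.

rot_x <- function(a) {
  a <- deg2rad(a)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
}
rot_z <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

# rigid 6-atom pseudo-base templates: ring nitrogens N1/N3 defining the
# pair plane, a ring carbon C2, and one donor triplet N2-H2 plus an
# acceptor O2 arranged so that within a pair both D-A distances are
# 2.9 A with linear D-H...A geometry.
pair_template <- function() {
  base1 <- rbind(N1 = c(-4.0,  1.4, 0), N3 = c(-4.0, -1.4, 0),
                 C2 = c(-5.2,  0.0, 0), N2 = c(-2.0,  0.7, 0),
                 H2 = c(-1.0,  0.7, 0), O2 = c(-0.9, -0.7, 0))
  base2 <- -base1          # 180-degree rotation about z: partner base
  rownames(base2) <- rownames(base1)
  list(base1 = base1, base2 = base2,
       elements = c("N", "N", "C", "N", "H", "O"))
}

complement_base <- function(b) c(A = "T", T = "A", G = "C", C = "G")[b]

#' Recipe for an idealized duplex
#'
#' Parameters of the synthetic duplex generator. Defaults mirror an
#' 8-base-pair P-form-like PNA duplex: sequence CCGTACGG with its
#' antiparallel complement, per-step rise 3.35 Angstrom and helical
#' twist 17.5 degrees (the slowly twisting helix family PNA duplexes
#' adopt), no programmed bend, no coordinate noise. The programmed bend
#' is applied as a smooth per-step tilt of the helical axis about a
#' fixed direction and is defined as the plane-normal angle between the
#' second and second-to-last base pairs, i.e. the pairs the bend metric
#' measures.
#'
#' @param n_base_pairs Number of base pairs, `>= 4` (default 8).
#' @param rise Axial rise per step, Angstrom (default 3.35).
#' @param twist Helical twist per step, degrees (default 17.5).
#' @param programmed_bend Target bend between the second and
#'   second-to-last pairs, degrees (default 0).
#' @param noise_sd Isotropic Gaussian positional noise, Angstrom
#'   (default 0).
#' @param seed Optional RNG seed for the noise.
#' @param sequence Base letters of strand 1 (recycled/truncated to
#'   `n_base_pairs`; default CCGTACGG).
#' @return An object of class `duplex_recipe`.
#' @export
duplex_recipe <- function(n_base_pairs = 8L, rise = 3.35, twist = 17.5,
                          programmed_bend = 0, noise_sd = 0, seed = NULL,
                          sequence = c("C", "C", "G", "T", "A", "C", "G", "G")) {
  if (n_base_pairs < 4L) stop_("need at least 4 base pairs")
  if (rise <= 0) stop_("rise must be positive")
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  sequence <- rep_len(toupper(sequence), n_base_pairs)
  if (!all(sequence %in% c("A", "C", "G", "T")))
    stop_("sequence letters must be A/C/G/T")
  structure(list(n_base_pairs = as.integer(n_base_pairs), rise = rise,
                 twist = twist, programmed_bend = programmed_bend,
                 noise_sd = noise_sd, seed = seed, sequence = sequence),
            class = "duplex_recipe")
}

#' Build an idealized duplex structure
#'
#' Places two antiparallel strands of rigid pseudo-bases on a helical
#' axis with the recipe's rise and twist; the programmed bend is applied
#' as a uniform per-step tilt about a fixed axis so that the plane-normal
#' angle between the second and second-to-last base pairs equals
#' `programmed_bend` exactly (before noise). Within every pair the two
#' donor--acceptor contacts are at 2.9 Angstrom with linear D-H...A
#' geometry. Strand 1 carries residues `1..n`; strand 2 carries
#' `n+1..2n` with pair `i` formed by residues `(i, 2n+1-i)` -- for the
#' default 8-mer, the second/second-to-last pairs are residues (2, 15)
#' and (7, 10).
#'
#' The generator's ground truth (programmed bend, measurement pairs,
#' donor/acceptor atom indices) is attached as the `"truth"` attribute.
#'
#' @param recipe A [duplex_recipe()].
#' @return A [structure_model()] with `8 x 2 x 6`-style atom count
#'   (`n_base_pairs * 2 * 6` atoms).
#' @export
build_duplex <- function(recipe = duplex_recipe()) {
  stopifnot(inherits(recipe, "duplex_recipe"))
  n <- recipe$n_base_pairs
  tpl <- pair_template()
  tilt_step <- recipe$programmed_bend / (n - 3L)
  atoms <- NULL; xyz <- NULL
  origin <- c(0, 0, 0)
  for (i in seq_len(n)) {
    Ri <- rot_x((i - 1L) * tilt_step)
    Rtw <- Ri %*% rot_z((i - 1L) * recipe$twist)
    if (i > 1L) origin <- origin + as.numeric(Ri %*% c(0, 0, recipe$rise))
    place <- function(pts) sweep(pts %*% t(Rtw), 2L, origin, `+`)
    b1 <- place(tpl$base1); b2 <- place(tpl$base2)
    res2 <- 2L * n + 1L - i
    atoms <- rbind(atoms,
      data.frame(atom_name = rownames(tpl$base1), residue_index = i,
                 residue_name = recipe$sequence[i], element = tpl$elements),
      data.frame(atom_name = rownames(tpl$base2), residue_index = res2,
                 residue_name = unname(complement_base(recipe$sequence[i])),
                 element = tpl$elements))
    xyz <- rbind(xyz, b1, b2)
  }
  rownames(xyz) <- NULL
  if (recipe$noise_sd > 0) {
    if (!is.null(recipe$seed)) set.seed(recipe$seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = recipe$noise_sd),
                        nrow(xyz), 3L)
  }
  model <- structure_model(atoms, xyz)
  attr(model, "truth") <- list(
    programmed_bend = recipe$programmed_bend,
    pair_a = c(2L, 2L * n - 1L), pair_b = c(n - 1L, n + 2L),
    hbonds = duplex_hbonds(atoms, n))
  model
}

#' Canonical donor/acceptor table of a generated duplex
#'
#' For each base pair of a [build_duplex()] structure, the two
#' donor--hydrogen--acceptor triplets (one per strand) as atom indices.
#'
#' @param atoms Atom-metadata data frame of the generated duplex (or the
#'   duplex/trajectory object itself).
#' @param n_base_pairs Number of base pairs.
#' @return Data frame with columns `pair`, `donor`, `hydrogen`,
#'   `acceptor` (atom indices).
#' @export
duplex_hbonds <- function(atoms, n_base_pairs) {
  if (inherits(atoms, "structure_model") || inherits(atoms, "trajectory_ensemble"))
    atoms <- atoms$atoms
  idx <- function(res, name) {
    i <- which(atoms$residue_index == res & atoms$atom_name == name)
    if (length(i) != 1L) stop_(sprintf("atom %s of residue %d not found", name, res))
    i
  }
  out <- NULL
  for (i in seq_len(n_base_pairs)) {
    r1 <- i; r2 <- 2L * n_base_pairs + 1L - i
    out <- rbind(out,
      data.frame(pair = i, donor = idx(r1, "N2"), hydrogen = idx(r1, "H2"),
                 acceptor = idx(r2, "O2")),
      data.frame(pair = i, donor = idx(r2, "N2"), hydrogen = idx(r2, "H2"),
                 acceptor = idx(r1, "O2")))
  }
  out
}

#' Build a synthetic multi-model ensemble of a duplex
#'
#' Replicates [build_duplex()] with independent positional noise per
#' model, emulating a deposited NMR-style ensemble with a known
#' programmed bend. Purely synthetic: it shares nothing with any real
#' deposition beyond the duplex layout.
#'
#' @param recipe A [duplex_recipe()] (its `noise_sd`/`seed` are ignored
#'   in favour of the arguments below).
#' @param n_models Number of models (default 11).
#' @param model_noise_sd Per-model positional noise, Angstrom
#'   (default 0.05).
#' @param seed RNG seed.
#' @return List of [structure_model()]s with the recipe's truth attached
#'   to the list.
#' @export
build_duplex_ensemble <- function(recipe = duplex_recipe(), n_models = 11L,
                                  model_noise_sd = 0.05, seed = 1L) {
  base <- build_duplex(duplex_recipe(
    n_base_pairs = recipe$n_base_pairs, rise = recipe$rise,
    twist = recipe$twist, programmed_bend = recipe$programmed_bend,
    noise_sd = 0, sequence = recipe$sequence))
  set.seed(seed)
  models <- lapply(seq_len(n_models), function(m) {
    xyz <- base$xyz + matrix(stats::rnorm(length(base$xyz), sd = model_noise_sd),
                             nrow(base$xyz), 3L)
    structure_model(base$atoms, xyz, model_id = m)
  })
  attr(models, "truth") <- attr(base, "truth")
  models
}

#' Build a synthetic trajectory with scheduled perturbations
#'
#' Frames are the idealized duplex plus isotropic Gaussian thermal noise,
#' with optional events: `break_hbond` displaces both acceptor atoms of a
#' pair along the hydrogen-to-acceptor direction so the donor--acceptor
#' distance exceeds the 3.5 Angstrom criterion during the given frames;
#' `shift_basin` adds a fixed displacement to every strand-1 atom,
#' creating separable conformational basins for the PCA pipeline.
#' Per-frame basin labels and the broken-bond schedule are recorded in
#' the `"truth"` attribute.
#'
#' @param recipe A [duplex_recipe()] (noise-free base geometry is used;
#'   thermal noise is controlled here).
#' @param n_frames Number of frames.
#' @param events List of events, each a list with `type`
#'   (`"break_hbond"` or `"shift_basin"`), `frames` (integer vector),
#'   and `pair` + optional `displacement` (default 1.5 Angstrom) for
#'   `break_hbond`, or `vector` (length-3 displacement) for
#'   `shift_basin`.
#' @param thermal_sd Thermal noise per coordinate, Angstrom
#'   (default 0.1).
#' @param seed RNG seed (default the recipe's seed, else 1).
#' @return A [trajectory_ensemble()] with attribute `"truth"`: `basin`
#'   (integer per frame, 1 = unperturbed), `broken` (data frame of pair
#'   and frame), and the duplex truth fields.
#' @export
build_trajectory <- function(recipe = duplex_recipe(), n_frames = 100L,
                             events = list(), thermal_sd = 0.1,
                             seed = NULL) {
  base_recipe <- duplex_recipe(n_base_pairs = recipe$n_base_pairs,
                               rise = recipe$rise, twist = recipe$twist,
                               programmed_bend = recipe$programmed_bend,
                               noise_sd = 0, sequence = recipe$sequence)
  base <- build_duplex(base_recipe)
  n <- recipe$n_base_pairs
  hb <- duplex_hbonds(base$atoms, n)
  strand1 <- which(base$atoms$residue_index <= n)
  set.seed(seed %||% recipe$seed %||% 1L)

  basin <- rep(1L, n_frames)
  broken <- data.frame(pair = integer(0), frame = integer(0))
  n_basins <- 1L
  for (ev in events) {
    if (is.null(ev$type) || is.null(ev$frames)) stop_("event needs type and frames")
    if (any(ev$frames < 1L | ev$frames > n_frames))
      stop_("event references frames outside the trajectory")
    if (ev$type == "shift_basin") {
      n_basins <- n_basins + 1L
      basin[ev$frames] <- n_basins
    } else if (ev$type == "break_hbond") {
      if (is.null(ev$pair) || !ev$pair %in% seq_len(n))
        stop_("break_hbond event references an invalid pair")
      broken <- rbind(broken, data.frame(pair = ev$pair, frame = ev$frames))
    } else stop_(sprintf("unknown event type '%s'", ev$type))
  }

  coords <- array(0, dim = c(n_frames, nrow(base$xyz), 3L))
  for (f in seq_len(n_frames)) {
    fr <- base$xyz
    for (ev in events) {
      if (!f %in% ev$frames) next
      if (ev$type == "break_hbond") {
        disp <- ev$displacement %||% 1.5
        rows <- hb[hb$pair == ev$pair, ]
        for (r in seq_len(nrow(rows))) {
          a <- rows$acceptor[r]; h <- rows$hydrogen[r]
          fr[a, ] <- fr[a, ] + disp * unit(base$xyz[a, ] - base$xyz[h, ])
        }
      } else if (ev$type == "shift_basin") {
        fr[strand1, ] <- sweep(fr[strand1, , drop = FALSE], 2L,
                               as.numeric(ev$vector), `+`)
      }
    }
    if (thermal_sd > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), sd = thermal_sd), nrow(fr), 3L)
    coords[f, , ] <- fr
  }
  traj <- trajectory_ensemble(coords, base$atoms)
  attr(traj, "truth") <- c(list(basin = basin, broken = broken),
                           attr(base, "truth"))
  traj
}

#' Synthesize a torsional scan with a planted series
#'
#' Builds a baseline profile from a smooth shape function and a target
#' profile equal to baseline + planted torsion series + optional
#' Gaussian noise, both min-shifted; the planted series is returned as
#' ground truth for recovery tests. Stands in for a quantum-mechanical
#' target scan and its molecular-mechanics baseline.
#'
#' @param series The planted [dihedral_series()] (may be empty).
#' @param baseline_shape Function of angle (degrees) giving the smooth
#'   baseline energy (kcal/mol); default a fixed two-harmonic shape.
#' @param noise_sd Gaussian noise on the target, kcal/mol (default 0).
#' @param seed RNG seed for the noise.
#' @param grid A [scan_spec()] or numeric angle vector.
#' @return List with `target`, `baseline` (both [energy_profile()]s) and
#'   `truth` (the planted series).
#' @export
synth_scan <- function(series = dihedral_series(), baseline_shape = NULL,
                       noise_sd = 0, seed = NULL, grid = scan_spec()) {
  angles <- if (inherits(grid, "scan_spec")) scan_angles(grid) else as.numeric(grid)
  if (length(angles) == 0L) stop_("empty scan grid")
  angles <- sort(angles)
  shape <- baseline_shape %||%
    function(phi) 1.1 * cos(deg2rad(phi - 35)) + 0.6 * cos(deg2rad(2 * phi + 20))
  base_e <- shape(angles)
  targ_e <- base_e + dihedral_energy(angles, series)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    targ_e <- targ_e + stats::rnorm(length(targ_e), sd = noise_sd)
  }
  list(target = energy_profile(angles, targ_e),
       baseline = energy_profile(angles, base_e),
       truth = series)
}
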