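make_traj <- function(frames) {
  n <- nrow(frames[[1]])
  trajectory_ensemble(frames, data.frame(
    atom_name = paste0("X", seq_len(n)), residue_index = seq_len(n),
    residue_name = "RES"))
}

test_that("Kabsch superposition nulls rigid motion and matches a rotational search", {
  set.seed(101)
  P <- matrix(stats::rnorm(15, sd = 3), 5, 3)
  fit <- superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  R <- random_rotation(); t <- c(3, -2, 7)
  moved <- P %*% R + matrix(t, 5, 3, byrow = TRUE)
  expect_lt(superpose(moved, P)$rmsd, 1e-10)
  expect_equal(det(superpose(moved, P)$rotation), 1, tolerance = 1e-10)
  # 4-atom toys against the derivative-free rotational search
  for (rep in 1:3) {
    A <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    B <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    expect_equal(superpose(A, B)$rmsd, oracle_superpose_rmsd(A, B),
                 tolerance = 1e-6)
  }
  line <- cbind(1:4, 1:4, 1:4)
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition agrees with bio3d's least-squares fit", {
  skip_if_not_installed("bio3d")
  set.seed(103)
  A <- matrix(stats::rnorm(30, sd = 2), 10, 3)
  B <- A %*% random_rotation() + matrix(c(1, 2, 3), 10, 3, byrow = TRUE) +
    matrix(stats::rnorm(30, sd = 0.3), 10, 3)
  ref <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
  expect_equal(round(superpose(B, A)$rmsd, 3), ref)  # bio3d prints 3 decimals
})

test_that("RMSD series is zero for constant and rigidly moving trajectories", {
  set.seed(102)
  base <- matrix(stats::rnorm(30, sd = 3), 10, 3)
  const <- make_traj(replicate(5, base, simplify = FALSE))
  expect_equal(rmsd_series(const), rep(0, 5), tolerance = 1e-12)
  rigid <- make_traj(lapply(1:5, function(i)
    base %*% random_rotation() + matrix(stats::rnorm(3), 10, 3, byrow = TRUE)))
  expect_lt(max(rmsd_series(rigid)), 1e-10)
  # single displaced atom: raw RMSD follows the closed form d / sqrt(N)
  d <- 0.8
  shifted <- base; shifted[4, 1] <- shifted[4, 1] + d
  tr <- make_traj(list(base, shifted))
  expect_equal(rmsd_series(tr, fit = FALSE)[2], d / sqrt(10), tolerance = 1e-12)
  expect_lte(rmsd_series(tr)[2], d / sqrt(10) + 1e-12)
  expect_equal(rmsd_series(tr)[1], 0)
  expect_error(rmsd_series(tr, reference = 9), "reference")
})

test_that("RMSF reproduces a two-point oscillation and ignores rigid motion", {
  # symmetric +/-a oscillation of two on-axis atoms: no net translation
  # or rotation, analytic RMSF = a for those atoms, 0 elsewhere
  a <- 0.5
  anchors <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0),
                   c(0, 0, 5), c(0, 0, -5))
  frames <- lapply(1:10, function(i) {
    f <- anchors
    s <- if (i %% 2 == 0) a else -a
    f[1, 1] <- f[1, 1] + s
    f[2, 1] <- f[2, 1] - s
    f
  })
  tr <- make_traj(frames)
  r <- rmsf(tr)
  expect_equal(unname(r[1:2]), c(a, a), tolerance = 1e-10)
  expect_equal(unname(r[3:6]), rep(0, 4), tolerance = 1e-10)
  # constant trajectory -> zeros
  expect_equal(max(rmsf(make_traj(replicate(4, anchors, simplify = FALSE)))), 0,
               tolerance = 1e-12)
  # one global rotation applied to every frame leaves RMSF unchanged
  set.seed(104)
  R <- random_rotation()
  tr_rot <- make_traj(lapply(frames, function(f) f %*% R))
  expect_equal(unname(rmsf(tr_rot)), unname(r), tolerance = 1e-9)
  expect_error(rmsf(tr, window = integer(0)), "empty")
})

test_that("hydrogen-bond occupancy applies the distance and linearity criterion", {
  # linear D-H...A at 2.9 A in every frame
  geom <- function(da) rbind(D = c(0, 0, 0), H = c(1, 0, 0), A = c(da, 0, 0),
                             P = c(0, 5, 0))
  tr <- make_traj(replicate(4, geom(2.9), simplify = FALSE))
  occ <- hbond_occupancy(tr, cbind(1, 2), 3)
  expect_equal(occ$occupancy, 1)
  tr_far <- make_traj(replicate(4, geom(3.6), simplify = FALSE))
  expect_equal(hbond_occupancy(tr_far, cbind(1, 2), 3)$occupancy, 0)
  # bent geometry just past 30 degrees from linearity fails
  bent <- geom(2.9)
  ang <- 35 * pi / 180  # acceptor 35 degrees off the D->H axis: D-H-A = 145
  bent["A", ] <- bent["H", ] + 1.9 * c(cos(ang), sin(ang), 0)
  tr_bent <- make_traj(list(bent))
  expect_equal(hbond_occupancy(tr_bent, cbind(1, 2), 3)$occupancy, 0)
  expect_equal(hbond_occupancy(tr_bent, cbind(1, 2), 3,
                               hbond_criterion(3.5, 40))$occupancy, 1)
  expect_error(hbond_occupancy(tr, cbind(1, 2)[0, , drop = FALSE], 3), "non-empty")
  expect_error(hbond_criterion(-1), "positive")
  expect_error(hbond_criterion(3.5, 95), "\\(0, 90\\)")
})

test_that("occupancy is monotone in both cutoffs", {
  rec <- duplex_recipe()
  tr <- build_trajectory(rec, n_frames = 40, thermal_sd = 0.35, seed = 17)
  hb <- duplex_hbonds(tr, 8)
  don <- as.matrix(hb[hb$pair == 3, c("donor", "hydrogen")])[1, , drop = FALSE]
  acc <- hb$acceptor[hb$pair == 3][1]
  occ_d <- vapply(c(2.5, 3.0, 3.5, 4.0, 5.0), function(cut)
    hbond_occupancy(tr, don, acc, hbond_criterion(cut, 30))$occupancy, numeric(1))
  expect_true(all(diff(occ_d) >= 0))
  occ_a <- vapply(c(5, 15, 30, 50, 80), function(dev)
    hbond_occupancy(tr, don, acc, hbond_criterion(3.5, dev))$occupancy, numeric(1))
  expect_true(all(diff(occ_a) >= 0))
})

test_that("torsion series follows the IUPAC convention and its symmetries", {
  cis <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))
  trans <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0))
  tr <- make_traj(list(cis, trans))
  expect_equal(torsion_series(tr, 1:4), c(0, 180), tolerance = 1e-10)
  set.seed(105)
  for (rep in 1:20) {
    p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    tr1 <- make_traj(list(p))
    got <- torsion_series(tr1, 1:4)
    expect_equal(got, oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    # a signed torsion is invariant under reversing the atom order
    rev <- torsion_series(tr1, 4:1)
    expect_equal(rev, got, tolerance = 1e-9)
    expect_true(got > -180 && got <= 180)
  }
  expect_error(torsion_series(tr, c(1, 1, 2, 3)), "distinct")
})

test_that("torsion histograms are proper probability distributions", {
  h1 <- torsion_histogram(rep(42.3, 50), bin_width = 10)
  expect_equal(sum(h1$probability), 1)
  expect_equal(h1$probability[h1$lower == 40], 1)
  set.seed(106)
  x <- stats::runif(1e5, -180, 180)
  h <- torsion_histogram(x, bin_width = 10)
  expect_equal(nrow(h), 36)
  expect_equal(sum(h$probability), 1, tolerance = 1e-12)
  p0 <- 1 / 36
  se <- sqrt(p0 * (1 - p0) / 1e5)
  expect_true(all(abs(h$probability - p0) < 3 * se + 1e-4))
  expect_error(torsion_histogram(x, bin_width = 7), "divide")
})
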