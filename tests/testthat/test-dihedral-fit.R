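test_that("torsion energy matches the closed form and brute-force sums", {
  expect_equal(dihedral_energy(0, dihedral_series(dihedral_term(1, 1, 0))), 2)
  expect_equal(dihedral_energy(60, dihedral_series(dihedral_term(2.40, 3, 0))), 0)
  set.seed(11)
  for (rep in 1:5) {
    s <- random_planted_series()
    phi <- stats::runif(100, -360, 720)
    brute <- rowSums(vapply(s$terms, function(t)
      t$k * (1 + cos((t$n * phi - t$delta) * pi / 180)), numeric(length(phi))))
    expect_equal(dihedral_energy(phi, s), brute, tolerance = 1e-12)
    # 360-degree periodicity and non-negativity
    expect_equal(dihedral_energy(phi + 360, s), dihedral_energy(phi, s),
                 tolerance = 1e-9)
    expect_true(all(dihedral_energy(phi, s) >= -1e-12))
  }
})

test_that("term and series constructors enforce their invariants", {
  expect_error(dihedral_term(-1, 3, 0), ">= 0")
  expect_error(dihedral_term(1, 0, 0), "positive integer")
  expect_error(dihedral_term(1, 7, 0), "1..6")
  expect_error(dihedral_term(1, 3, 360), "\\[-180, 360\\)")
  expect_error(dihedral_series(dihedral_term(1, 3, 0), dihedral_term(2, 3, 0)),
               "duplicate")
})

test_that("profile_from_series covers the grid and is min-anchored", {
  p <- profile_from_series(dihedral_series(dihedral_term(1.2, 2, 0)), scan_spec())
  expect_length(p$angles, 24)  # 15-degree grid over a full turn, endpoint deduplicated
  expect_equal(min(p$energies), 0)
  z <- profile_from_series(dihedral_series(), scan_spec())
  expect_true(all(z$energies == 0))
  set.seed(21)
  for (rep in 1:5) {
    p <- profile_from_series(random_planted_series(), scan_spec())
    expect_equal(min(p$energies), 0)
  }
})

test_that("scan periodicity check flags a conformer change at 360", {
  ang <- seq(0, 360, by = 15)
  ok <- energy_profile(ang, cos(ang * pi / 180), normalize = FALSE)
  v <- check_scan_periodicity(ok, tol = 0.1)
  expect_true(v$periodic)
  expect_equal(v$gap, 0)
  drift <- energy_profile(ang, c(rep(0, 24), -1.3), normalize = FALSE)
  v2 <- check_scan_periodicity(drift, tol = 0.1)
  expect_false(v2$periodic)
  expect_equal(v2$gap, 1.3)
  expect_true(v2$rescan_backward)
  # any pure torsion series is analytically periodic
  set.seed(31)
  for (rep in 1:5) {
    s <- random_planted_series()
    prof <- energy_profile(ang, dihedral_energy(ang, s))
    expect_true(check_scan_periodicity(prof, tol = 1e-9)$periodic)
  }
  no_end <- profile_from_series(dihedral_series(dihedral_term(1, 1, 0)), scan_spec())
  expect_error(check_scan_periodicity(no_end), "endpoints")
})

test_that("pairwise error is symmetric, offset-invariant, and matches enumeration", {
  grid <- seq(0, 345, by = 15)
  a <- energy_profile(grid, dihedral_energy(grid, dihedral_series(dihedral_term(1, 3, 0))))
  expect_equal(pairwise_error(a, a), 0)
  shifted <- energy_profile(a$angles, a$energies + 0.7, normalize = FALSE)
  expect_equal(pairwise_error(shifted, a), 0, tolerance = 1e-12)
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    ang <- sort(stats::runif(n, 0, 359))
    m <- energy_profile(ang, stats::runif(n, 0, 3), normalize = FALSE)
    t <- energy_profile(ang, stats::runif(n, 0, 3), normalize = FALSE)
    expect_equal(pairwise_error(m, t), oracle_pairwise(m$energies, t$energies),
                 tolerance = 1e-12)
    expect_equal(pairwise_error(m, t), pairwise_error(t, m))
    expect_gte(pairwise_error(m, t), 0)
  }
  b <- energy_profile(seq(0, 90, 15), rep(0, 7), normalize = FALSE)
  expect_error(pairwise_error(a, b), "grid")
})

test_that("fit recovers planted parameters exactly without noise", {
  set.seed(51)
  for (rep in 1:10) {
    truth <- random_planted_series()
    sc <- synth_scan(truth)
    fit <- fit_series(sc$target, sc$baseline)
    expect_lt(fit$final_error, 1e-8)
    expect_lt(kchi_rel_error(fit$series, truth), 1e-6)
  }
  # target == baseline -> no terms, zero error
  sc0 <- synth_scan(dihedral_series())
  fit0 <- fit_series(sc0$target, sc0$baseline)
  expect_length(fit0$series$terms, 0)
  expect_equal(fit0$final_error, 0, tolerance = 1e-12)
})

test_that("fit converges under realistic noise with bounded parameter error", {
  set.seed(61)
  sigma <- 0.05
  for (rep in 1:5) {
    truth <- dihedral_series(dihedral_term(stats::runif(1, 0.5, 2.5), 3, 0))
    sc <- synth_scan(truth, noise_sd = sigma)
    fit <- fit_series(sc$target, sc$baseline, tol = 0.2)
    expect_true(fit$converged)
    # noise sd 0.05 on 24 points: a 3-sigma-scale bound on the amplitude
    expect_lt(kchi_rel_error(fit$series, truth),
              3 * sigma / truth$terms[[1]]$k + 0.05)
  }
})

test_that("refinement mode reproduces the iterative amplitude-tuning route", {
  truth <- dihedral_series(dihedral_term(2.40, 3, 0))
  sc <- synth_scan(truth)
  init <- dihedral_series(dihedral_term(1.80, 3, 0))
  fit <- fit_series(sc$target, sc$baseline, method = "refine", init = init)
  expect_equal(fit$series$terms[[1]]$k, 2.40, tolerance = 1e-6)
  expect_lt(fit$final_error, 1e-8)
  expect_gt(fit$initial_error, fit$final_error)
  expect_error(fit_series(sc$target, sc$baseline, method = "refine"), "init")
  expect_error(fit_series(sc$target, sc$baseline, method = "refine",
                          init = dihedral_series(dihedral_term(1, 4, 0))),
               "allowed basis")
})

test_that("enlarging the allowed basis never worsens the fit", {
  set.seed(71)
  for (rep in 1:5) {
    sc <- synth_scan(dihedral_series(dihedral_term(1.5, 3, 0)), noise_sd = 0.3)
    e_small <- fit_series(sc$target, sc$baseline, allowed_n = c(1, 3))$final_error
    e_big <- fit_series(sc$target, sc$baseline, allowed_n = c(1, 2, 3))$final_error
    expect_lte(e_big, e_small + 1e-8)
  }
})

test_that("median planted-recovery error stays within contract bounds", {
  set.seed(81)
  rel0 <- replicate(50, {
    truth <- random_planted_series()
    fit <- fit_series(synth_scan(truth)$target, synth_scan(truth)$baseline)
    kchi_rel_error(fit$series, truth)
  })
  expect_lt(stats::median(rel0), 0.01)
  set.seed(82)
  rel1 <- replicate(50, {
    truth <- dihedral_series(dihedral_term(stats::runif(1, 0.8, 2.5), 3, 0))
    sc <- synth_scan(truth, noise_sd = 0.05)
    kchi_rel_error(fit_series(sc$target, sc$baseline)$series, truth)
  })
  expect_lt(stats::median(rel1), 0.10)
})

test_that("underdetermined grids are rejected, not silently fitted", {
  ang <- c(0, 40, 80, 120)
  t <- energy_profile(ang, c(0, 1, 2, 1), normalize = FALSE)
  b <- energy_profile(ang, rep(0, 4), normalize = FALSE)
  expect_error(fit_series(t, b, allowed_n = 1:6), "underdetermined")
  expect_error(fit_series(t, b, allowed_n = integer(0)), "non-empty")
})

test_that("fit report renders deterministically and parses back", {
  truth <- dihedral_series(dihedral_term(2.40, 3, 0))
  sc <- synth_scan(truth)
  fit <- fit_series(sc$target, sc$baseline)
  txt <- fit_report_table(fit)
  expect_match(txt, sprintf("initial pairwise error: %.2f", fit$initial_error))
  expect_match(txt, sprintf("final pairwise error:   %.2f", fit$final_error))
  back <- parse_fit_report(txt)
  expect_equal(back$initial_error, round(fit$initial_error, 2))
  expect_equal(back$final_error, round(fit$final_error, 2))
  expect_equal(back$iterations, fit$iterations)
  expect_equal(back$converged, fit$converged)
  expect_equal(back$terms$k, 2.4, tolerance = 1e-4)
  expect_equal(back$terms$n, 3L)
  # empty-series sentinel
  sc0 <- synth_scan(dihedral_series())
  txt0 <- fit_report_table(fit_series(sc0$target, sc0$baseline))
  expect_match(txt0, "no terms")
  expect_equal(nrow(parse_fit_report(txt0)$terms), 0)
})
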