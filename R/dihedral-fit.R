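#' Offset-invariant pairwise error between two energy profiles
#'
#' Relative energetics are only defined up to an additive constant, so the
#' discrepancy between a model profile and a target profile is measured on
#' point-pair differences: for every unordered pair of grid points
#' \eqn{i < j}, the mismatch is
#' \eqn{(m_i - m_j) - (t_i - t_j)}, and the pairwise error is the RMS of
#' these mismatches over all pairs. The statistic is symmetric in its
#' arguments and invariant to adding a constant to either profile. The
#' simpler RMSD-after-mean-alignment variant is available via
#' `method = "rmsd"` for comparison.
#'
#' @param model,target [energy_profile()]s on identical angle grids.
#' @param method `"pairwise"` (default) or `"rmsd"` (RMS deviation after
#'   aligning the profile means).
#' @return Error in kcal/mol.
#' @details For profiles of length n the pairwise RMS equals
#'   \eqn{\sqrt{2n/(n-1)}} times the population standard deviation of the
#'   per-point residual, so minimizing it is equivalent to least squares
#'   with a free intercept.
#' @export
pairwise_error <- function(model, target, method = c("pairwise", "rmsd")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "energy_profile"), inherits(target, "energy_profile"))
  if (length(model$angles) != length(target$angles) ||
      any(abs(model$angles - target$angles) > 1e-9))
    stop_("model and target profiles must share an identical angle grid")
  d <- model$energies - target$energies
  n <- length(d)
  if (method == "rmsd") return(sqrt(mean((d - mean(d))^2)))
  # sum over i<j of (d_i - d_j)^2 = n*sum(dc^2) - sum(dc)^2 for any common
  # shift of d; centering first avoids catastrophic cancellation when the
  # two profiles differ by a large constant
  dc <- d - mean(d)
  ss <- n * sum(dc^2) - sum(dc)^2
  sqrt(max(0, ss) / (n * (n - 1) / 2))
}

# design matrix of cos(n*phi - delta) columns over allowed (n, delta)
torsion_basis <- function(phi, allowed_n, allowed_delta) {
  combos <- expand.grid(n = allowed_n, delta = allowed_delta,
                        KEEP.OUT.ATTRS = FALSE)
  B <- matrix(0, length(phi), nrow(combos))
  for (j in seq_len(nrow(combos)))
    B[, j] <- cos(deg2rad(combos$n[j] * phi - combos$delta[j]))
  list(B = B, combos = combos)
}

#' Fit a torsion Fourier series to a target energy profile
#'
#' Finds non-negative force constants \eqn{k_\chi} over an allowed set of
#' multiplicities and phase offsets so that `baseline + series` best
#' matches `target` under the offset-invariant [pairwise_error()]. The
#' baseline is the molecular-mechanics profile with the fitted torsion's
#' contribution absent (or frozen); it is an input, never computed here.
#'
#' Two modes share one solver, cyclic coordinate descent with a
#' non-negativity clamp on each \eqn{k_\chi} over mean-centered basis
#' columns: `method = "ls"` starts from zero (on a uniform full-period
#' grid the cosine columns are near-orthogonal, so this is the linear
#' least-squares solve), while `method = "refine"` starts from a supplied
#' series and plays the role of iterative amplitude tuning of an existing
#' parameter guess.
#'
#' @param target,baseline [energy_profile()]s on identical grids.
#' @param allowed_n Allowed multiplicities (default `c(1, 2, 3, 6)`, the
#'   common CHARMM set).
#' @param allowed_delta Allowed phase offsets in degrees (default
#'   `c(0, 180)`; with both present a negative amplitude on one column is
#'   absorbed by the other, keeping \eqn{k_\chi \ge 0}).
#' @param tol Convergence tolerance on the final pairwise error, kcal/mol
#'   (default 0.2). Reported, never used to stop the solver early.
#' @param method `"ls"` or `"refine"`.
#' @param init Starting [dihedral_series()] for `method = "refine"`; every
#'   `(n, delta)` of `init` must be in the allowed sets.
#' @param max_iter Cap on coordinate-descent sweeps (default 10000);
#'   non-convergence of the solver is reported via the `iterations` field
#'   equalling the cap, never silently accepted.
#' @param drop_tol Fitted terms with \eqn{k_\chi} below this are dropped
#'   from the returned series (default 1e-10).
#' @return A list of class `fit_report`: `series` (the fitted
#'   [dihedral_series()]), `initial_error`, `final_error` (kcal/mol),
#'   `iterations` (coordinate-descent sweeps), `converged`
#'   (`final_error <= tol`), `tol`, `method`.
#' @export
#' @examples
#' grid <- scan_spec()
#' truth <- dihedral_series(dihedral_term(1.7, 3, 0))
#' base <- profile_from_series(dihedral_series(dihedral_term(0.8, 1, 0)), grid)
#' targ <- energy_profile(base$angles,
#'                        base$energies + dihedral_energy(base$angles, truth))
#' fit <- fit_series(targ, base)
#' fit$series
fit_series <- function(target, baseline,
                       allowed_n = c(1, 2, 3, 6), allowed_delta = c(0, 180),
                       tol = 0.2, method = c("ls", "refine"), init = NULL,
                       max_iter = 10000L, drop_tol = 1e-10) {
  method <- match.arg(method)
  stopifnot(inherits(target, "energy_profile"), inherits(baseline, "energy_profile"))
  if (length(target$angles) != length(baseline$angles) ||
      any(abs(target$angles - baseline$angles) > 1e-9))
    stop_("target and baseline must share an identical angle grid")
  if (length(allowed_n) == 0L) stop_("allowed_n must be non-empty")
  if (any(allowed_n != round(allowed_n)) || any(allowed_n < 1))
    stop_("allowed_n must be positive integers")
  phi <- target$angles
  bas <- torsion_basis(phi, as.integer(allowed_n), as.numeric(allowed_delta))
  # distinct basis directions up to sign: (n, delta mod 180)
  n_eff <- nrow(unique(cbind(bas$combos$n, bas$combos$delta %% 180)))
  if (length(phi) < n_eff + 1L)
    stop_("scan grid has fewer points than basis functions: underdetermined fit")

  d <- target$energies - baseline$energies
  ctr <- function(x) x - mean(x)
  Bc <- apply(bas$B, 2L, ctr)
  dc <- ctr(d)
  nrm2 <- colSums(Bc^2)

  k <- numeric(ncol(Bc))
  if (method == "refine") {
    if (is.null(init)) stop_("method = \"refine\" needs an init series")
    stopifnot(inherits(init, "dihedral_series"))
    for (t in init$terms) {
      j <- which(bas$combos$n == t$n & abs(bas$combos$delta - t$delta) < 1e-9)
      if (length(j) != 1L)
        stop_(sprintf("init term (n = %d, delta = %g) is not in the allowed basis", t$n, t$delta))
      k[j] <- t$k
    }
  }

  initial_error <- pairwise_error(baseline, target)
  r <- dc - as.numeric(Bc %*% k)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta_max <- 0
    for (j in seq_along(k)) {
      if (nrm2[j] < 1e-12) next
      kj_new <- max(0, k[j] + sum(Bc[, j] * r) / nrm2[j])
      step <- kj_new - k[j]
      if (step != 0) {
        r <- r - step * Bc[, j]
        k[j] <- kj_new
        delta_max <- max(delta_max, abs(step))
      }
    }
    if (delta_max < 1e-13 || iter >= max_iter) break
  }

  keep <- which(k > drop_tol)
  terms <- lapply(keep, function(j)
    dihedral_term(k[j], bas$combos$n[j], bas$combos$delta[j]))
  series <- dihedral_series(terms)
  model <- energy_profile(phi, baseline$energies + dihedral_energy(phi, series),
                          normalize = FALSE)
  final_error <- pairwise_error(model, target)
  structure(list(series = series, initial_error = initial_error,
                 final_error = final_error, iterations = iter,
                 converged = final_error <= tol, tol = tol, method = method),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(fit_report_table(x))
  invisible(x)
}

#' Render a fit report as text
#'
#' Deterministic fixed-format rendering of a [fit_series()] report:
#' initial and final pairwise error (2 decimals), iteration count,
#' convergence verdict, and one line per fitted term. The rendering can
#' be parsed back with [parse_fit_report()].
#'
#' @param report A `fit_report` from [fit_series()].
#' @return A single string (with embedded newlines).
#' @export
fit_report_table <- function(report) {
  stopifnot(inherits(report, "fit_report"))
  lines <- c(
    "torsion fit report",
    sprintf("initial pairwise error: %.2f kcal/mol", report$initial_error),
    sprintf("final pairwise error:   %.2f kcal/mol", report$final_error),
    sprintf("iterations: %d", report$iterations),
    sprintf("converged: %s (tol %.2f kcal/mol)",
            if (report$converged) "yes" else "no", report$tol))
  if (length(report$series$terms) == 0L) {
    lines <- c(lines, "terms: no terms")
  } else {
    lines <- c(lines, "terms:", "  k_chi        n    delta")
    for (t in report$series$terms)
      lines <- c(lines, sprintf("  %-10.4f %3d %8.2f", t$k, t$n, t$delta))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a rendered fit report
#'
#' Inverse of [fit_report_table()] at the printed precision.
#'
#' @param text String produced by [fit_report_table()].
#' @return A list with `initial_error`, `final_error`, `iterations`,
#'   `converged` and `terms` (data frame with columns `k`, `n`, `delta`;
#'   zero rows for the "no terms" sentinel).
#' @export
parse_fit_report <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  num <- function(pat) as.numeric(sub(pat, "\\1", grep(pat, lines, value = TRUE)[1L]))
  out <- list(
    initial_error = num("^initial pairwise error: ([-0-9.]+) kcal/mol$"),
    final_error   = num("^final pairwise error:   ([-0-9.]+) kcal/mol$"),
    iterations    = as.integer(num("^iterations: ([0-9]+)$")),
    converged     = grepl("^converged: yes", grep("^converged:", lines, value = TRUE)[1L]))
  if (any(lines == "terms: no terms")) {
    out$terms <- data.frame(k = numeric(0), n = integer(0), delta = numeric(0))
  } else {
    body <- lines[seq(which(lines == "terms:") + 2L, length(lines))]
    body <- body[nzchar(trimws(body))]
    fields <- do.call(rbind, lapply(strsplit(trimws(body), "[ ]+"), as.numeric))
    out$terms <- data.frame(k = fields[, 1L], n = as.integer(fields[, 2L]),
                            delta = fields[, 3L])
  }
  out
}
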