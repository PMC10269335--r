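# Shared independent oracles and small generators for the suite.

cross3_h <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# brute-force pairwise error: explicit loop over all unordered pairs
oracle_pairwise <- function(m, t) {
  d <- m - t
  n <- length(d)
  acc <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    acc <- acc + (d[i] - d[j])^2
    np <- np + 1
  }
  sqrt(acc / np)
}

rot_euler <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# derivative-free rotational search for the optimal-superposition RMSD:
# coarse Euler-angle grid then Nelder-Mead refinement (proper rotations
# only); independent of the SVD route
oracle_superpose_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    R <- rot_euler(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P0 %*% R - Q0)^2)))
  }
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in seq(0, 2 * pi, length.out = 9))
    for (b in seq(0, pi, length.out = 5))
      for (g in seq(0, 2 * pi, length.out = 9)) {
        v <- obj(c(a, b, g))
        if (v < best) { best <- v; best_ang <- c(a, b, g) }
      }
  o <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 20000))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 20000))
  o$value
}

# SVD-free plane search: angular grid over unit normals + local
# refinement, minimizing the out-of-plane variance of centered points
oracle_plane_normal <- function(pts) {
  P0 <- sweep(pts, 2, colMeans(pts))
  obj <- function(ang) {
    n <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    sum((P0 %*% n)^2)
  }
  best <- Inf; best_ang <- c(0, 0)
  for (th in seq(0, pi, length.out = 91))
    for (ph in seq(0, 2 * pi, length.out = 181)) {
      v <- obj(c(th, ph))
      if (v < best) { best <- v; best_ang <- c(th, ph) }
    }
  o <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 10000))
  ang <- o$par
  c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
}

# projection-based signed dihedral (independent construction; same IUPAC
# convention as the implementation, hence the cross(v, u) ordering)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  u <- (p1 - p2) - sum((p1 - p2) * b2) / sum(b2^2) * b2
  v <- (p4 - p3) - sum((p4 - p3) * b2) / sum(b2^2) * b2
  ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  s <- sign(sum(cross3_h(v, u) * b2))
  if (s == 0) s <- 1
  s * ang
}

# naive double-loop coordinate covariance (1/n)
oracle_covariance <- function(X) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  C <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    C[i, j] <- sum((X[, i] - mu[i]) * (X[, j] - mu[j])) / n
  C
}

# exhaustive 2-partition k-means objective for tiny point sets
oracle_best_wcss_k2 <- function(pts) {
  n <- nrow(pts)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    wcss <- 0
    for (grp in list(which(g), which(!g))) {
      mu <- colMeans(pts[grp, , drop = FALSE])
      wcss <- wcss + sum(sweep(pts[grp, , drop = FALSE], 2, mu)^2)
    }
    if (wcss < best) best <- wcss
  }
  best
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rigid_transform_traj <- function(traj, R, t) {
  for (i in seq_len(dim(traj$coords)[1])) {
    fr <- traj$coords[i, , ]
    traj$coords[i, , ] <- fr %*% R + matrix(t, nrow(fr), 3, byrow = TRUE)
  }
  traj
}

random_planted_series <- function() {
  ns <- sample(c(1, 2, 3, 6), sample(1:3, 1))
  dihedral_series(lapply(ns, function(n)
    dihedral_term(stats::runif(1, 0.3, 3), n, sample(c(0, 180), 1))))
}

# largest relative force-constant error between a fitted and a planted
# series, matching terms on (n, delta)
kchi_rel_error <- function(fitted, truth) {
  key <- function(t) paste(t$n, t$delta)
  fk <- vapply(fitted$terms, function(t) t$k, numeric(1))
  names(fk) <- vapply(fitted$terms, key, character(1))
  errs <- vapply(truth$terms, function(t) {
    k_hat <- if (key(t) %in% names(fk)) fk[[key(t)]] else 0
    abs(k_hat - t$k) / t$k
  }, numeric(1))
  max(errs)
}
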