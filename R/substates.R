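# Conformational-substate pipeline: 3N Cartesian covariance of selected
# atoms -> PCA -> low-dimensional projections -> k-means clustering ->
# centroid representative frames.

flatten_frames <- function(traj, sel, align, ref_index = 1L) {
  nf <- n_frames(traj)
  X <- matrix(0, nf, 3L * length(sel))
  ref <- get_frame(traj, ref_index)
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    if (align) fr <- apply_rigid(fr, superpose(fr, ref, sel))
    X[i, ] <- as.numeric(t(fr[sel, , drop = FALSE]))  # x1,y1,z1,x2,...
  }
  X
}

#' Cartesian coordinate covariance of a trajectory
#'
#' The essential-dynamics covariance matrix over the 3N Cartesian
#' coordinates of the selected atoms:
#' \eqn{c_{ij} = \langle (x_i - \langle x_i \rangle)(x_j - \langle x_j
#' \rangle) \rangle} with the average over frames. By default every
#' frame is first rigid-body superposed onto the first frame over the
#' same selection, so that rigid-body motion does not masquerade as
#' internal variance.
#'
#' @param traj A [trajectory_ensemble()] with at least 2 frames.
#' @param selection Integer atom indices; default all atoms.
#' @param align Superpose frames onto the first frame before averaging
#'   (default `TRUE`).
#' @param normalization `"n"` (default, population averaging over frames)
#'   or `"n-1"` (sample covariance).
#' @return An object of class `coord_covariance`: `matrix` (3N x 3N,
#'   Angstrom^2), `mean` (length-3N mean coordinate vector), `X` (frames
#'   x 3N aligned coordinate matrix, kept for projection), `selection`.
#' @export
coord_covariance <- function(traj, selection = NULL, align = TRUE,
                             normalization = c("n", "n-1")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (n_frames(traj) < 2L) stop_("covariance needs at least 2 frames")
  sel <- selection %||% seq_len(nrow(traj$atoms))
  if (length(sel) == 0L) stop_("empty selection")
  X <- flatten_frames(traj, sel, align)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  denom <- if (normalization == "n") nrow(X) else nrow(X) - 1L
  C <- crossprod(Xc) / denom
  structure(list(matrix = C, mean = mu, X = X, selection = sel,
                 normalization = normalization), class = "coord_covariance")
}

#' @export
print.coord_covariance <- function(x, ...) {
  cat(sprintf("Coordinate covariance: %d x %d (trace %.4f A^2, 1/%s)\n",
              nrow(x$matrix), ncol(x$matrix), sum(diag(x$matrix)),
              x$normalization))
  invisible(x)
}

#' PCA of a coordinate covariance
#'
#' Eigendecomposition of the covariance, eigenvalues descending.
#' Explained-variance fractions are \eqn{\lambda_m / \sum \lambda};
#' eigenvector signs are fixed by making each vector's
#' largest-magnitude component positive, so degenerate spectra still
#' decompose reproducibly.
#'
#' @param cov A [coord_covariance()].
#' @return An object of class `substate_model`: `eigenvalues`
#'   (Angstrom^2), `eigenvectors` (columns, orthonormal), `fractions`,
#'   `scree` (data frame: component, eigenvalue, fraction, cumulative),
#'   plus the covariance's `mean`, `X` and `selection` carried along for
#'   projection.
#' @export
pca_substates <- function(cov) {
  stopifnot(inherits(cov, "coord_covariance"))
  e <- eigen(cov$matrix, symmetric = TRUE)
  vals <- e$values
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  total <- sum(vals)
  fr <- if (total > 0) vals / total else rep(0, length(vals))
  scree <- data.frame(component = seq_along(vals), eigenvalue = vals,
                      fraction = fr, cumulative = cumsum(fr))
  structure(list(eigenvalues = vals, eigenvectors = vecs, fractions = fr,
                 scree = scree, mean = cov$mean, X = cov$X,
                 selection = cov$selection), class = "substate_model")
}

#' @export
print.substate_model <- function(x, ...) {
  cat(sprintf("Substate model: %d modes, top fractions %s\n",
              length(x$eigenvalues),
              paste(sprintf("%.3f", utils::head(x$fractions, 3)), collapse = ", ")))
  invisible(x)
}

#' Project trajectory frames onto principal components
#'
#' Centers the stored (aligned) frame coordinates on the model mean and
#' dots them onto the chosen eigenvectors. Projecting onto all
#' components and reconstructing recovers the centered coordinates to
#' numerical precision.
#'
#' @param model A [pca_substates()] model.
#' @param dims Integer vector of component indices (default `1:2`).
#' @return `frames x length(dims)` matrix of projections (Angstrom).
#' @export
project_frames <- function(model, dims = 1:2) {
  stopifnot(inherits(model, "substate_model"))
  if (any(dims < 1L) || any(dims > ncol(model$eigenvectors)))
    stop_("requested components outside the kept range")
  Xc <- sweep(model$X, 2L, model$mean)
  Xc %*% model$eigenvectors[, dims, drop = FALSE]
}

#' Choose how many principal components to keep
#'
#' `"threshold"` keeps the smallest m whose cumulative explained-variance
#' fraction reaches `param`; `"elbow"` returns the maximum-curvature
#' index of the scree curve (largest discrete second difference over the
#' nonzero eigenvalues). Both are deterministic.
#'
#' @param eigenvalues Numeric vector, descending.
#' @param method `"threshold"` or `"elbow"`.
#' @param param Cumulative-fraction target for `"threshold"` (default
#'   0.9).
#' @return Integer count of components to keep.
#' @export
choose_dims <- function(eigenvalues, method = c("threshold", "elbow"), param = 0.9) {
  method <- match.arg(method)
  if (length(eigenvalues) == 0L) stop_("empty spectrum")
  lam <- pmax(eigenvalues, 0)
  nz <- which(lam > 1e-12 * max(lam, 1e-300))
  if (length(nz) <= 1L) return(max(1L, length(nz)))
  if (method == "threshold") {
    cum <- cumsum(lam) / sum(lam)
    return(which(cum >= param - 1e-12)[1L])
  }
  lam_nz <- lam[nz]
  if (length(lam_nz) == 2L) return(1L)
  curv <- lam_nz[1:(length(lam_nz) - 2L)] - 2 * lam_nz[2:(length(lam_nz) - 1L)] +
    lam_nz[3:length(lam_nz)]
  which.max(curv) + 1L
}

#' Cluster projected frames into conformational substates
#'
#' Lloyd-style k-means on the projected coordinates with multiple random
#' restarts, keeping the solution with the lowest within-cluster sum of
#' squares. Deterministic under a fixed seed.
#'
#' @param projections `frames x dims` matrix from [project_frames()].
#' @param k Number of substates, `1 <= k <=` number of frames.
#' @param seed Integer RNG seed (default 2023).
#' @param restarts Number of random restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart (default 100).
#' @return List with `labels` (integer in 1..k per frame), `centers`
#'   (k x dims matrix), `wcss` (total within-cluster sum of squares).
#' @export
cluster_substates <- function(projections, k, seed = 2023L, restarts = 10L,
                              iter_max = 100L) {
  projections <- as.matrix(projections)
  n <- nrow(projections)
  if (k < 1L) stop_("k must be >= 1")
  if (k > n) stop_("k exceeds the number of frames")
  if (k == 1L) {
    mu <- matrix(colMeans(projections), 1L)
    return(list(labels = rep(1L, n), centers = mu,
                wcss = sum(sweep(projections, 2L, mu)^2)))
  }
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(projections, centers = k, iter.max = iter_max,
                  nstart = restarts, algorithm = "Lloyd"))
  list(labels = as.integer(km$cluster), centers = unname(km$centers),
       wcss = km$tot.withinss)
}

#' Representative frame of each substate
#'
#' Per cluster, the member frame whose projection is nearest (Euclidean)
#' to the cluster centroid; ties go to the lowest frame index.
#'
#' @param projections `frames x dims` matrix.
#' @param labels Integer cluster labels per frame (1..k).
#' @param centers `k x dims` matrix of cluster centroids.
#' @return Integer vector of frame indices, one per cluster.
#' @export
centroid_frames <- function(projections, labels, centers) {
  projections <- as.matrix(projections); centers <- as.matrix(centers)
  if (nrow(projections) != length(labels)) stop_("labels do not match projections")
  vapply(seq_len(nrow(centers)), function(c) {
    members <- which(labels == c)
    if (length(members) == 0L) stop_(sprintf("cluster %d has no members", c))
    d2 <- colSums((t(projections[members, , drop = FALSE]) - centers[c, ])^2)
    members[which.min(d2)]  # which.min takes the first (lowest index) on ties
  }, integer(1))
}

#' Silhouette-score scan over candidate substate counts
#'
#' Mean silhouette width for k = 2..k_max (k = 1 has no silhouette and is
#' reported as NA), as guidance for choosing the substate count; the
#' choice itself stays with the user.
#'
#' @param projections `frames x dims` matrix.
#' @param k_max Largest k to try (default 10).
#' @param seed RNG seed passed to [cluster_substates()].
#' @return Data frame with columns `k` and `mean_silhouette`.
#' @export
silhouette_scan <- function(projections, k_max = 10L, seed = 2023L) {
  projections <- as.matrix(projections)
  n <- nrow(projections)
  D <- as.matrix(stats::dist(projections))
  out <- data.frame(k = seq_len(min(k_max, n - 1L)), mean_silhouette = NA_real_)
  for (k in out$k) {
    if (k < 2L) next
    cl <- cluster_substates(projections, k, seed = seed)$labels
    s <- vapply(seq_len(n), function(i) {
      same <- which(cl == cl[i]); same <- setdiff(same, i)
      if (length(same) == 0L) return(0)
      a <- mean(D[i, same])
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(c2) mean(D[i, cl == c2]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    out$mean_silhouette[out$k == k] <- mean(s)
  }
  out
}
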