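#' Rigid-body superposition of an ensemble
#'
#' Least-squares (Kabsch) alignment of every frame onto a reference:
#' optimal translation plus proper rotation (reflections are rejected via
#' the determinant correction). The reference is either a fixed frame, an
#' external coordinate set, or the ensemble mean, in which case alignment
#' and mean are iterated until the mean moves by less than `tol` Angstrom.
#'
#' @param traj an `EnsembleTrajectory`.
#' @param reference `"mean"` (default), `"frame"`, or `"external"`.
#' @param ref_frame frame index when `reference = "frame"`.
#' @param ref_coords N x 3 matrix when `reference = "external"`.
#' @param selection optional labels used to compute the fit (all points are
#'   moved).
#' @param max_iter,tol iteration control for the mean reference.
#' @return list with `trajectory` (the superposed `EnsembleTrajectory`),
#'   `rmsd` (per-frame, Angstrom, against the final reference),
#'   `reference` coordinates and `iterations` used.
#' @export
superpose_ensemble <- function(traj, reference = c("mean", "frame", "external"),
                               ref_frame = 1L, ref_coords = NULL,
                               selection = NULL, max_iter = 20L, tol = 1e-6) {
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  reference <- match.arg(reference)
  labels <- traj$labels
  sel <- if (is.null(selection)) seq_along(labels) else {
    idx <- match(selection, labels)
    if (anyNA(idx)) stop_("selection label(s) not in trajectory: %s",
                          paste(selection[is.na(idx)], collapse = ", "))
    idx
  }
  f <- n_frames(traj)
  check_degenerate <- function(m, what) {
    s <- svd(scale(m, center = TRUE, scale = FALSE))$d
    if (length(s) < 2L || s[2] < 1e-9 * max(s[1], 1))
      stop_("%s is collinear/degenerate; cannot define a rotation", what)
  }
  align_all <- function(coords, ref) {
    out <- coords
    rmsd <- numeric(f)
    for (k in seq_len(f)) {
      fr <- coords[k, , , drop = TRUE]
      fit <- kabsch(fr[sel, , drop = FALSE], ref[sel, , drop = FALSE])
      moved <- sweep(fr, 2, fit$p_center) %*% fit$rotation
      moved <- sweep(moved, 2, fit$q_center, `+`)
      out[k, , ] <- moved
      rmsd[k] <- sqrt(mean(rowSums((moved[sel, , drop = FALSE] -
                                      ref[sel, , drop = FALSE])^2)))
    }
    list(coords = out, rmsd = rmsd)
  }

  coords <- traj$coords
  check_degenerate(coords[1, , , drop = TRUE][sel, , drop = FALSE], "frame 1")
  iterations <- 1L
  if (reference == "frame") {
    ref <- coords[ref_frame, , , drop = TRUE]
    res <- align_all(coords, ref)
  } else if (reference == "external") {
    if (is.null(ref_coords)) stop_("ref_coords required for an external reference")
    ref <- as.matrix(ref_coords)
    if (nrow(ref) != length(labels)) stop_("ref_coords must have one row per point")
    res <- align_all(coords, ref)
  } else {
    ref <- coords[1, , , drop = TRUE]
    res <- align_all(coords, ref)
    for (it in seq_len(max_iter)) {
      iterations <- it
      new_ref <- apply(res$coords, c(2, 3), mean)
      shift <- sqrt(max(rowSums((new_ref - ref)^2)))
      ref <- new_ref
      res <- align_all(res$coords, ref)
      if (shift < tol) break
    }
  }
  out <- traj
  out$coords <- res$coords
  dimnames(out$coords) <- list(NULL, labels, c("x", "y", "z"))
  out$superposed <- TRUE
  list(trajectory = out, rmsd = res$rmsd, reference = ref,
       iterations = iterations)
}

# optimal proper rotation aligning P onto Q (both N x 3, same N)
kabsch <- function(p, q) {
  pc <- colMeans(p); qc <- colMeans(q)
  h <- crossprod(sweep(p, 2, pc), sweep(q, 2, qc))
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, p_center = pc, q_center = qc)
}

#' Construct a correlation matrix object
#'
#' @param values symmetric N x N matrix with unit diagonal, entries in
#'   `[-1, 1]`.
#' @param labels residue labels.
#' @param n_frames number of frames the matrix was estimated from.
#' @return object of class `CorrelationMatrix`.
#' @export
correlation_matrix <- function(values, labels = rownames(values), n_frames = NA_integer_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_("correlation matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop_("correlation matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-8) stop_("diagonal must be 1")
  if (any(values < -1 - 1e-8 | values > 1 + 1e-8)) stop_("entries must lie in [-1, 1]")
  values <- (values + t(values)) / 2
  values[values > 1] <- 1; values[values < -1] <- -1
  diag(values) <- 1
  labels <- labels %||% paste0("n", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels,
                 n_frames = as.integer(n_frames)),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf("CorrelationMatrix: %d x %d (from %s frames)\n",
              nrow(x$values), ncol(x$values),
              ifelse(is.na(x$n_frames), "?", x$n_frames)))
  invisible(x)
}

#' Dynamic cross-correlation matrix of an ensemble
#'
#' Computes `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, the
#' normalized covariance of the Cartesian displacement vectors from the
#' ensemble-mean position. Rigid-body motion contaminates these
#' correlations, so by default the ensemble is superposed to its mean
#' first; pass `superpose = FALSE` only for ensembles already expressed in
#' a common frame (e.g. direct draws from a covariance model).
#'
#' @param traj an `EnsembleTrajectory`.
#' @param selection optional subset of labels.
#' @param superpose superpose to the ensemble mean first (default `TRUE`;
#'   skipped when the trajectory is already marked superposed).
#' @return a `CorrelationMatrix`.
#' @export
compute_dccm <- function(traj, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  if (n_frames(traj) < 2L) stop_("need at least 2 frames")
  if (superpose && !isTRUE(traj$superposed)) {
    traj <- superpose_ensemble(traj, reference = "mean")$trajectory
  }
  labels <- traj$labels
  sel <- if (is.null(selection)) seq_along(labels) else {
    idx <- match(selection, labels)
    if (anyNA(idx)) stop_("selection label(s) missing: %s",
                          paste(selection[is.na(idx)], collapse = ", "))
    idx
  }
  f <- n_frames(traj)
  num <- 0
  msq <- 0
  for (ax in 1:3) {
    d <- traj$coords[, sel, ax, drop = TRUE]
    d <- sweep(matrix(d, nrow = f), 2, colMeans(matrix(d, nrow = f)))
    num <- num + crossprod(d) / f
  }
  msq <- diag(num)
  zero <- msq < 1e-12
  if (any(zero)) stop_("zero-variance point(s): %s",
                       paste(labels[sel][zero], collapse = ", "))
  c_mat <- num / sqrt(tcrossprod(msq))
  correlation_matrix(c_mat, labels = labels[sel], n_frames = f)
}

#' Spearman comparison of two correlation matrices
#'
#' Rank-correlates the entries of two same-shaped correlation matrices over
#' a chosen region (default: strict upper triangle, diagonal excluded) and
#' runs the two-sided Spearman rank-order test.
#'
#' @param a,b `CorrelationMatrix` objects with identical labels.
#' @param region `"upper"` (strict upper triangle), `"upper_diag"`, or
#'   `"all"`.
#' @return a `DccmComparison`: list with `rho`, `n`, `region`, `p_value`.
#' @export
compare_dccm_spearman <- function(a, b, region = c("upper", "upper_diag", "all")) {
  region <- match.arg(region)
  stopifnot(inherits(a, "CorrelationMatrix"), inherits(b, "CorrelationMatrix"))
  if (!identical(dim(a$values), dim(b$values)) || !identical(a$labels, b$labels))
    stop_("matrices must share shape and labels")
  keep <- switch(region,
                 upper = upper.tri(a$values, diag = FALSE),
                 upper_diag = upper.tri(a$values, diag = TRUE),
                 all = matrix(TRUE, nrow(a$values), ncol(a$values)))
  x <- a$values[keep]; y <- b$values[keep]
  rho <- cor(x, y, method = "spearman")
  p <- suppressWarnings(cor.test(x, y, method = "spearman",
                                 alternative = "two.sided", exact = FALSE))$p.value
  structure(list(rho = rho, n = length(x), region = region, p_value = p),
            class = "DccmComparison")
}

#' @export
print.DccmComparison <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f over %d entries (%s region), two-sided p = %.3g\n",
              x$rho, x$n, x$region, x$p_value))
  invisible(x)
}

#' Cartesian principal component analysis of an ensemble
#'
#' Eigen-decomposition of the coordinate covariance over frames (each frame
#' flattened to a 3N vector). Eigenvalues are non-increasing and
#' non-negative; eigenvectors are orthonormal.
#'
#' @param traj a superposed `EnsembleTrajectory`.
#' @param selection optional subset of labels.
#' @return list with `values` (variances, length 3N), `vectors`
#'   (3N x 3N, columns are modes, coordinates interleaved per point),
#'   `labels`.
#' @export
principal_components <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  if (n_frames(traj) < 2L) stop_("need at least 2 frames")
  labels <- traj$labels
  sel <- if (is.null(selection)) seq_along(labels) else match(selection, labels)
  if (anyNA(sel)) stop_("selection label(s) missing")
  f <- n_frames(traj)
  n <- length(sel)
  # frames x 3n, interleaved (x1, y1, z1, x2, ...)
  mat <- matrix(0, f, 3 * n)
  for (ax in 1:3) mat[, seq(ax, 3 * n, by = 3)] <- matrix(traj$coords[, sel, ax], nrow = f)
  cv <- stats::cov(mat)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  list(values = vals, vectors = e$vectors, labels = labels[sel])
}

#' Construct a distance series
#'
#' @param distances non-negative per-frame distances (Angstrom).
#' @param point_a,point_b labels of the two tracked points.
#' @return object of class `DistanceSeries`.
#' @export
distance_series <- function(distances, point_a, point_b) {
  distances <- as.numeric(distances)
  if (any(distances < 0)) stop_("distances must be >= 0")
  structure(list(distances = distances, point_a = point_a, point_b = point_b,
                 seed = NULL),
            class = "DistanceSeries")
}

#' Per-frame distance between two labelled points
#'
#' Euclidean distance in each frame; no superposition is applied because
#' internal distances are invariant under rigid-body motion.
#'
#' @param traj an `EnsembleTrajectory`.
#' @param point_a,point_b labels present in the trajectory.
#' @return a `DistanceSeries`.
#' @export
extract_distance_series <- function(traj, point_a, point_b) {
  stopifnot(inherits(traj, "EnsembleTrajectory"))
  ia <- match(point_a, traj$labels); ib <- match(point_b, traj$labels)
  if (is.na(ia)) stop_("label not in trajectory: %s", point_a)
  if (is.na(ib)) stop_("label not in trajectory: %s", point_b)
  d <- sqrt(rowSums((matrix(traj$coords[, ia, ], ncol = 3) -
                       matrix(traj$coords[, ib, ], ncol = 3))^2))
  distance_series(d, point_a, point_b)
}

#' Kernel-density distance distribution with mode detection
#'
#' Gaussian KDE of a distance series over `[0, max + 3 bw]` (Silverman's
#' rule by default) with modes reported as the local density maxima above
#' 10 percent of the global maximum, sorted ascending. Components closer
#' than the bandwidth merge into a single detected mode.
#'
#' @param series a `DistanceSeries` (or bare numeric vector).
#' @param bandwidth `"auto"` (Silverman) or a numeric bandwidth in
#'   Angstrom.
#' @param min_density_frac mode-acceptance floor relative to the global
#'   density maximum.
#' @param n_grid KDE evaluation grid size.
#' @return a `DistanceDistribution`: list with `x`, `density`, `bandwidth`,
#'   `modes`, `mode_densities`, `n`.
#' @export
distance_distribution <- function(series, bandwidth = "auto",
                                  min_density_frac = 0.1, n_grid = 2048L) {
  x <- if (inherits(series, "DistanceSeries")) series$distances else as.numeric(series)
  if (length(x) == 0L) stop_("series is empty")
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(x) else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-3, stats::sd(x), na.rm = TRUE) * 0.1
  den <- density(x, bw = bw, from = 0, to = max(x) + 3 * bw, n = n_grid)
  y <- den$y
  floor_y <- min_density_frac * max(y)
  k <- length(y)
  is_max <- c(y[1] > y[2], y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
              y[k] > y[k - 1]) & y >= floor_y
  modes <- den$x[is_max]
  structure(list(x = den$x, density = y, bandwidth = bw,
                 modes = sort(modes), mode_densities = y[is_max][order(modes)],
                 n = length(x)),
            class = "DistanceDistribution")
}

#' @export
print.DistanceDistribution <- function(x, ...) {
  cat(sprintf("DistanceDistribution: n = %d, bw = %.3f A, modes at %s A\n",
              x$n, x$bandwidth, paste(sprintf("%.2f", x$modes), collapse = ", ")))
  invisible(x)
}
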