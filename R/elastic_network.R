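#' Build a toy elastic network from point coordinates
#'
#' Places harmonic springs between every pair of nodes closer than `cutoff`
#' and returns the resulting elastic network. The network stands in for a
#' coarse-grained (one site per residue) protein model: its inverse
#' connectivity (Kirchhoff) or Hessian matrix supplies the fluctuation
#' covariance that downstream ensemble statistics assume.
#'
#' @param coords numeric N x 3 matrix of positions in Angstrom. Row names,
#'   if present, become node labels; chain-qualified labels such as
#'   `"A:12"` are used to tag subunits in dimer models.
#' @param cutoff contact distance in Angstrom; springs connect pairs at or
#'   below it.
#' @param stiffness spring force constant (arbitrary energy/A^2 units)
#'   applied uniformly.
#' @param labels optional character vector of node labels (defaults to row
#'   names or `"n1"..."nN"`).
#' @return an object of class `ToyElasticNetwork`: list with `coords`,
#'   `labels`, `springs` (data.frame `i`, `j`, `k` with `i < j` by node
#'   index) and `cutoff`.
#' @examples
#' net <- build_toy_network(cbind(c(0, 3, 6), 0, 0), cutoff = 4)
#' nrow(net$springs) # 2: only consecutive points are within 4 A
#' @export
build_toy_network <- function(coords, cutoff, stiffness = 1, labels = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop_("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 3L) stop_("need at least 3 nodes, got %d", n)
  if (!is.numeric(cutoff) || cutoff <= 0) stop_("cutoff must be > 0")
  if (!is.numeric(stiffness) || stiffness <= 0) stop_("stiffness must be > 0")
  labels <- labels %||% rownames(coords) %||% paste0("n", seq_len(n))
  if (anyDuplicated(labels)) stop_("node labels must be unique")
  rownames(coords) <- labels

  d <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  springs <- data.frame(i = idx[, 1], j = idx[, 2], k = stiffness)

  net <- structure(list(coords = coords, labels = labels,
                        springs = springs, cutoff = cutoff),
                   class = "ToyElasticNetwork")
  comp <- network_components(net)
  if (max(comp) > 1L) {
    main <- which.max(tabulate(comp))
    iso <- labels[comp != main]
    stop_("elastic network is disconnected; node(s) not reachable from the main component: %s",
          paste(iso, collapse = ", "))
  }
  net
}

# connected-component labels (1-based) from the spring list
network_components <- function(net) {
  n <- nrow(net$coords)
  comp <- integer(n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(net$springs))) {
    i <- net$springs$i[r]; j <- net$springs$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) if (comp[v] == 0L) { comp[v] <- cur; queue <- c(queue, v) }
    }
  }
  comp
}

#' @export
print.ToyElasticNetwork <- function(x, ...) {
  cat(sprintf("ToyElasticNetwork: %d nodes, %d springs, cutoff %.2f A\n",
              nrow(x$coords), nrow(x$springs), x$cutoff))
  invisible(x)
}

# Kirchhoff (connectivity) matrix: K_ij = -k_ij, rows sum to zero
kirchhoff_matrix <- function(net) {
  n <- nrow(net$coords)
  K <- matrix(0, n, n, dimnames = list(net$labels, net$labels))
  for (r in seq_len(nrow(net$springs))) {
    i <- net$springs$i[r]; j <- net$springs$j[r]; k <- net$springs$k[r]
    K[i, j] <- K[i, j] - k
    K[j, i] <- K[j, i] - k
    K[i, i] <- K[i, i] + k
    K[j, j] <- K[j, j] + k
  }
  K
}

# anisotropic-network Hessian, 3N x 3N, coordinates interleaved per node
hessian_matrix <- function(net) {
  n <- nrow(net$coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(net$springs))) {
    i <- net$springs$i[r]; j <- net$springs$j[r]; k <- net$springs$k[r]
    dv <- net$coords[i, ] - net$coords[j, ]
    d2 <- sum(dv^2)
    if (d2 < 1e-12) stop_("coincident nodes %s and %s", net$labels[i], net$labels[j])
    blk <- k * tcrossprod(dv) / d2
    ii <- (3 * (i - 1) + 1):(3 * i)
    jj <- (3 * (j - 1) + 1):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  H
}

#' Fluctuation covariance of an elastic network
#'
#' Pseudo-inverts the network's connectivity (scalar mode, one coordinate
#' per node, Gaussian-network style) or its 3N Hessian (`three_d` mode,
#' anisotropic-network style), dropping the expected zero modes: 1 for the
#' scalar connectivity, 6 rigid-body modes for the 3-D Hessian. Eigenvalues
#' below `tol` times the largest are treated as zero; finding more or fewer
#' than expected is an error (disconnected or degenerate geometry).
#'
#' @param net a `ToyElasticNetwork`.
#' @param mode `"scalar"` (N x N covariance) or `"three_d"` (3N x 3N).
#' @param scale kT-like multiplier applied to the pseudo-inverse.
#' @param tol relative eigenvalue tolerance for zero modes.
#' @return object of class `CovarianceModel`: `mean_coords`, `covariance`,
#'   `dropped_modes`, `mode`, `labels`, `scale`.
#' @export
network_covariance <- function(net, mode = c("scalar", "three_d"),
                               scale = 1, tol = 1e-8) {
  mode <- match.arg(mode)
  if (!is.numeric(scale) || scale <= 0) stop_("scale must be > 0")
  if (mode == "scalar") {
    m <- kirchhoff_matrix(net)
    n_zero <- 1L
  } else {
    m <- hessian_matrix(net)
    n_zero <- 6L
  }
  dec <- psdinv(m, n_zero, tol)
  cov <- scale * dec$pinv
  if (mode == "scalar") dimnames(cov) <- list(net$labels, net$labels)
  structure(list(mean_coords = net$coords,
                 covariance = cov,
                 dropped_modes = n_zero,
                 mode = mode,
                 labels = net$labels,
                 scale = scale),
            class = "CovarianceModel")
}

#' Stiffen or soften springs around selected nodes
#'
#' Multiplies the stiffness of every spring touching `nodes` by `factor`.
#' With `factor > 1` this emulates a bound regulator rigidifying part of
#' the structure (e.g. the subunit interface of a dimer): the variance of
#' the perturbed nodes in the derived covariance strictly decreases.
#'
#' @param net a `ToyElasticNetwork`.
#' @param nodes node labels or indices (non-empty).
#' @param factor positive multiplier; 1 leaves the network unchanged.
#' @return the modified `ToyElasticNetwork`.
#' @export
perturb_network <- function(net, nodes, factor) {
  if (length(nodes) == 0L) stop_("nodes must be non-empty")
  if (!is.numeric(factor) || factor <= 0) stop_("factor must be > 0")
  idx <- if (is.character(nodes)) match(nodes, net$labels) else as.integer(nodes)
  if (anyNA(idx) || any(idx < 1L | idx > length(net$labels))) {
    bad <- if (is.character(nodes)) nodes[is.na(match(nodes, net$labels))] else nodes
    stop_("unknown node id(s): %s", paste(bad, collapse = ", "))
  }
  hit <- net$springs$i %in% idx | net$springs$j %in% idx
  net$springs$k[hit] <- net$springs$k[hit] * factor
  net
}

#' Sample a Gaussian conformational ensemble from a covariance model
#'
#' Draws `n_frames` independent snapshots from the zero-mean Gaussian with
#' the model covariance and adds them to the mean coordinates. In scalar
#' mode the same N x N covariance drives three independent Cartesian axes
#' (isotropic Gaussian-network convention), so the analytic displacement
#' correlation of the ensemble equals the normalized model covariance. In
#' `three_d` mode the full 3N covariance is sampled.
#'
#' @param cov a `CovarianceModel`.
#' @param n_frames number of snapshots (>= 2).
#' @param seed integer seed; sampling is reproducible under a fixed seed.
#' @return an `EnsembleTrajectory`: list with `coords` (array
#'   `n_frames` x N x 3), `labels`, `seed`.
#' @export
sample_ensemble <- function(cov, n_frames, seed) {
  stopifnot(inherits(cov, "CovarianceModel"))
  if (n_frames < 2L) stop_("need n_frames >= 2 for any ensemble statistics")
  e <- eigen((cov$covariance + t(cov$covariance)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values))
  if (any(e$values < -tol)) stop_("covariance is not positive semi-definite")
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values))
  n <- length(cov$labels)
  coords <- with_seed(seed, {
    if (cov$mode == "scalar") {
      # one draw per axis; dim n_frames x n x 3
      z <- array(rnorm(3L * n_frames * n), dim = c(n, n_frames, 3L))
      fl <- array(0, dim = c(n_frames, n, 3L))
      for (ax in 1:3) fl[, , ax] <- t(L %*% z[, , ax])
      fl
    } else {
      z <- matrix(rnorm(n_frames * 3L * n), nrow = 3L * n)
      x <- t(L %*% z)                       # n_frames x 3n, interleaved
      array(x[, rep(3L * seq_len(n), times = 3L) - rep(2:0, each = n)],
            dim = c(n_frames, n, 3L))
    }
  })
  for (ax in 1:3) coords[, , ax] <- coords[, , ax] +
      matrix(cov$mean_coords[, ax], n_frames, n, byrow = TRUE)
  ensemble_trajectory(coords, cov$labels, seed = seed)
}

#' Construct an ensemble trajectory object
#'
#' @param coords array of dim `F x N x 3` (frames, points, xyz), Angstrom.
#' @param labels character vector of N point labels.
#' @param seed generating seed, or `NULL` for externally loaded ensembles.
#' @return object of class `EnsembleTrajectory`.
#' @export
ensemble_trajectory <- function(coords, labels, seed = NULL) {
  coords <- unname(coords)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop_("coords must be an F x N x 3 array")
  if (dim(coords)[2] != length(labels))
    stop_("labels length (%d) does not match point count (%d)",
          length(labels), dim(coords)[2])
  if (!all(is.finite(coords))) stop_("coordinates must be finite")
  dimnames(coords) <- list(NULL, labels, c("x", "y", "z"))
  structure(list(coords = coords, labels = labels, seed = seed,
                 superposed = FALSE),
            class = "EnsembleTrajectory")
}

#' @export
print.EnsembleTrajectory <- function(x, ...) {
  cat(sprintf("EnsembleTrajectory: %d frames x %d points%s%s\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (isTRUE(x$superposed)) ", superposed" else "",
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
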