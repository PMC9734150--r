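rigid_copy_ensemble <- function(n = 8, seed = 21) {
  set.seed(seed)
  base <- matrix(runif(n * 3, 0, 10), ncol = 3)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  coords <- array(0, dim = c(2, n, 3))
  coords[1, , ] <- base
  coords[2, , ] <- base %*% rot + matrix(c(5, -2, 3), n, 3, byrow = TRUE)
  ensemble_trajectory(coords, paste0("r", seq_len(n)))
}

test_that("superposition removes rigid-body motion exactly", {
  tr <- rigid_copy_ensemble()
  sup <- superpose_ensemble(tr, reference = "frame", ref_frame = 1)
  expect_lt(sup$rmsd[2], 1e-9)
  expect_true(isTRUE(sup$trajectory$superposed))

  # pure translation
  tr2 <- tr
  tr2$coords[2, , ] <- tr$coords[1, , ] + matrix(c(1, 2, 3), 8, 3, byrow = TRUE)
  sup2 <- superpose_ensemble(tr2, reference = "frame", ref_frame = 1)
  expect_equal(unname(sup2$trajectory$coords[2, , ]),
               unname(sup2$trajectory$coords[1, , ]), tolerance = 1e-9)

  # collinear frames cannot define a rotation
  bad <- array(rep(cbind(1:4, 0, 0), each = 2), dim = c(2, 4, 3))
  expect_error(superpose_ensemble(ensemble_trajectory(bad, paste0("c", 1:4))),
               "collinear")
})

test_that("iterative mean-reference superposition converges quickly on Gaussian ensembles", {
  cov <- network_covariance(make_helix(6), mode = "three_d")
  tr <- sample_ensemble(cov, 300, seed = 13)
  sup <- superpose_ensemble(tr, reference = "mean", tol = 1e-6)
  expect_lte(sup$iterations, 20)
  expect_true(all(sup$rmsd >= 0))
})

test_that("superposition agrees with an established reference implementation", {
  cov <- network_covariance(make_helix(5), mode = "three_d")
  tr <- sample_ensemble(cov, 20, seed = 31)
  ref <- tr$coords[1, , ]
  sup <- superpose_ensemble(tr, reference = "frame", ref_frame = 1)
  xyz <- matrix(0, 20, 15)
  for (ax in 1:3) xyz[, seq(ax, 15, by = 3)] <- tr$coords[, , ax]
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(ref)), mobile = xyz,
                           fixed.inds = 1:15, mobile.inds = 1:15)
  for (ax in 1:3)
    expect_equal(unname(sup$trajectory$coords[, , ax]),
                 fitted[, seq(ax, 15, by = 3)], tolerance = 1e-6)
})

test_that("DCCM hits the in-phase / anti-phase limits", {
  # two points sharing every displacement: C = +1
  set.seed(5)
  disp <- rnorm(40)
  coords <- array(0, dim = c(40, 2, 3))
  coords[, 1, 1] <- disp
  coords[, 2, 1] <- 10 + disp
  tr <- ensemble_trajectory(coords, c("p", "q"))
  dc <- compute_dccm(tr, superpose = FALSE)
  expect_equal(dc$values["p", "q"], 1)

  coords[, 2, 1] <- 10 - disp
  dc2 <- compute_dccm(ensemble_trajectory(coords, c("p", "q")), superpose = FALSE)
  expect_equal(dc2$values["p", "q"], -1)

  # zero-variance point is reported by name
  coords[, 2, ] <- 3
  expect_error(compute_dccm(ensemble_trajectory(coords, c("p", "q")),
                            superpose = FALSE), "q")
})

test_that("sampled DCCM converges to the analytic correlation of the model", {
  cov <- network_covariance(make_chain(6, cutoff = 4), mode = "scalar")
  tr <- sample_ensemble(cov, 5000, seed = 17)
  dc <- compute_dccm(tr, superpose = FALSE)
  ana <- cov$covariance / sqrt(tcrossprod(diag(cov$covariance)))
  expect_lt(max(abs(dc$values - ana)), 0.05)
})

test_that("DCCM is invariant to global rigid-body motion (with superposition) and frame order", {
  cov <- network_covariance(make_toy_dimer(), mode = "scalar")
  tr <- sample_ensemble(cov, 400, seed = 23)
  dc <- compute_dccm(tr, superpose = TRUE)

  # rotate + translate the whole ensemble
  th <- 1.1
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- tr
  for (k in seq_len(400))
    moved$coords[k, , ] <- tr$coords[k, , ] %*% rot + matrix(c(-4, 8, 1), 24, 3, byrow = TRUE)
  dc_moved <- compute_dccm(moved, superpose = TRUE)
  expect_equal(dc_moved$values, dc$values, tolerance = 1e-8)

  shuf <- tr
  set.seed(1); ord <- sample(400)
  shuf$coords <- tr$coords[ord, , , drop = FALSE]
  expect_equal(compute_dccm(shuf, superpose = FALSE)$values,
               compute_dccm(tr, superpose = FALSE)$values, tolerance = 1e-12)
})

test_that("Spearman matrix comparison matches hand-ranked values and is symmetric", {
  mk <- function(up) {
    m <- diag(4)
    m[upper.tri(m)] <- up
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    correlation_matrix(m, paste0("r", 1:4))
  }
  a <- mk(c(0.1, 0.4, 0.2, 0.9, 0.3, 0.5))
  b <- mk(c(0.2, 0.1, 0.5, 0.8, 0.9, 0.3))
  cmp <- compare_dccm_spearman(a, b)
  # hand-ranked oracle: ranks a = 1 4 2 6 3 5, b = 2 1 4 5 6 3,
  # rho = 1 - 6*28 / (6*35) = 0.2
  expect_equal(cmp$rho, 0.2)
  expect_equal(cmp$n, 6L)
  expect_equal(compare_dccm_spearman(b, a)$rho, cmp$rho)

  expect_equal(compare_dccm_spearman(a, a)$rho, 1)
  neg <- mk(rev(c(0.1, 0.4, 0.2, 0.9, 0.3, 0.5)) * -1)
  # a rank-reversing transform of the entries
  flip <- mk(1 - c(0.1, 0.4, 0.2, 0.9, 0.3, 0.5))
  expect_equal(compare_dccm_spearman(a, flip)$rho, -1)

  expect_equal(compare_dccm_spearman(a, b, region = "upper_diag")$n, 10L)
  expect_error(compare_dccm_spearman(a, correlation_matrix(diag(3), paste0("r", 1:3))),
               "shape")
})

test_that("Cartesian PCA has the spectral properties of a coordinate covariance", {
  # variation along a single direction: one nonzero eigenvalue
  coords <- array(0, dim = c(30, 4, 3))
  base <- matrix(runif(12), 4, 3)
  set.seed(3)
  amp <- rnorm(30)
  dir <- matrix(rnorm(12), 4, 3); dir <- dir / sqrt(sum(dir^2))
  for (k in 1:30) coords[k, , ] <- base + amp[k] * dir
  pc <- principal_components(ensemble_trajectory(coords, paste0("a", 1:4)))
  expect_equal(sum(pc$values > 1e-10 * pc$values[1]), 1L)

  # trace identity and orthonormality on a sampled ensemble
  cov <- network_covariance(make_chain(5, cutoff = 4), mode = "scalar")
  tr <- sample_ensemble(cov, 500, seed = 29)
  pc2 <- principal_components(tr)
  flat <- do.call(cbind, lapply(1:3, function(ax) tr$coords[, , ax]))
  expect_equal(sum(pc2$values), sum(apply(flat, 2, var)), tolerance = 1e-8)
  expect_equal(crossprod(pc2$vectors), diag(ncol(pc2$vectors)), tolerance = 1e-8)
  expect_true(all(diff(pc2$values) <= 1e-12))

  # leading PC aligns with the softest internal mode of the network
  K <- allonet:::kirchhoff_matrix(make_chain(5, cutoff = 4))
  ek <- eigen(K, symmetric = TRUE)
  soft <- ek$vectors[, which(ek$values > 1e-8)[sum(ek$values > 1e-8)]]
  # scalar sampling drives all three axes with the same mode structure;
  # project the leading PC's per-axis blocks onto the soft mode
  lead <- pc2$vectors[, 1]
  per_axis <- matrix(lead, nrow = 5, byrow = TRUE)  # 5 nodes x 3 axes
  best <- max(abs(cor(per_axis, soft)))
  expect_gt(best, 0.95)
})

test_that("distance series extraction is exact and superposition-free", {
  coords <- array(0, dim = c(3, 2, 3))
  coords[, 2, 1] <- 4.4
  tr <- ensemble_trajectory(coords, c("a", "b"))
  expect_equal(extract_distance_series(tr, "a", "b")$distances, rep(4.4, 3))
  coords[, 2, ] <- coords[, 1, ]
  expect_equal(extract_distance_series(ensemble_trajectory(coords, c("a", "b")),
                                       "a", "b")$distances, rep(0, 3))
  expect_error(extract_distance_series(tr, "a", "zz"), "zz")

  # round trip: a simulated series embedded on the x-axis is recovered
  s <- simulate_distance_series(c(4.4, 7.8), sigma = 0.3, n = 500, seed = 2)
  emb <- array(0, dim = c(500, 2, 3))
  emb[, 2, 1] <- s$distances
  tr2 <- ensemble_trajectory(emb, c("o", "p"))
  expect_equal(extract_distance_series(tr2, "o", "p")$distances, s$distances)
})

test_that("mode detection recovers well-separated mixture components", {
  s <- simulate_distance_series(c(4.4, 7.8), sigma = 0.3, n = 10000, seed = 6)
  dd <- distance_distribution(s)
  expect_length(dd$modes, 2L)
  expect_lt(abs(dd$modes[1] - 4.4), 0.1)
  expect_lt(abs(dd$modes[2] - 7.8), 0.1)

  uni <- distance_distribution(simulate_distance_series(5, weights = 1,
                                                        sigma = 0.4, n = 5000, seed = 8))
  expect_length(uni$modes, 1L)

  # components closer than the bandwidth merge into one mode
  merged <- distance_distribution(simulate_distance_series(c(5, 5.3), sigma = 0.4,
                                                           n = 5000, seed = 9))
  expect_length(merged$modes, 1L)
})

test_that("mode recovery holds across seeds for separation >= 4 sigma", {
  for (seed in 1:8) {
    s <- simulate_distance_series(c(4.4, 7.8), sigma = 0.3, n = 5000, seed = seed)
    m <- distance_distribution(s)$modes
    expect_length(m, 2L)
    expect_lt(abs(m[1] - 4.4), 0.1)
    expect_lt(abs(m[2] - 7.8), 0.1)
  }
})
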