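#' Perturbation-response matrix of a covariance model
#'
#' Linear-response magnitude of each residue to a unit force applied at
#' every other residue. Under linear response the displacement of residue
#' i caused by a force f at residue j is the covariance block `G_ij`
#' acting on f. Averaging the squared response isotropically over force
#' directions on the unit sphere has the closed form
#' `R_ij = sqrt(tr(G_ij' G_ij) / 3)` in 3-D mode; in scalar mode the block
#' is a single number and the definition collapses to `R_ij = |cov_ij|`.
#'
#' @param model a `CovarianceModel` (zero modes already removed).
#' @return N x N matrix of response magnitudes, labelled.
#' @seealso [perturbation_response_mc()] for the Monte-Carlo cross-check.
#' @export
perturbation_response_matrix <- function(model) {
  stopifnot(inherits(model, "CovarianceModel"))
  n <- length(model$labels)
  if (model$mode == "scalar") {
    r <- abs(model$covariance)
  } else {
    r <- matrix(0, n, n)
    for (i in seq_len(n)) {
      ii <- (3 * (i - 1) + 1):(3 * i)
      for (j in seq_len(n)) {
        jj <- (3 * (j - 1) + 1):(3 * j)
        g <- model$covariance[ii, jj]
        r[i, j] <- sqrt(sum(g * g) / 3)
      }
    }
  }
  dimnames(r) <- list(model$labels, model$labels)
  r
}

#' Monte-Carlo perturbation response (test oracle)
#'
#' Estimates the isotropically averaged root-mean-square response by
#' drawing random unit forces, as a cross-check for the analytic
#' direction-averaging of [perturbation_response_matrix()]. Retained as a
#' verification oracle; the analytic form is what the pipeline uses.
#'
#' @param model a 3-D `CovarianceModel`.
#' @param n_forces number of random unit-force draws.
#' @param seed integer seed.
#' @return N x N matrix of response magnitudes.
#' @export
perturbation_response_mc <- function(model, n_forces = 10000L, seed = 1L) {
  stopifnot(inherits(model, "CovarianceModel"), model$mode == "three_d")
  n <- length(model$labels)
  forces <- with_seed(seed, {
    f <- matrix(rnorm(3L * n_forces), ncol = 3L)
    f / sqrt(rowSums(f^2))
  })
  r2 <- matrix(0, n, n)
  for (j in seq_len(n)) {
    jj <- (3 * (j - 1) + 1):(3 * j)
    resp <- model$covariance[, jj] %*% t(forces)   # 3N x n_forces
    for (i in seq_len(n)) {
      ii <- (3 * (i - 1) + 1):(3 * i)
      r2[i, j] <- mean(colSums(resp[ii, , drop = FALSE]^2))
    }
  }
  r <- sqrt(r2)
  dimnames(r) <- list(model$labels, model$labels)
  r
}

#' Dynamical flexibility index profile
#'
#' Normalizes the perturbation-response matrix row-wise into per-residue
#' shares of the total response: `DFI_i = sum_j R_ij / sum_kj R_kj`.
#' Residues with large DFI absorb a disproportionate share of the
#' structure's response to random (Brownian-kick-like) perturbations; the
#' profile sums to 1 and is invariant to any uniform scaling of the
#' underlying covariance.
#'
#' @param response non-negative N x N response matrix (from
#'   [perturbation_response_matrix()]).
#' @param source provenance tag (`"covariance"` or `"elastic_network"`).
#' @return a `DFIProfile`: list with named `dfi` (sums to 1),
#'   `normalized = TRUE`, `source`.
#' @export
dfi_profile <- function(response, source = "covariance") {
  response <- as.matrix(response)
  if (any(response < 0)) stop_("response magnitudes must be non-negative")
  tot <- sum(response)
  if (tot <= 0) stop_("all-zero response matrix")
  dfi <- rowSums(response) / tot
  labels <- rownames(response) %||% paste0("n", seq_len(nrow(response)))
  structure(list(dfi = setNames(dfi, labels), normalized = TRUE,
                 source = source),
            class = "DFIProfile")
}

#' @export
print.DFIProfile <- function(x, ...) {
  cat(sprintf("DFIProfile: %d residues (sum %.6f), source %s\n",
              length(x$dfi), sum(x$dfi), x$source))
  invisible(x)
}
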