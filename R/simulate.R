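#' Simulate a bimodal (Gaussian-mixture) distance series
#'
#' Draws `n` distances from a Gaussian mixture, emulating the side-chain to
#' ligand distance of a residue that hops between a catalytic rotamer and a
#' non-catalytic one (modes near 4.4 and 7.8 Angstrom in the motivating
#' system). Negative draws are re-drawn, not truncated, so the mixture
#' shape near each mode is preserved; the fraction re-drawn is reported and
#' a warning is raised if it exceeds 1 percent.
#'
#' @param modes numeric vector of component means (Angstrom).
#' @param weights component probabilities, summing to 1 (default equal).
#' @param sigma common component standard deviation (> 0, Angstrom).
#' @param n number of draws.
#' @param seed integer seed.
#' @param point_a,point_b labels carried into the resulting series.
#' @return a `DistanceSeries` whose `distances` hold the draws; attribute
#'   `redraw_fraction` records the share of re-drawn values.
#' @export
simulate_distance_series <- function(modes, weights = NULL, sigma, n, seed,
                                     point_a = "sidechain", point_b = "ligand") {
  weights <- weights %||% rep(1 / length(modes), length(modes))
  if (length(weights) != length(modes)) stop_("weights and modes differ in length")
  if (abs(sum(weights) - 1) > 1e-8) stop_("weights must sum to 1")
  if (!is.numeric(sigma) || sigma <= 0) stop_("sigma must be > 0")
  redrawn <- 0L
  x <- with_seed(seed, {
    comp <- sample.int(length(modes), n, replace = TRUE, prob = weights)
    v <- rnorm(n, mean = modes[comp], sd = sigma)
    while (any(bad <- v < 0)) {
      redrawn <- redrawn + sum(bad)
      v[bad] <- rnorm(sum(bad), mean = modes[comp[bad]], sd = sigma)
    }
    v
  })
  frac <- redrawn / n
  if (frac > 0.01)
    warning(sprintf("%.1f%% of distance draws were negative and re-drawn", 100 * frac))
  out <- distance_series(x, point_a = point_a, point_b = point_b)
  attr(out, "redraw_fraction") <- frac
  out$seed <- seed
  out
}

#' Simulate kinetic or melting data from the model equations
#'
#' Evaluates one of the four measurement models on a grid and adds optional
#' Gaussian noise: `eq1` Michaelis-Menten saturation, `eq2` thermal
#' unfolding sigmoid, `eq3` tight-binding (quadratic) activation titration,
#' `eq5` Hill sigmoid. With `noise_sd = 0` the exact curve is returned, so
#' a subsequent fit must recover the generating parameters.
#'
#' @param model one of `"eq1"`, `"eq2"`, `"eq3"`, `"eq5"`.
#' @param params named list of parameters; required names are `eq1`:
#'   `k_cat`, `K_M`; `eq2`: `LL`, `UL`, `T_m`, `c`; `eq3`: `V_max`, `G`,
#'   `K_D`; `eq5`: `V_max`, `K_half`, `h` (optional `form`, see
#'   [hill_rate()]).
#' @param grid x values (substrate mM, regulator uM, or temperature C).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return a `RateMeasurementSet`: list with `x`, `v`, `model`, `params`,
#'   `fixed`, `noise_sd`, `seed`.
#' @export
simulate_rate_data <- function(model = c("eq1", "eq2", "eq3", "eq5"),
                               params, grid, noise_sd = 0, seed = NULL) {
  model <- match.arg(model)
  if (length(grid) == 0L) stop_("grid must be non-empty")
  need <- switch(model,
                 eq1 = c("k_cat", "K_M"),
                 eq2 = c("LL", "UL", "T_m", "c"),
                 eq3 = c("V_max", "G", "K_D"),
                 eq5 = c("V_max", "K_half", "h"))
  miss <- setdiff(need, names(params))
  if (length(miss)) stop_("missing parameter(s) for %s: %s", model,
                          paste(miss, collapse = ", "))
  v <- switch(model,
    eq1 = mm_rate(grid, params$k_cat, params$K_M),
    eq2 = melting_fraction(grid, params$LL, params$UL, params$T_m, params$c),
    eq3 = binding_rate(grid, params$G, params$V_max, params$K_D),
    eq5 = hill_rate(grid, params$V_max, params$K_half, params$h,
                    form = params$form %||% "standard"))
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  if (noise_sd > 0) v <- v + with_seed(seed, rnorm(length(grid), 0, noise_sd))
  fixed <- params[setdiff(names(params), c(need, "form"))]
  structure(list(x = as.numeric(grid), v = as.numeric(v), model = model,
                 params = params, fixed = fixed,
                 noise_sd = noise_sd, seed = seed),
            class = "RateMeasurementSet")
}

#' @export
print.RateMeasurementSet <- function(x, ...) {
  cat(sprintf("RateMeasurementSet (%s): %d points, noise sd %.3g\n",
              x$model, length(x$x), x$noise_sd))
  invisible(x)
}

#' Toy catalytic-dimer elastic network
#'
#' Deterministic two-subunit geometry used throughout the synthetic
#' studies: each subunit is a planar grid of residues (spacing 3.8 A, the
#' Calpha virtual-bond length), the two subunits face each other across a
#' 4.5 A interface gap so that only the facing columns form inter-subunit
#' springs. Labels are chain-qualified (`"A:1"`, `"B:7"`, ...). The
#' returned network carries the interface node labels in `$interface`; the
#' regulator-bound variant is obtained by stiffening the springs that
#' touch those nodes (see [perturb_network()]).
#'
#' In the default (nonactivated) network the inter-subunit springs are
#' soft (`cross_stiffness = 0.2` vs intra-subunit 1), modelling a loose
#' dimer interface; [stiffen_intersubunit()] restores them to intra
#' stiffness to emulate the regulator clamping the interface.
#'
#' @param nx,ny grid dimensions per subunit (default 4 x 3 = 12 residues).
#' @param spacing in-plane residue spacing (Angstrom).
#' @param gap inter-subunit gap between facing columns (Angstrom).
#' @param cutoff spring cutoff (Angstrom).
#' @param stiffness intra-subunit spring constant.
#' @param cross_stiffness inter-subunit spring constant of the
#'   nonactivated dimer.
#' @return a `ToyElasticNetwork` with an extra `interface` element.
#' @export
make_toy_dimer <- function(nx = 4, ny = 3, spacing = 3.8, gap = 4.5,
                           cutoff = 6, stiffness = 1, cross_stiffness = 0.2) {
  grid_xy <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
  a <- cbind(grid_xy$ix * spacing, grid_xy$iy * spacing, 0)
  b <- a
  b[, 1] <- (nx - 1 - grid_xy$ix) * spacing + (nx - 1) * spacing + gap
  coords <- rbind(a, b)
  labels <- c(paste0("A:", seq_len(nrow(a))), paste0("B:", seq_len(nrow(b))))
  rownames(coords) <- labels
  net <- build_toy_network(coords, cutoff = cutoff, stiffness = stiffness)
  sub <- node_subunit(labels)
  cross <- sub[net$springs$i] != sub[net$springs$j]
  net$springs$k[cross] <- cross_stiffness
  iface_a <- labels[seq_len(nrow(a))][grid_xy$ix == nx - 1]
  iface_b <- labels[nrow(a) + which(grid_xy$ix == nx - 1)]
  net$interface <- c(iface_a, iface_b)
  net
}

#' Regulator-bound variant of a dimer network
#'
#' Multiplies the stiffness of every inter-subunit spring (endpoints on
#' different chains) by `factor`, emulating a bound regulator rigidifying
#' the couplings across the dimer interface and thereby constraining the
#' conformational dynamics. With the defaults of [make_toy_dimer()] a
#' factor of 5 brings the interface springs to the intra-subunit
#' stiffness.
#'
#' @param net a chain-labelled `ToyElasticNetwork`.
#' @param factor positive stiffness multiplier (default 5).
#' @return the stiffened `ToyElasticNetwork`.
#' @export
stiffen_intersubunit <- function(net, factor = 5) {
  if (!is.numeric(factor) || factor <= 0) stop_("factor must be > 0")
  sub <- node_subunit(net$labels)
  cross <- sub[net$springs$i] != sub[net$springs$j]
  if (!any(cross)) stop_("network has no inter-subunit springs")
  net$springs$k[cross] <- net$springs$k[cross] * factor
  net
}

#' Chain-qualified subunit of a node label
#'
#' @param labels character labels such as `"A:12"`; anything before the
#'   first colon is the subunit tag, labels without a colon map to `NA`.
#' @return character vector of subunit tags.
#' @export
node_subunit <- function(labels) {
  has <- grepl(":", labels, fixed = TRUE)
  out <- rep(NA_character_, length(labels))
  out[has] <- sub(":.*$", "", labels[has])
  out
}
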