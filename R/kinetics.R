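#' Michaelis-Menten rate
#'
#' Steady-state saturation curve `v/E_T = k_cat S / (K_M + S)`.
#'
#' @param S substrate concentration (mM), vectorized.
#' @param k_cat turnover number (1/s).
#' @param K_M apparent Michaelis constant (mM).
#' @return v/E_T in 1/s.
#' @export
mm_rate <- function(S, k_cat, K_M) k_cat * S / (K_M + S)

#' Fraction unfolded in a thermal melt
#'
#' Boltzmann sigmoid `F_U = LL + (UL - LL) / (1 + exp((T_m - T)/c))` used
#' for differential-scanning-fluorimetry melting curves.
#'
#' @param T temperature (C), vectorized.
#' @param LL,UL folded and unfolded baselines (signal units).
#' @param T_m melting temperature (C).
#' @param c slope of the transition region (C).
#' @return signal on the `LL`..`UL` scale.
#' @export
melting_fraction <- function(T, LL, UL, T_m, c) {
  LL + (UL - LL) / (1 + exp((T_m - T) / c))
}

#' Tight-binding (quadratic) activation rate
#'
#' Initial rate of the catalytic subunit G titrated with regulator Z when
#' free-regulator depletion cannot be neglected (Z comparable to both G
#' and K_D):
#' `v = V_max (G + Z + K_D - sqrt((G + Z + K_D)^2 - 4 G Z)) / (2 G)`.
#' Small negative discriminants from rounding are clamped to zero; a
#' genuinely negative discriminant is an error.
#'
#' @param Z regulator concentration (uM), vectorized.
#' @param G catalytic-subunit concentration (uM, fixed).
#' @param V_max maximal velocity (rate units).
#' @param K_D_app apparent equilibrium dissociation constant (uM).
#' @return rates on the `V_max` scale; `v = 0` at `Z = 0`.
#' @export
binding_rate <- function(Z, G, V_max, K_D_app) {
  if (G <= 0) stop_("G must be > 0")
  s <- G + Z + K_D_app
  disc <- s^2 - 4 * G * Z
  bad <- disc < -1e-9 * pmax(s^2, 1)
  if (any(bad)) stop_("negative discriminant beyond tolerance: inconsistent inputs")
  V_max * (s - sqrt(pmax(disc, 0))) / (2 * G)
}

#' Concentration of the assembled complex
#'
#' Equilibrium concentration of the G:Z complex (the holoenzyme, ATPPRT)
#' at total concentrations G and Z:
#' `[complex] = (G + Z + K_D - sqrt((G + Z + K_D)^2 - 4 G Z)) / 2`,
#' bounded by `0 <= [complex] <= min(G, Z)` and symmetric in G and Z.
#'
#' @param G,Z total concentrations (uM), `Z` vectorized.
#' @param K_D_app apparent dissociation constant (uM).
#' @return complex concentration (uM).
#' @export
complex_concentration <- function(G, Z, K_D_app) {
  if (any(c(G, Z, K_D_app) < 0)) stop_("all inputs must be >= 0")
  s <- G + Z + K_D_app
  disc <- s^2 - 4 * G * Z
  bad <- disc < -1e-9 * pmax(s^2, 1)
  if (any(bad)) stop_("negative discriminant beyond tolerance: inconsistent inputs")
  (s - sqrt(pmax(disc, 0))) / 2
}

#' Hill (cooperative) activation rate
#'
#' Sigmoidal dependence of rate on regulator concentration. The
#' dimensionally consistent standard form is
#' `v = V_max Z^h / (K_half^h + Z^h)`; the `as_printed` variant
#' `v = V_max Z^h / (K_half + Z^h)` (half-saturation constant not raised
#' to h) is retained verbatim behind a flag for comparison with fits made
#' in that parameterization. Both reduce to the hyperbola at `h = 1`.
#'
#' @param Z regulator concentration (uM), vectorized.
#' @param V_max maximal velocity.
#' @param K_half inflection-point concentration K_0.5 (uM).
#' @param h Hill coefficient (> 0).
#' @param form `"standard"` or `"as_printed"`.
#' @return rates on the `V_max` scale.
#' @export
hill_rate <- function(Z, V_max, K_half, h, form = c("standard", "as_printed")) {
  form <- match.arg(form)
  if (h <= 0) stop_("h must be > 0")
  zh <- Z^h
  den <- if (form == "standard") K_half^h + zh else K_half + zh
  V_max * zh / den
}

nls_fit <- function(formula, data, start, lower, upper = NULL) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper, control = ctrl),
    error = function(e) stop_("fit did not converge: %s", conditionMessage(e)))
  cf <- summary(fit)$coefficients
  list(fit = fit,
       estimates = setNames(cf[, "Estimate"], rownames(cf)),
       se = setNames(cf[, "Std. Error"], rownames(cf)),
       rss = sum(stats::resid(fit)^2))
}

fit_data_frame <- function(data) {
  if (inherits(data, "RateMeasurementSet")) {
    data.frame(x = data$x, v = data$v)
  } else {
    d <- as.data.frame(data)
    names(d)[1:2] <- c("x", "v")
    d
  }
}

#' Fit the Michaelis-Menten saturation curve
#'
#' Unweighted nonlinear least squares with data-driven starting values
#' (`k_cat` from the rate plateau, `K_M` from the half-saturating
#' concentration) and asymptotic standard errors from the Jacobian.
#'
#' @param data a `RateMeasurementSet` (or data.frame with columns x = S in
#'   mM, v = rate in 1/s) with at least 4 distinct substrate levels.
#' @return a `MichaelisFit`: `k_cat`, `K_M`, `se`, `rss`, `fit`.
#' @export
fit_michaelis <- function(data) {
  d <- fit_data_frame(data)
  if (length(unique(d$x)) < 4L) stop_("need >= 4 distinct substrate concentrations")
  k0 <- max(d$v)
  km0 <- max(d$x[which.min(abs(d$v - k0 / 2))], min(d$x[d$x > 0]))
  res <- nls_fit(v ~ k_cat * x / (K_M + x), d,
                 start = list(k_cat = k0, K_M = km0),
                 lower = c(1e-12, 1e-12))
  if (any(res$estimates <= 0)) stop_("negative or zero parameter estimate")
  structure(list(k_cat = unname(res$estimates["k_cat"]),
                 K_M = unname(res$estimates["K_M"]),
                 se = res$se, rss = res$rss, fit = res$fit, data = d),
            class = "MichaelisFit")
}

#' Fit a thermal melting curve
#'
#' Fits the Boltzmann unfolding sigmoid to temperature/signal data and
#' checks that a genuine transition is present (signal range above noise,
#' baselines ordered `LL < UL`, `T_m` inside the scanned range).
#'
#' @param curve data.frame with columns T (C) and signal (or a
#'   `RateMeasurementSet` with `x` = T).
#' @return a `MeltingFit`: `T_m`, `c`, `LL`, `UL`, `se`, `rss`, `fit`.
#' @export
fit_melting <- function(curve) {
  d <- fit_data_frame(curve)
  if (diff(range(d$v)) <= 1e-12) stop_("flat signal: no unfolding transition to fit")
  mid <- (max(d$v) + min(d$v)) / 2
  tm0 <- d$x[which.min(abs(d$v - mid))]
  res <- nls_fit(v ~ LL + (UL - LL) / (1 + exp((T_m - x) / c)), d,
                 start = list(LL = min(d$v), UL = max(d$v), T_m = tm0, c = 2),
                 lower = c(-Inf, -Inf, min(d$x), 1e-6))
  est <- res$estimates
  if (est["UL"] <= est["LL"]) stop_("no valid transition: fitted UL <= LL")
  if (est["T_m"] < min(d$x) || est["T_m"] > max(d$x))
    stop_("fitted T_m outside the data range")
  structure(list(T_m = unname(est["T_m"]), c = unname(est["c"]),
                 LL = unname(est["LL"]), UL = unname(est["UL"]),
                 se = res$se, rss = res$rss, fit = res$fit, data = d),
            class = "MeltingFit")
}

#' Fit the tight-binding activation titration
#'
#' Fits `V_max` and the apparent K_D of the quadratic (free-ligand
#' depletion) activation curve with the catalytic-subunit concentration G
#' held fixed at its known assay value.
#'
#' @param data a `RateMeasurementSet` (x = Z in uM) with at least 5
#'   regulator levels; `G` is read from `data$fixed$G` unless given.
#' @param G fixed catalytic-subunit concentration (uM).
#' @return a `BindingFit`: `V_max`, `K_D_app`, `G`, `se`, `rss`, `fit`.
#' @export
fit_binding <- function(data, G = NULL) {
  d <- fit_data_frame(data)
  G <- G %||% (if (inherits(data, "RateMeasurementSet")) data$fixed$G else NULL) %||%
    (if (inherits(data, "RateMeasurementSet")) data$params$G else NULL)
  if (is.null(G) || G <= 0) stop_("fixed G (> 0) is required")
  if (length(unique(d$x)) < 5L) stop_("need >= 5 regulator concentrations")
  v0 <- max(d$v)
  kd0 <- max(d$x[which.min(abs(d$v - v0 / 2))], 1e-3)
  res <- nls_fit(v ~ V_max * (G + x + K_D - sqrt((G + x + K_D)^2 - 4 * G * x)) / (2 * G),
                 d, start = list(V_max = v0, K_D = kd0),
                 lower = c(1e-12, 1e-12))
  if (any(res$estimates <= 0)) stop_("negative or zero parameter estimate")
  structure(list(V_max = unname(res$estimates["V_max"]),
                 K_D_app = unname(res$estimates["K_D"]),
                 G = G, se = res$se, rss = res$rss, fit = res$fit, data = d),
            class = "BindingFit")
}

#' Fit the Hill activation curve
#'
#' Fits `V_max`, K_0.5 and the Hill coefficient h (bounded to (0, 10])
#' to a sigmoidal titration. When the titration cannot be run under
#' pseudo-first-order conditions the fit is descriptive only: it
#' characterizes the sigmoidicity without the parameters carrying their
#' usual equilibrium meaning.
#'
#' @param data a `RateMeasurementSet` (x = Z in uM) with at least 6 levels
#'   spanning the inflection.
#' @param form `"standard"` (K_0.5 raised to h) or `"as_printed"`.
#' @return a `HillFit`: `V_max`, `K_half`, `h`, `form`, `se`, `rss`,
#'   `fit`.
#' @export
fit_hill <- function(data, form = c("standard", "as_printed")) {
  form <- match.arg(form)
  d <- fit_data_frame(data)
  if (length(unique(d$x)) < 6L) stop_("need >= 6 regulator concentrations")
  v0 <- max(d$v)
  k0 <- max(d$x[which.min(abs(d$v - v0 / 2))], 1e-3)
  if (form == "standard") {
    res <- nls_fit(v ~ V_max * x^h / (K_half^h + x^h), d,
                   start = list(V_max = v0, K_half = k0, h = 1.5),
                   lower = c(1e-12, 1e-12, 1e-6), upper = c(Inf, Inf, 10))
  } else {
    res <- nls_fit(v ~ V_max * x^h / (K_half + x^h), d,
                   start = list(V_max = v0, K_half = k0, h = 1.5),
                   lower = c(1e-12, 1e-12, 1e-6), upper = c(Inf, Inf, 10))
  }
  structure(list(V_max = unname(res$estimates["V_max"]),
                 K_half = unname(res$estimates["K_half"]),
                 h = unname(res$estimates["h"]), form = form,
                 se = res$se, rss = res$rss, fit = res$fit, data = d),
            class = "HillFit")
}

#' Fold change between two rate constants
#'
#' Exact ratio of two rate constants plus the integer fold (rounded half
#' away from zero) used in activation/impairment tables. Units must
#' cancel.
#'
#' @param numerator,denominator positive rate constants.
#' @param num_unit,den_unit unit strings; a mismatch is an error.
#' @param num_label,den_label optional labels for reporting.
#' @return a `FoldChangeReport`: `fold` (exact), `fold_rounded` (integer),
#'   labels/units, `rounding` convention string.
#' @export
fold_change <- function(numerator, denominator,
                        num_unit = "s^-1", den_unit = "s^-1",
                        num_label = "", den_label = "") {
  if (!identical(num_unit, den_unit))
    stop_("unit mismatch: %s vs %s", num_unit, den_unit)
  if (denominator <= 0) stop_("denominator must be > 0")
  fold <- numerator / denominator
  structure(list(numerator = numerator, denominator = denominator,
                 num_label = num_label, den_label = den_label,
                 unit = num_unit, fold = fold,
                 fold_rounded = round_half_away(fold),
                 rounding = "half-away-from-zero to integer"),
            class = "FoldChangeReport")
}

#' @export
print.FoldChangeReport <- function(x, ...) {
  cat(sprintf("%s / %s = %.4g -> %d-fold\n",
              if (nzchar(x$num_label)) x$num_label else format(x$numerator),
              if (nzchar(x$den_label)) x$den_label else format(x$denominator),
              x$fold, as.integer(x$fold_rounded)))
  invisible(x)
}

#' @export
print.MichaelisFit <- function(x, ...) {
  cat(sprintf("MichaelisFit: k_cat = %.4g +/- %.2g s^-1, K_M = %.4g +/- %.2g mM\n",
              x$k_cat, x$se["k_cat"], x$K_M, x$se["K_M"]))
  invisible(x)
}

#' @export
print.MeltingFit <- function(x, ...) {
  cat(sprintf("MeltingFit: T_m = %.2f +/- %.2g C, c = %.3g C, baselines [%.3g, %.3g]\n",
              x$T_m, x$se["T_m"], x$c, x$LL, x$UL))
  invisible(x)
}

#' @export
print.BindingFit <- function(x, ...) {
  cat(sprintf("BindingFit: V_max = %.4g, K_D(app) = %.4g +/- %.2g uM (G = %.3g uM fixed)\n",
              x$V_max, x$K_D_app, x$se["K_D"], x$G))
  invisible(x)
}

#' @export
print.HillFit <- function(x, ...) {
  cat(sprintf("HillFit (%s form): V_max = %.4g, K_0.5 = %.4g +/- %.2g uM, h = %.3g +/- %.2g\n",
              x$form, x$V_max, x$K_half, x$se["K_half"], x$h, x$se["h"]))
  invisible(x)
}
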