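# Electrophysiology fitting: sum-of-two-Boltzmann open-probability curves,
# the gating polarity index, residue-propensity correlations and MTSET
# modification kinetics.

#' Evaluate the sum-of-two-Boltzmann model
#'
#' `I(V) = O1 + (A1 - O1)/(1 + exp(k1 (V - V1)))
#'       + O2 + (A2 - O2)/(1 + exp(k2 (V - V2)))`
#'
#' Each component interpolates between its amplitude `A` (the limb's
#' saturating level on one voltage side) and its offset `O` (the other
#' side), with half-point `V` (mV) and slope factor `k` (1/mV); the sign
#' of `k` sets which side saturates at `A`. The symmetric form above is
#' the default; `strict_printed = TRUE` reproduces a published variant in
#' which the first component's bracket reads `(A1 - O2)` (making `O1` a
#' pure additive constant).
#'
#' @param V Voltages, mV.
#' @param p Named numeric vector or list with `A1`, `O1`, `V1`, `k1`,
#'   `A2`, `O2`, `V2`, `k2`.
#' @param strict_printed Use the as-printed asymmetric variant.
#' @return Numeric vector of model values.
#' @export
double_boltzmann <- function(V, p, strict_printed = FALSE) {
  p <- as.list(p)
  a1 <- if (strict_printed) p$A1 - p$O2 else p$A1 - p$O1
  p$O1 + a1 / (1 + exp(p$k1 * (V - p$V1))) +
    p$O2 + (p$A2 - p$O2) / (1 + exp(p$k2 * (V - p$V2)))
}

# Canonical parameterisation. Each component carries an exact
# representation symmetry (A, O, k) <-> (O, A, -k) (the same sigmoid read
# from the other side), so components are first put into k > 0 form: A is
# then the level approached on hyperpolarisation, O on depolarisation.
# Components are then ordered by half-point, so component 1 is the limb
# with the more negative V-half.
.canonicalize_components <- function(p) {
  for (i in c("1", "2")) {
    kk <- paste0("k", i)
    if (p[[kk]] < 0) {
      tmp <- p[[paste0("A", i)]]
      p[[paste0("A", i)]] <- p[[paste0("O", i)]]
      p[[paste0("O", i)]] <- tmp
      p[[kk]] <- -p[[kk]]
    }
  }
  if (p[["V1"]] > p[["V2"]]) {
    p[c("A1", "O1", "V1", "k1", "A2", "O2", "V2", "k2")] <-
      p[c("A2", "O2", "V2", "k2", "A1", "O1", "V1", "k1")]
  }
  p
}

#' Canonical form of double-Boltzmann parameters
#'
#' Maps a parameter set to the unique equivalent representation with both
#' slope factors positive (swapping `A`/`O` and negating `k` leaves each
#' component's curve unchanged) and components ordered by half-point, so
#' that parameter sets describing the same curve become comparable.
#'
#' @param p Named vector/list with `A1 O1 V1 k1 A2 O2 V2 k2`.
#' @return Named numeric vector in canonical form.
#' @export
canonical_boltzmann <- function(p) {
  out <- unlist(.canonicalize_components(as.list(p)))
  out[c("A1", "O1", "V1", "k1", "A2", "O2", "V2", "k2")]
}

#' Fit a sum of two Boltzmann components to a Po-V curve
#'
#' Nonlinear least squares with multi-start: initial half-points are drawn
#' from a grid spanning the measured voltage range, slopes from both signs
#' and two magnitudes, and amplitudes/offsets from the data extremes. The
#' best converged fit by residual sum of squares wins; component 1 is
#' reported as the limb with the more negative half-point.
#'
#' @param voltages Voltages, mV (>= 8 points recommended).
#' @param relative_po Relative open probability at each voltage.
#' @param strict_printed Fit the as-printed asymmetric model variant.
#' @param n_starts Cap on the number of multi-start attempts (default 48).
#' @return Object of class `boltzmann_fit`: list with `par` (named vector
#'   A1 O1 V1 k1 A2 O2 V2 k2), `identifiable` (the gauge-invariant
#'   combinations amp1 = A1-O1, amp2 = A2-O2, baseline = O1+O2, V1, k1,
#'   V2, k2 — shifting offset mass between components changes `par` but
#'   never these), `rss`, `fitted`, `voltages`, `relative_po`,
#'   `strict_printed`.
#' @export
fit_double_boltzmann <- function(voltages, relative_po,
                                 strict_printed = FALSE, n_starts = 48) {
  if (is.data.frame(voltages)) {
    relative_po <- voltages$relative_po
    voltages <- voltages$voltage_mV
  }
  stopifnot(length(voltages) == length(relative_po))
  if (length(voltages) < 8) stop("need >= 8 voltage points")
  if (is.unsorted(voltages) && is.unsorted(rev(voltages)))
    stop("voltages must be monotone")
  V <- as.numeric(voltages); y <- as.numeric(relative_po)
  rng <- range(y); span <- diff(range(V))
  obj <- function(par) {
    p <- stats::setNames(as.list(par),
                         c("A1", "O1", "V1", "k1", "A2", "O2", "V2", "k2"))
    r <- double_boltzmann(V, p, strict_printed) - y
    sum(r * r)
  }
  v_grid <- stats::quantile(V, c(0.25, 0.5, 0.75), names = FALSE)
  k_grid <- c(-0.1, -0.03, 0.03, 0.1)
  starts <- list()
  for (v1 in v_grid) for (k1 in k_grid[k_grid > 0])
    for (v2 in v_grid) for (k2 in k_grid[k_grid < 0]) {
      starts[[length(starts) + 1]] <-
        c(A1 = rng[2], O1 = rng[1], V1 = v1, k1 = k1,
          A2 = rng[2], O2 = rng[1], V2 = v2, k2 = k2)
    }
  # also try both-positive / both-negative slope sign pairs
  starts[[length(starts) + 1]] <-
    c(A1 = rng[2], O1 = rng[1], V1 = v_grid[1], k1 = 0.05,
      A2 = rng[2], O2 = rng[1], V2 = v_grid[3], k2 = 0.05)
  starts[[length(starts) + 1]] <-
    c(A1 = rng[2], O1 = rng[1], V1 = v_grid[1], k1 = -0.05,
      A2 = rng[2], O2 = rng[1], V2 = v_grid[3], k2 = -0.05)
  if (length(starts) > n_starts) starts <- starts[seq_len(n_starts)]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # polish with Nelder-Mead from the BFGS solution
    fit2 <- tryCatch(
      stats::optim(fit$par, obj,
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) fit)
    if (fit2$value < fit$value) fit <- fit2
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("double-Boltzmann fit failed to converge from any start")
  # final polish: alternate quasi-Newton and simplex rounds from the best
  # solution until the objective stops improving
  for (round in 1:3) {
    improved <- FALSE
    for (meth in c("BFGS", "Nelder-Mead")) {
      pol <- tryCatch(
        stats::optim(best$par, obj, method = meth,
                     control = list(maxit = 5000, reltol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(pol) && pol$value < best$value - 1e-16) {
        best <- pol; improved <- TRUE
      }
    }
    if (!improved) break
  }
  par <- .canonicalize_components(best$par)
  p <- stats::setNames(as.list(par),
                       c("A1", "O1", "V1", "k1", "A2", "O2", "V2", "k2"))
  # the model has an exact gauge freedom (shifting offset mass between the
  # two components leaves the curve unchanged), so only these combinations
  # are identifiable from data
  ident <- c(amp1 = par[["A1"]] - par[["O1"]],
             amp2 = par[["A2"]] - par[["O2"]],
             baseline = par[["O1"]] + par[["O2"]],
             V1 = par[["V1"]], k1 = par[["k1"]],
             V2 = par[["V2"]], k2 = par[["k2"]])
  structure(list(par = par, identifiable = ident, rss = best$value,
                 fitted = double_boltzmann(V, p, strict_printed),
                 voltages = V, relative_po = y,
                 strict_printed = strict_printed),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("sum-of-two-Boltzmann fit (rss =", format(x$rss, digits = 4), ")\n")
  print(round(x$par, 4))
  invisible(x)
}

#' Predict from a Boltzmann fit
#' @param object A `boltzmann_fit`.
#' @param voltages Voltages, mV (default the fitted ones).
#' @param ... Ignored.
#' @return Numeric vector.
#' @export
predict.boltzmann_fit <- function(object, voltages = object$voltages, ...) {
  double_boltzmann(voltages, object$par, object$strict_printed)
}

#' Gating polarity index
#'
#' Ratio of the relative open probability at a hyperpolarised potential to
#' that at a depolarised one, `Po(-150 mV) / Po(+50 mV)` by default. An
#' index above 1 marks a predominantly hyperpolarisation-activated
#' (inwardly rectifying) channel, below 1 a depolarisation-activated one.
#' Accepts either a fitted model (evaluated exactly) or a measured curve
#' (linearly interpolated, flagged as such).
#'
#' @param x A `boltzmann_fit`, or a data.frame with `voltage_mV` and
#'   `relative_po`.
#' @param v_neg,v_pos Evaluation potentials, mV (defaults -150 and +50).
#' @return Object of class `polarity_index`: list with `po_neg`, `po_pos`,
#'   `index` (Inf-flagged when `po_pos` is 0), `source` ("fit" or
#'   "interpolated").
#' @export
polarity_index <- function(x, v_neg = -150, v_pos = 50) {
  if (inherits(x, "boltzmann_fit")) {
    po <- predict(x, c(v_neg, v_pos))
    src <- "fit"
  } else {
    V <- x$voltage_mV; y <- x$relative_po
    if (min(V) > v_neg || max(V) < v_pos)
      stop("curve does not span the evaluation potentials")
    po <- stats::approx(V, y, xout = c(v_neg, v_pos))$y
    src <- "interpolated"
  }
  idx <- if (po[2] == 0) Inf else po[1] / po[2]
  structure(list(po_neg = po[1], po_pos = po[2], index = idx,
                 source = src),
            class = "polarity_index")
}

#' Bundled residue-property scales
#'
#' Per-residue physicochemical scales used for gating-polarity
#' correlations:
#' \describe{
#'   \item{`kyte_doolittle`}{Hydropathy index (Kyte & Doolittle 1982).}
#'   \item{`helical_propensity`}{Chou-Fasman alpha-helix propensity
#'     P(alpha); bundled as a stand-in for experimentally derived
#'     transmembrane helical-propensity scales, which correlate with it.}
#'   \item{`turn_propensity`}{Chou-Fasman beta-turn propensity P(turn).}
#' }
#'
#' @param name One of `"kyte_doolittle"`, `"helical_propensity"`,
#'   `"turn_propensity"`.
#' @return Named numeric vector over the 20 one-letter residue codes.
#' @export
residue_scale <- function(name = c("kyte_doolittle", "helical_propensity",
                                   "turn_propensity")) {
  name <- match.arg(name)
  switch(name,
    kyte_doolittle = c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
    helical_propensity = c(
      A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70, Q = 1.11, E = 1.51,
      G = 0.57, H = 1.00, I = 1.08, L = 1.21, K = 1.16, M = 1.45, F = 1.13,
      P = 0.57, S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06),
    turn_propensity = c(
      A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19, Q = 0.98, E = 0.74,
      G = 1.56, H = 0.95, I = 0.47, L = 0.59, K = 1.01, M = 0.60, F = 0.60,
      P = 1.52, S = 1.43, T = 0.96, W = 0.96, Y = 1.14, V = 0.50))
}

#' Correlate gating polarity indices with a residue-property scale
#'
#' Pearson correlation (with least-squares slope and intercept) between a
#' transform of the gating polarity index of each residue substitution and
#' the substituted residue's value on a physicochemical scale. The default
#' transform is `log10`, appropriate for a ratio spanning orders of
#' magnitude. Infinite or non-finite indices are excluded with a warning;
#' a constant transformed index leaves `r` undefined (`NA`) with a flag.
#'
#' @param indices Named numeric vector of polarity indices, names being
#'   one-letter residue codes of the substitution.
#' @param scale A scale name accepted by [residue_scale()] or a named
#'   numeric vector.
#' @param transform Function applied to the indices (default `log10`);
#'   use `identity` for raw indices.
#' @return List with `r`, `slope`, `intercept`, `n`, `excluded`
#'   (character), `undefined` (logical).
#' @export
propensity_correlation <- function(indices, scale = "kyte_doolittle",
                                   transform = log10) {
  if (is.character(scale)) scale <- residue_scale(scale)
  res <- intersect(names(indices), names(scale))
  if (length(res) < length(indices))
    warning("substitution(s) absent from scale: ",
            paste(setdiff(names(indices), res), collapse = ", "))
  y <- transform(indices[res])
  x <- scale[res]
  ok <- is.finite(y) & is.finite(x)
  excluded <- res[!ok]
  if (length(excluded) > 0)
    warning("excluding non-finite index for: ",
            paste(excluded, collapse = ", "))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 substitutions with finite indices")
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = length(x), excluded = excluded, undefined = TRUE))
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(x), excluded = excluded, undefined = FALSE)
}

#' Fit MTSET modification kinetics
#'
#' Fits peak current against cumulative reagent-exposure time to the
#' mono-exponential `I(t) = Iinf + (I0 - Iinf) exp(-t / tau)` and converts
#' the time constant to an apparent second-order modification rate
#' `k2nd = 1 / (tau * concentration)` in 1/(M s). Handles both
#' potentiation (current increase) and inhibition. When the fitted
#' amplitude change is indistinguishable from noise, the rate is flagged
#' as an upper bound only.
#'
#' @param exposure_s Cumulative exposure times, s (>= 5 points).
#' @param current Peak currents (arbitrary units).
#' @param concentration Reagent concentration, mol/L.
#' @return Object of class `modification_fit`: list with `tau` (s),
#'   `k2nd` (1/(M s)), `I0`, `Iinf`, `tau_stderr`, `k2nd_stderr`,
#'   `no_change` (logical upper-bound flag), `fitted`.
#' @export
fit_modification_rate <- function(exposure_s, current, concentration) {
  if (is.data.frame(exposure_s)) {
    current <- exposure_s$peak_current
    exposure_s <- exposure_s$cum_exposure_s
  }
  if (length(exposure_s) < 5) stop("need >= 5 exposure points")
  if (concentration <= 0) stop("concentration must be positive")
  t <- as.numeric(exposure_s); y <- as.numeric(current)
  df <- data.frame(t = t, y = y)
  span <- diff(range(y))
  noise_scale <- stats::sd(diff(y)) / sqrt(2)
  if (span < 1e-12 ||
      (is.finite(noise_scale) && span < 2 * noise_scale)) {
    return(structure(list(tau = Inf, k2nd = 0, I0 = mean(y),
                          Iinf = mean(y), tau_stderr = NA_real_,
                          k2nd_stderr = NA_real_, no_change = TRUE,
                          fitted = rep(mean(y), length(y))),
                     class = "modification_fit"))
  }
  # tau starts: a log-spaced sweep over the observation window
  tau_starts <- exp(seq(log(max(diff(range(t)) / 50, 1e-3)),
                        log(max(t) * 3), length.out = 8))
  best <- NULL
  for (tau0 in tau_starts) {
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ Iinf + (I0 - Iinf) * exp(-t / tau), data = df,
                   start = list(I0 = y[1], Iinf = y[length(y)], tau = tau0),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("mono-exponential fit failed to converge")
  cf <- stats::coef(best$fit)
  if (cf[["tau"]] <= 0) stop("fit converged to non-positive tau")
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(I0 = NA, Iinf = NA, tau = NA))
  tau <- cf[["tau"]]
  k2nd <- 1 / (tau * concentration)
  structure(list(tau = tau, k2nd = k2nd,
                 I0 = cf[["I0"]], Iinf = cf[["Iinf"]],
                 tau_stderr = unname(se["tau"]),
                 k2nd_stderr = unname(se["tau"]) / (tau^2 * concentration),
                 no_change = FALSE,
                 fitted = stats::fitted(best$fit)),
            class = "modification_fit")
}
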