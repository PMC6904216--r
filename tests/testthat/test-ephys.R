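# Po-V curve fitting, polarity indices, propensity correlations, MTSET
# kinetics.

bipolar_truth <- c(A1 = 1, O1 = 0.1, V1 = -100, k1 = 0.08,
                   A2 = 0.6, O2 = 0.1, V2 = 0, k2 = -0.07)

test_that("noiseless double-Boltzmann curves are recovered on the identifiable scale", {
  cv <- make_pov_curve(bipolar_truth)
  fit <- fit_double_boltzmann(cv)
  expect_lt(fit$rss, 1e-8)
  # the model has a one-parameter offset gauge; only combinations on the
  # canonical (k > 0) representation are identifiable: amp1 = 0.9,
  # amp2 = 0.1 - 0.6 = -0.5 after the depolarisation limb is flipped to
  # canonical form, baseline = 0.1 + 0.6 = 0.7
  truth_ident <- c(amp1 = 0.9, amp2 = -0.5, baseline = 0.7,
                   V1 = -100, k1 = 0.08, V2 = 0, k2 = 0.07)
  for (nm in names(truth_ident))
    expect_equal(unname(fit$identifiable[nm]), unname(truth_ident[nm]),
                 tolerance = 0.01, label = nm)
  # component 1 is the hyperpolarisation limb
  expect_lt(fit$par[["V1"]], fit$par[["V2"]])
  # the fitted curve reproduces the truth everywhere
  expect_lt(max(abs(fit$fitted - cv$relative_po)), 1e-4)
})

test_that("parameter recovery holds across random truths (fixed seed)", {
  # random bipolar curves with well-separated half-points and slope
  # factors of 8-17 mV per e-fold; shallower/overlapping components make
  # the decomposition itself ill-conditioned, so the curve-space check
  # below is the binding one there
  set.seed(77)
  n_cases <- 12
  for (i in seq_len(n_cases)) {
    truth <- c(A1 = runif(1, 0.6, 1), O1 = runif(1, 0, 0.2),
               V1 = runif(1, -120, -80), k1 = runif(1, 0.06, 0.12),
               A2 = runif(1, 0.5, 1), O2 = runif(1, 0, 0.2),
               V2 = runif(1, -10, 30), k2 = -runif(1, 0.06, 0.12))
    cv <- make_pov_curve(truth, voltages = seq(-160, 60, by = 10))
    fit <- fit_double_boltzmann(cv)
    # the fitted curve must reproduce the generator everywhere
    expect_lt(max(abs(fit$fitted - cv$relative_po)), 1e-3)
    # canonical parameters recovered within 2% (scaled)
    ct <- canonical_boltzmann(truth)
    ident_truth <- c(amp1 = unname(ct["A1"] - ct["O1"]),
                     amp2 = unname(ct["A2"] - ct["O2"]),
                     baseline = unname(ct["O1"] + ct["O2"]),
                     V1 = unname(ct["V1"]), k1 = unname(ct["k1"]),
                     V2 = unname(ct["V2"]), k2 = unname(ct["k2"]))
    got <- unname(fit$identifiable[names(ident_truth)])
    rel <- abs(got - unname(ident_truth)) /
      pmax(abs(unname(ident_truth)), 0.1)
    expect_lt(max(rel), 0.02, label = paste("case", i))
  }
})

test_that("a flat curve fits as two flat components", {
  V <- seq(-150, 50, by = 20)
  fit <- fit_double_boltzmann(V, rep(0.5, length(V)))
  expect_equal(fit$fitted, rep(0.5, length(V)), tolerance = 1e-6)
})

test_that("single-Boltzmann data: the two-component fit matches a nested oracle", {
  V <- seq(-150, 50, by = 10)
  y <- 0.05 + 0.9 / (1 + exp(0.07 * (V + 80)))
  fit2 <- fit_double_boltzmann(V, y)
  # one-component oracle fit on the same data (optim rather than nls: nls
  # cannot iterate on exactly zero-residual data)
  one_rss <- function(p)
    sum((p[1] + (p[2] - p[1]) / (1 + exp(p[4] * (V - p[3]))) - y)^2)
  one <- optim(c(O = 0, A = 1, Vh = -70, k = 0.05), one_rss,
               method = "BFGS", control = list(reltol = 1e-14))
  one <- optim(one$par, one_rss, control = list(maxit = 5000,
                                                reltol = 1e-15))
  one <- optim(one$par, one_rss, method = "BFGS",
               control = list(reltol = 1e-15))
  rss1 <- one$value
  expect_lt(abs(fit2$rss - rss1), 1e-8)
})

test_that("the as-printed asymmetric model variant is also fittable", {
  cv <- make_pov_curve(bipolar_truth)
  fit <- fit_double_boltzmann(cv, strict_printed = TRUE)
  expect_lt(fit$rss, 1e-6)
})

test_that("polarity index follows its definition and is scale invariant", {
  # direct closed forms through a synthetic fit on a designed curve
  curve <- data.frame(voltage_mV = c(-150, -100, 0, 50),
                      relative_po = c(0.9, 0.5, 0.2, 0.1))
  pidx <- polarity_index(curve)
  expect_equal(pidx$index, 9)
  expect_equal(pidx$source, "interpolated")
  sym <- data.frame(voltage_mV = c(-150, 0, 50),
                    relative_po = c(0.4, 0.1, 0.4))
  expect_equal(polarity_index(sym)$index, 1)
  # scaling the whole curve leaves the ratio unchanged
  scaled <- curve; scaled$relative_po <- scaled$relative_po * 3.7
  expect_equal(polarity_index(scaled)$index, 9, tolerance = 1e-12)
  # zero Po at depolarised potential flags infinity
  zero <- data.frame(voltage_mV = c(-150, 50), relative_po = c(0.5, 0))
  expect_true(is.infinite(polarity_index(zero)$index))
})

test_that("a growing depolarised limb monotonically lowers the polarity index", {
  idx <- sapply(c(0.2, 0.4, 0.6, 0.8), function(a2) {
    truth <- c(A1 = 0.3, O1 = 0, V1 = -110, k1 = 0.08,
               A2 = a2, O2 = 0, V2 = 10, k2 = -0.08)
    cv <- make_pov_curve(truth)
    polarity_index(fit_double_boltzmann(cv))$index
  })
  expect_true(all(diff(idx) < 0))
  expect_lt(idx[4], 1)   # depolarisation-dominated: index well below 1
})

test_that("propensity correlation equals the closed-form Pearson oracle", {
  # indices exactly exp-linear in the scale give |r| = 1
  kd <- residue_scale("kyte_doolittle")
  res <- c("L", "V", "A", "S", "Q")
  idx <- 10^(2 - 0.5 * kd[res])
  names(idx) <- res
  out <- propensity_correlation(idx, "kyte_doolittle")
  expect_equal(abs(out$r), 1, tolerance = 1e-12)
  expect_equal(out$slope, -0.5, tolerance = 1e-9)

  # arbitrary pairing matches the direct formula to 1e-12
  idx3 <- c(L = 12, A = 0.3, S = 55)
  out3 <- propensity_correlation(idx3, "turn_propensity")
  x <- residue_scale("turn_propensity")[names(idx3)]
  y <- log10(idx3)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out3$r, unname(oracle), tolerance = 1e-12)

  # constant indices leave r undefined-flagged
  flat <- propensity_correlation(c(L = 2, A = 2, S = 2), "kyte_doolittle")
  expect_true(flat$undefined)
  expect_true(is.na(flat$r))

  # infinite indices are excluded with a warning
  expect_warning(
    inf_out <- propensity_correlation(
      c(L = 12, A = 0.3, S = 55, V = Inf), "kyte_doolittle"),
    "non-finite")
  expect_equal(inf_out$n, 3)
})

test_that("modification kinetics: exact arithmetic of k = 1/(tau C)", {
  # activated-state rate: tau = 1/(440 * 1e-3) s at 1 mM gives 440 1/(M s)
  tau <- 1 / (440 * 1e-3)
  t <- seq(0, 4 * tau, length.out = 20)
  y <- 2.5 + (1 - 2.5) * exp(-t / tau)
  fit <- fit_modification_rate(t, y, concentration = 1e-3)
  expect_equal(fit$k2nd, 440, tolerance = 1e-6)
  # tau = 10 s at 0.1 M -> 1.0 1/(M s)
  y2 <- 0 + (1 - 0) * exp(-seq(0, 40, 2) / 10)
  fit2 <- fit_modification_rate(seq(0, 40, 2), y2, concentration = 0.1)
  expect_equal(fit2$k2nd, 1.0, tolerance = 1e-6)
  # constant current flags no change
  flatfit <- fit_modification_rate(1:10, rep(2, 10), concentration = 1e-3)
  expect_true(flatfit$no_change)
  expect_error(fit_modification_rate(1:3, 1:3, 1e-3), ">= 5")
  expect_error(fit_modification_rate(1:10, exp(-(1:10)), 0), "positive")
})

test_that("noisy modification courses are recovered within the fitted standard error", {
  for (case in list(list(k = 440, seed = 31), list(k = 7.5, seed = 32))) {
    course <- make_modification_course(case$k, concentration = 1e-3,
                                       timepoints = 20,
                                       noise_frac = 0.02,
                                       seed = case$seed)
    fit <- fit_modification_rate(course, concentration = 1e-3)
    expect_lt(abs(fit$k2nd - case$k), 3 * fit$k2nd_stderr)
    expect_lt(abs(fit$k2nd - case$k) / case$k, 0.10)
  }
})
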