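# Bennett acceptance ratio free-energy estimation and the alchemical
# thermodynamic cycle used to score a point mutation's state preference.
#
# Conventions: work and free energies in kcal/mol; forward work W_f is the
# work of the i -> i+1 transformation, reverse work W_r that of i+1 -> i.
# Crooks' theorem then relates the two work distributions through the true
# free-energy difference, and BAR is the minimum-variance estimator built
# on that relation.

#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872041

#' Convert multiples of kT to kcal/mol
#'
#' @param kt Energy in units of kT.
#' @param temperature Temperature in K (default 300).
#' @return Energy in kcal/mol.
#' @export
kt_to_kcal <- function(kt, temperature = 300) {
  if (temperature <= 0) stop("temperature must be positive")
  kt * KB_KCAL * temperature
}

#' Construct a work-sample set for one lambda window
#'
#' @param forward_work Work samples for the forward transformation,
#'   kcal/mol.
#' @param reverse_work Work samples for the reverse transformation,
#'   kcal/mol.
#' @param temperature Temperature in K (default 300).
#' @param window_index Optional window label.
#' @return Object of class `work_samples`.
#' @export
work_samples <- function(forward_work, reverse_work, temperature = 300,
                         window_index = 1L) {
  if (length(forward_work) == 0 || length(reverse_work) == 0)
    stop("both work directions must be non-empty")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(forward_work = as.numeric(forward_work),
                 reverse_work = as.numeric(reverse_work),
                 temperature = as.numeric(temperature),
                 window_index = as.integer(window_index)),
            class = "work_samples")
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Solves the BAR self-consistency equation
#' `sum_f 1/(1 + exp(M + beta W_f - beta dG)) =
#'  sum_r 1/(1 + exp(-M + beta W_r + beta dG))`
#' with `M = ln(n_f/n_r)`, by bracketed root-finding to 1e-8 kcal/mol.
#' The standard error comes from the asymptotic maximum-likelihood
#' variance; when the forward and reverse work distributions barely
#' overlap the variance estimate diverges and the result is flagged.
#'
#' @param samples A [work_samples()] object.
#' @return List with `dG` (kcal/mol), `stderr` (kcal/mol), and
#'   `overlap_warning` (logical).
#' @export
bar_estimate <- function(samples) {
  wf <- samples$forward_work
  wr <- samples$reverse_work
  if (length(wf) < 10 || length(wr) < 10)
    stop("need >= 10 work samples in each direction")
  beta <- 1 / (KB_KCAL * samples$temperature)
  M <- log(length(wf) / length(wr))
  fermi <- function(x) 1 / (1 + exp(pmin(x, 700)))
  g <- function(dG)
    sum(fermi(M + beta * (wf - dG))) - sum(fermi(-M + beta * (wr + dG)))
  # bracket: dG lies within the span of the work values (shifted by M/beta)
  lo <- min(-wr, wf) - abs(M) / beta - 1
  hi <- max(-wr, wf) + abs(M) / beta + 1
  # g is monotone increasing in dG
  root <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-8,
                         extendInt = "upX")
  dG <- root$root
  # asymptotic variance (maximum-likelihood form): the Fisher information
  # of the pooled logistic problem minus the sampling-count term
  x <- c(M + beta * (wf - dG), -(-M + beta * (wr + dG)))
  sech2 <- 1 / (2 + 2 * cosh(pmin(abs(x), 700)))
  info <- sum(sech2)
  nf <- length(wf); nr <- length(wr)
  var_beta_dG <- 1 / info - (nf + nr) / (nf * nr)
  overlap_warning <- !is.finite(var_beta_dG) || var_beta_dG <= 0 ||
    info < 1e-12
  stderr <- if (overlap_warning) NA_real_ else sqrt(var_beta_dG) / beta
  if (overlap_warning)
    warning("work distributions barely overlap; BAR stderr unreliable")
  list(dG = dG, stderr = stderr, overlap_warning = overlap_warning)
}

#' Chain lambda-window free energies
#'
#' Total free energy of a multi-window alchemical path: the per-window
#' estimates add, and their standard errors combine in quadrature under
#' the independent-window assumption.
#'
#' @param per_window List of per-window results, each a list with `dG` and
#'   `stderr` (e.g. outputs of [bar_estimate()]).
#' @return List with `dG`, `stderr`, `n_windows`.
#' @export
chain_windows <- function(per_window) {
  if (length(per_window) == 0) stop("no windows supplied")
  dgs <- vapply(per_window, function(w) w$dG, numeric(1))
  ses <- vapply(per_window, function(w)
    if (is.null(w$stderr)) NA_real_ else w$stderr, numeric(1))
  list(dG = sum(dgs),
       stderr = if (all(is.finite(ses))) sqrt(sum(ses^2)) else NA_real_,
       n_windows = length(per_window))
}

#' Alchemical thermodynamic cycle for a mutation's state preference
#'
#' Combines per-conformation alchemical free energies of the wild-type ->
#' mutant transformation computed in the activated and resting states:
#' `ddG_per_vsd = mean(dG_activated) - mean(dG_resting)`. A positive value
#' means the mutation destabilises the activated state relative to the
#' resting one. The per-channel value assumes `subunits` independent
#' identical voltage sensors. The standard error combines the two
#' leg-level standard errors in quadrature; a leg with a single estimate
#' contributes no spread.
#'
#' @param legs_activated,legs_resting Numeric vectors of per-conformation
#'   dG values (kcal/mol) for each leg.
#' @param subunits Sensors per channel (default 4).
#' @return Object of class `cycle_result`: list with `dG_activated`,
#'   `dG_resting`, `ddG_per_vsd`, `ddG_per_channel`, `stderr`.
#' @export
thermodynamic_cycle <- function(legs_activated, legs_resting, subunits = 4) {
  if (length(legs_activated) < 1 || length(legs_resting) < 1)
    stop("both legs need >= 1 estimate")
  se_leg <- function(x)
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  dga <- mean(legs_activated)
  dgr <- mean(legs_resting)
  ddg <- dga - dgr
  se <- sqrt(se_leg(legs_activated)^2 + se_leg(legs_resting)^2)
  structure(list(dG_activated = dga, dG_resting = dgr,
                 ddG_per_vsd = ddg,
                 ddG_per_channel = subunits * ddg,
                 stderr = se),
            class = "cycle_result")
}

#' Read work samples from CSV
#'
#' Expected columns: `window`, `direction` (`"forward"`/`"reverse"`),
#' `work_kcal_mol`.
#'
#' @param path CSV path.
#' @param temperature Temperature in K attached to every window.
#' @return List of [work_samples()], one per window, in window order.
#' @export
read_work_csv <- function(path, temperature = 300) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window", "direction", "work_kcal_mol")
  if (!all(need %in% names(df)))
    stop("work CSV must have columns ", paste(need, collapse = ", "))
  lapply(sort(unique(df$window)), function(w) {
    sub <- df[df$window == w, ]
    work_samples(sub$work_kcal_mol[sub$direction == "forward"],
                 sub$work_kcal_mol[sub$direction == "reverse"],
                 temperature = temperature, window_index = w)
  })
}
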