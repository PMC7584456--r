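# Electrophysiology analysis: Boltzmann activation fits on normalized
# tail currents, exponential gating kinetics, conversion of the fit to
# an activation energy, and double-mutant-cycle coupling energies.
#
# Normalized KCNQ1-KCNE1 tail currents do not saturate over the tested
# voltage range, so the fitted half-activation voltage is an
# "apparent" V1/2 (V1/2app) throughout.

#' Boltzmann activation curve
#'
#' `I_tail/I_tail,max = (1 - I_bottom) / (1 + exp((V1/2 - V)/k)) +
#' I_bottom`.
#'
#' @param v voltage (mV).
#' @param v12 half-activation voltage (mV).
#' @param k slope factor (mV).
#' @param bottom bottom plateau (dimensionless).
#' @return normalized tail current.
#' @export
boltzmann_gv <- function(v, v12, k, bottom = 0) {
  (1 - bottom) / (1 + exp((v12 - v) / k)) + bottom
}

fit_boltzmann_one <- function(v, y) {
  if (length(unique(v)) < 4) stop("need at least 4 distinct voltages")
  if (stats::sd(y) < 1e-9) stop("flat data; Boltzmann fit is undefined")
  b0 <- max(0, min(y))
  half <- (min(y) + max(y)) / 2
  v0 <- v[which.min(abs(y - half))]
  yr <- (y - min(y)) / max(1e-12, diff(range(y)))
  v20 <- v[which.min(abs(yr - 0.2))]
  v80 <- v[which.min(abs(yr - 0.8))]
  k0 <- max(1, abs(v80 - v20) / (2 * log(4)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (1 - bottom) / (1 + exp((v12 - v) / k)) + bottom,
      start = list(v12 = v0, k = k0, bottom = b0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(v12 = NA_real_, k = NA_real_, bottom = NA_real_,
                rss = NA_real_, converged = FALSE, negative_k = FALSE,
                vcov = NULL))
  }
  cf <- stats::coef(fit)
  list(
    v12 = unname(cf["v12"]), k = unname(cf["k"]),
    bottom = unname(cf["bottom"]),
    rss = sum(stats::residuals(fit)^2),
    converged = TRUE, negative_k = unname(cf["k"]) <= 0,
    vcov = tryCatch(stats::vcov(fit), error = function(e) NULL)
  )
}

#' Fit Boltzmann activation curves per cell
#'
#' `data` holds records of normalized tail current versus voltage with
#' columns `voltage`, `current` and optionally `cell` and `genotype`.
#' Each cell is fitted independently by nonlinear least squares
#' (starting values taken from the data: V at half range, slope from
#' the 20-80% span) and fits are aggregated as mean +/- SEM across
#' cells. A fit with non-positive slope is flagged, not silently kept.
#'
#' @param data data frame as described.
#' @param genotype optional genotype label to filter on.
#' @return a `BoltzmannFit`: list with `cells` (per-cell data frame),
#'   `v12`, `k`, `bottom` (means), `v12_sem`, `n_cells`, `converged`.
#' @export
fit_boltzmann <- function(data, genotype = NULL) {
  if (!is.null(genotype)) data <- data[data$genotype == genotype, , drop = FALSE]
  if (!nrow(data)) stop("no records", if (!is.null(genotype))
    paste0(" for genotype ", genotype))
  if (is.null(data$cell)) data$cell <- 1L
  cells <- split(data, data$cell)
  rows <- lapply(names(cells), function(cid) {
    f <- fit_boltzmann_one(cells[[cid]]$voltage, cells[[cid]]$current)
    data.frame(cell = cid, v12 = f$v12, k = f$k, bottom = f$bottom,
               rss = f$rss, converged = f$converged,
               negative_k = f$negative_k, stringsAsFactors = FALSE)
  })
  cells_df <- do.call(rbind, rows)
  ok <- cells_df$converged & !cells_df$negative_k
  n <- sum(ok)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(list(
    cells = cells_df,
    v12 = mean(cells_df$v12[ok]), k = mean(cells_df$k[ok]),
    bottom = mean(cells_df$bottom[ok]),
    v12_sem = sem(cells_df$v12[ok]),
    n_cells = n,
    converged = n > 0,
    genotype = genotype %||% NA_character_
  ), class = "BoltzmannFit")
}

#' @export
print.BoltzmannFit <- function(x, ...) {
  cat(sprintf(
    "BoltzmannFit%s: V1/2app = %.2f +/- %s mV, k = %.2f mV, bottom = %.3f (n = %d)\n",
    if (is.na(x$genotype)) "" else paste0(" [", x$genotype, "]"),
    x$v12, ifelse(is.na(x$v12_sem), "NA", sprintf("%.2f", x$v12_sem)),
    x$k, x$bottom, x$n_cells
  ))
  invisible(x)
}

#' Shift in apparent half-activation voltage
#'
#' `delta = V1/2app(mutant) - V1/2app(WT)` with the standard error
#' propagated in quadrature from the per-genotype SEMs.
#'
#' @param fit_mut,fit_wt converged [fit_boltzmann()] results.
#' @return list with `delta_v12` (mV) and `se`.
#' @export
delta_v12 <- function(fit_mut, fit_wt) {
  if (!fit_mut$converged || !fit_wt$converged) {
    stop("both fits must have converged")
  }
  se <- sqrt(sum(c(fit_mut$v12_sem, fit_wt$v12_sem)^2, na.rm = TRUE))
  list(delta_v12 = fit_mut$v12 - fit_wt$v12, se = se)
}

#' Single-exponential time-constant fit
#'
#' Activation: `I(t) = A (1 - exp(-t/tau)) + B`; deactivation:
#' `I(t) = A exp(-t/tau) + B`. A tau outside `(0, 10 x window)` is
#' flagged as unreliable.
#'
#' @param trace data frame with columns `time` (ms, uniform sampling)
#'   and `current`.
#' @param phase `"activation"` or `"deactivation"`.
#' @return list with `tau` (ms), `amplitude`, `baseline`, `converged`,
#'   `flagged`.
#' @export
fit_time_constant <- function(trace, phase = c("activation", "deactivation")) {
  phase <- match.arg(phase)
  t <- trace$time; y <- trace$current
  if (stats::sd(y) < 1e-12) stop("constant trace; no kinetics to fit")
  window <- diff(range(t))
  a0 <- diff(range(y)) * if (phase == "activation") 1 else 1
  b0 <- if (phase == "activation") min(y) else min(y)
  tau0 <- window / 5
  form <- if (phase == "activation") {
    y ~ A * (1 - exp(-t / tau)) + B
  } else {
    y ~ A * exp(-t / tau) + B
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = list(A = a0, tau = tau0, B = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(tau = NA_real_, amplitude = NA_real_, baseline = NA_real_,
                converged = FALSE, flagged = TRUE))
  }
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  list(
    tau = tau, amplitude = unname(cf["A"]), baseline = unname(cf["B"]),
    converged = TRUE,
    flagged = !(tau > 0 && tau < 10 * window)
  )
}

#' Activation energy from a Boltzmann fit
#'
#' Convention: the equivalent gating charge is `z = RT / (F k)` and the
#' activation energy `dG0 = z F V1/2 = RT V1/2 / k`, reported in
#' kcal/mol. This is one standard convention for converting a
#' two-state G(V) fit into an energy; it is labelled as such in all
#' outputs.
#'
#' @param fit a converged `BoltzmannFit` with positive slope factor.
#' @param temperature temperature in Kelvin (default 295, room
#'   temperature recordings).
#' @return activation energy dG0 in kcal/mol.
#' @export
activation_energy <- function(fit, temperature = 295) {
  if (!fit$converged) stop("fit did not converge")
  if (fit$k <= 0) stop("slope factor must be positive")
  R <- 8.31446261815324 # J / mol / K
  (R * temperature * (fit$v12 / fit$k)) / 4184
}

#' Double-mutant-cycle coupling energy
#'
#' With activation energies expressed relative to the wild-type pair
#' (dG_WT = 0), the coupling energy is
#' `ddG = dG_double - dG_mut1 - dG_mut2`; the two residues are called
#' interacting when `|ddG| >= cutoff` (1.0 kcal/mol by convention).
#'
#' @param dg_m1,dg_m2 single-mutant energies (kcal/mol, relative to WT).
#' @param dg_double double-mutant energy (kcal/mol, relative to WT).
#' @param cutoff interaction call threshold (kcal/mol, default 1.0).
#' @return a `CycleResult`: list with `ddg`, `abs_ddg`, `interacting`,
#'   and the input energies.
#' @export
mutant_cycle <- function(dg_m1, dg_m2, dg_double, cutoff = 1.0) {
  ddg <- dg_double - dg_m1 - dg_m2
  structure(list(
    dg_m1 = dg_m1, dg_m2 = dg_m2, dg_double = dg_double,
    ddg = ddg, abs_ddg = abs(ddg),
    cutoff = cutoff, interacting = abs(ddg) >= cutoff
  ), class = "CycleResult")
}

#' @export
print.CycleResult <- function(x, ...) {
  cat(sprintf(
    "Mutant cycle: ddG = %.2f kcal/mol (|ddG| = %.2f) -> %s (cutoff %.1f)\n",
    x$ddg, x$abs_ddg,
    if (x$interacting) "interacting" else "not interacting", x$cutoff
  ))
  invisible(x)
}
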