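#' Deterministic slowdown experiment: pulsing vs per-cycle mean input
#'
#' Runs the phosphorelay under a decreasing growth-rate schedule, feeds the
#' resulting pulsatile Spo0A~P trace and its per-cycle mean to the biofilm
#' network from a matrix-ON start, and reports when (and at which growth
#' rate) each input deactivates matrix production.
#'
#' @param g_start,g_end growth-rate ramp endpoints (1/h).
#' @param t_end ramp duration (h).
#' @param mode per-cycle surrogate for the comparison input
#'   (\code{"mean"}, \code{"max"}, \code{"min"}).
#' @param phos_params,biofilm_par model parameters.
#' @param extend extra time (h) simulated at the final growth rate, giving
#'   slow deactivations time to complete.
#' @return list: \code{signal} (pulsing input), \code{signal_const}
#'   (surrogate), \code{traj_pulsing}, \code{traj_const},
#'   \code{deactivation_time} (named, NA if still ON), \code{growth}.
#' @export
run_fig2 <- function(g_start = 0.6, g_end = 0.15, t_end = 60,
                     mode = "mean", phos_params = phosphorelay_params(),
                     biofilm_par = biofilm_params(), extend = 40) {
  growth <- function(t) {
    t <- pmin(pmax(t, 0), t_end)
    g_start + (g_end - g_start) * t / t_end
  }
  total <- t_end + extend
  phos <- simulate_phosphorelay(phos_params, growth = growth, t_end = total,
                                dt = 0.01)
  bounds <- attr(phos, "cycle_bounds")
  sig <- oap_signal(phos$time, phos$Ap)
  sig_const <- per_cycle_constant(sig, bounds, mode = mode)

  ref <- matrix_reference(biofilm_par)
  dur <- max(sig$times)
  tr_p <- simulate_biofilm(biofilm_par, sig, growth, dur, ref$state_on,
                           dt = 0.05)
  tr_c <- simulate_biofilm(biofilm_par, sig_const, growth, dur, ref$state_on,
                           dt = 0.05)
  deact <- function(tr) {
    i <- which(tr$TapA < ref$midpoint)
    if (length(i) == 0) NA_real_ else tr$time[i[1]]
  }
  td <- c(pulsing = deact(tr_p), constant = deact(tr_c))
  list(signal = sig, signal_const = sig_const, traj_pulsing = tr_p,
       traj_const = tr_c, deactivation_time = td,
       deactivation_growth = ifelse(is.na(td), NA, growth(td)),
       growth = growth, midpoint = ref$midpoint, cycle_bounds = bounds)
}

#' Stochastic ensembles and two-state fits: pulsing vs constant input
#'
#' The natural pulse at the given growth rate and its mean are fed to the
#' stochastic matrix model; for each input an initially-OFF and an
#' initially-ON ensemble are simulated, ON-fractions computed and the
#' two-state occupancy model fitted, yielding (kON, kOFF) per input.
#'
#' @param n_cells cells per ensemble arm.
#' @param g growth rate (1/h).
#' @param duration recorded time (h).
#' @param seed base seed (arms use distinct offsets).
#' @param model optional prebuilt \code{ssa_model}.
#' @param phos_params phosphorelay parameters for the input.
#' @param threshold ON threshold (molecules).
#' @param dt_record recording grid (h).
#' @return list with \code{fit_pulsing}, \code{fit_constant}, the four
#'   ensembles, and the two inputs.
#' @export
run_fig3 <- function(n_cells = 2000, g = 0.4, duration = 40, seed = 1,
                     model = NULL, phos_params = phosphorelay_params(),
                     threshold = 200, dt_record = 0.1) {
  if (is.null(model)) model <- biofilm_ssa_model(g = g)
  tim <- timing_from_growth(g)
  cyc <- natural_pulse_cycle(phos_params, tim)
  pulse_fun <- tile_signal_fun(cyc, tim$tau_cyc)
  cmean <- mean_of_cycle(cyc)

  ens <- list()
  offs <- c(pulsing_off = 0, pulsing_on = 1, constant_off = 2, constant_on = 3)
  for (nm in names(offs)) {
    input <- if (startsWith(nm, "pulsing")) pulse_fun else cmean
    ini <- if (endsWith(nm, "_on")) "on" else "off"
    ens[[nm]] <- run_ensemble(model, input, n_cells, duration, initial = ini,
                              seed_base = seed + offs[[nm]] * n_cells,
                              dt_record = dt_record)
  }
  fit_p <- fit_rates(fraction_on(ens$pulsing_off, threshold),
                     fraction_on(ens$pulsing_on, threshold))
  fit_c <- fit_rates(fraction_on(ens$constant_off, threshold),
                     fraction_on(ens$constant_on, threshold))
  list(fit_pulsing = fit_p, fit_constant = fit_c, ensembles = ens,
       input_mean = cmean, pulse = cyc, g = g, threshold = threshold)
}

#' Bistability diagram and oscillation-period threshold analysis
#'
#' @param g_grid growth rates for the constant-input threshold curve.
#' @param periods oscillation periods (h) for fixed-g thresholds.
#' @param matched_lengths cycle lengths for the matched-period curve.
#' @param params biofilm parameters.
#' @param ... passed to the threshold searches.
#' @return list: \code{constant_curve} (g vs MOFF), \code{period_curve}
#'   (T vs MOFF at g = 0.2), \code{matched} (threshold_curve),
#'   \code{fit} (powerlaw_fit).
#' @export
run_fig4 <- function(g_grid = c(0.1, 0.15, 0.2, 0.3),
                     periods = c(1, 3, 6),
                     matched_lengths = c(1, 3, 5, 6),
                     params = biofilm_params(), ...) {
  ref <- matrix_reference(params)
  const_curve <- data.frame(
    g = g_grid,
    moff = vapply(g_grid, function(g)
      bistable_threshold_constant(g, params, reference = ref), 0))
  period_curve <- data.frame(
    period = periods,
    moff = vapply(periods, function(T)
      oscillatory_threshold(T, 0.2, params, reference = ref, ...), 0))
  matched <- matched_period_curve(matched_lengths, params, ...)
  list(constant_curve = const_curve, period_curve = period_curve,
       matched = matched, fit = power_law_fit(matched))
}

#' Cycle-phase slowdown comparison (replication vs post-replication)
#'
#' Finds the deactivating cycle length when the cell cycle lengthens
#' through the DNA replication period only, and through the
#' post-replication period only.
#'
#' @param params,phos_params model parameters.
#' @param ... passed to \code{\link{find_deactivation_cycle}}.
#' @return list of two \code{deactivation_search} objects,
#'   \code{replication} and \code{post}.
#' @export
run_fig5 <- function(params = biofilm_params(),
                     phos_params = phosphorelay_params(), ...) {
  ref <- matrix_reference(params)
  list(replication = find_deactivation_cycle(params, phos_params,
                                             scenario = "replication",
                                             reference = ref, ...),
       post = find_deactivation_cycle(params, phos_params,
                                      scenario = "post",
                                      reference = ref, ...))
}

#' Five-condition decomposition of the deactivation threshold
#'
#' Cell-cycle deactivation thresholds for: the full model; without the
#' growth effect on protein dilution; without the growth effect on gene
#' dosage; without either; and with the pulsatile input replaced by its
#' per-cycle mean.
#'
#' @param params,phos_params model parameters.
#' @param conditions subset of condition names to run.
#' @param ... passed to \code{\link{find_deactivation_cycle}}.
#' @return named numeric vector of deactivating cycle lengths (h).
#' @export
run_fig6 <- function(params = biofilm_params(),
                     phos_params = phosphorelay_params(),
                     conditions = c("full", "no_dilution", "no_dosage",
                                    "neither", "constant_input"), ...) {
  ref <- matrix_reference(params)
  specs <- list(
    full = list(effects = biofilm_effects(), input = "pulsing"),
    no_dilution = list(effects = biofilm_effects(dilution = "fixed"),
                       input = "pulsing"),
    no_dosage = list(effects = biofilm_effects(dosage = "frozen"),
                     input = "pulsing"),
    neither = list(effects = biofilm_effects(dilution = "fixed",
                                             dosage = "frozen"),
                   input = "pulsing"),
    constant_input = list(effects = biofilm_effects(), input = "constant")
  )
  out <- vapply(conditions, function(nm) {
    s <- specs[[nm]]
    find_deactivation_cycle(params, phos_params, input = s$input,
                            effects = s$effects, reference = ref, ...)$tau_deact
  }, 0)
  names(out) <- conditions
  out
}
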