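#' Stable steady states of the matrix network under constant input
#'
#' Integrates to steady state from an OFF-like (SinR-dominated) and an
#' ON-like (SlrR-dominated) initial condition and reports the distinct
#' stable TapA levels found (1 = monostable, 2 = bistable).
#'
#' @param c0A constant Spo0A~P level (uM).
#' @param g growth rate (1/h).
#' @param params \code{biofilm_params}.
#' @param effects growth-effect switches.
#' @param distinct_factor TapA ratio above which the two end states are
#'   called distinct branches.
#' @return data.frame with columns \code{branch} ("OFF"/"ON") and
#'   \code{tapA}; one row per stable state.
#' @export
constant_input_steady_states <- function(c0A, g = 0.2,
                                         params = biofilm_params(),
                                         effects = biofilm_effects(),
                                         distinct_factor = 10) {
  if (c0A < 0) stop("c0A must be >= 0")
  s_off <- biofilm_steady(params, c0A, g, .matrix_off_init(), effects)
  s_on <- biofilm_steady(params, c0A, g, .matrix_on_init(), effects)
  if (s_on[["TapA"]] > distinct_factor * s_off[["TapA"]])
    data.frame(branch = c("OFF", "ON"),
               tapA = c(s_off[["TapA"]], s_on[["TapA"]]))
  else
    data.frame(branch = if (s_on[["TapA"]] > 1) "ON" else "OFF",
               tapA = s_on[["TapA"]])
}

# canonical initial conditions for the two basins
.matrix_off_init <- function() {
  stats::setNames(c(0, 2, 1, 0, 0, 0, 0), .biofilm_species)
}
.matrix_on_init <- function() {
  stats::setNames(c(0.2, 0, 0, 0, 4, 1, 2), .biofilm_species)
}

#' Matrix deactivation threshold under constant Spo0A~P
#'
#' The smallest constant Spo0A~P level at which the matrix-ON branch still
#' exists (below it the system is monostable OFF), located by bisection on
#' the ON-initialized steady state.
#'
#' @param g growth rate (1/h).
#' @param params \code{biofilm_params}.
#' @param effects growth-effect switches.
#' @param bracket initial search interval (uM).
#' @param tol bisection tolerance (uM).
#' @param reference optional precomputed \code{matrix_reference()}; the
#'   ON/OFF midpoint is always taken at the fixed g = 0.2 reference
#'   condition so that one classifier serves the whole growth-rate range.
#' @return threshold MOFF (uM).
#' @export
bistable_threshold_constant <- function(g = 0.2, params = biofilm_params(),
                                        effects = biofilm_effects(),
                                        bracket = c(0, 2), tol = 1e-3,
                                        reference = NULL) {
  if (is.null(reference))
    reference <- matrix_reference(params, effects = effects)
  # ON-branch continuation from the converged reference ON state: a naive
  # ON-like guess can transiently collapse inside a shallow basin near the
  # fold and overestimate the threshold
  on_holds <- function(c0A) {
    s <- biofilm_steady(params, c0A, g, reference$state_on, effects)
    s[["TapA"]] >= reference$midpoint
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (!on_holds(hi))
    stop("no ON branch at the upper bracket ", hi,
         " uM; tested range [", lo, ", ", hi, "]")
  if (on_holds(lo)) return(lo)  # ON persists to the lower bracket
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (on_holds(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Matrix deactivation threshold under cosine oscillations
#'
#' For a zero-minimum cosine input of period T, finds by bisection the
#' smallest oscillation mean (= amplitude) for which a matrix-ON cell
#' stays ON over a long horizon. The classification compares the final
#' full period's mean TapA with the constant-input branch midpoint.
#'
#' @param period oscillation period T (h).
#' @param g growth rate (1/h).
#' @param params \code{biofilm_params}.
#' @param effects growth-effect switches.
#' @param bracket amplitude search interval (uM).
#' @param tol bisection tolerance (uM).
#' @param horizon simulation length (h); default max(200, 25 T).
#' @param reference optional precomputed \code{matrix_reference()}.
#' @return threshold mean (uM).
#' @export
oscillatory_threshold <- function(period, g = 0.2, params = biofilm_params(),
                                  effects = biofilm_effects(),
                                  bracket = c(0, 8), tol = 1e-3,
                                  horizon = NULL, reference = NULL) {
  if (period <= 0) stop("period must be positive")
  if (is.null(horizon)) horizon <- max(200, 25 * period)
  # classifier midpoint always taken at the fixed g = 0.2 reference
  if (is.null(reference))
    reference <- matrix_reference(params, effects = effects)
  n_per <- ceiling(horizon / period)
  on_survives <- function(amplitude) {
    input <- function(t) amplitude * cos(2 * pi * t / period) + amplitude
    sim <- simulate_biofilm(params, input, g, n_per * period,
                            reference$state_on, effects, dt = 0.05,
                            rtol = 1e-6, atol = 1e-9)
    lastp <- sim$time >= sim$time[nrow(sim)] - period - 1e-9
    mean(sim$TapA[lastp]) >= reference$midpoint
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (!on_survives(hi))
    stop("ON state not sustained at the upper bracket ", hi, " uM")
  if (on_survives(lo)) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (on_survives(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Matched-period deactivation-threshold curve
#'
#' For each cycle length the oscillation period is set equal to it (one
#' Spo0A~P pulse per cell cycle, the natural situation) and the
#' deactivation threshold is computed with the growth rate implied by the
#' cycle length (g = ln 2 / tau_cyc).
#'
#' @param cycle_lengths cycle lengths = periods (h).
#' @param params \code{biofilm_params}.
#' @param effects growth-effect switches.
#' @param ... passed to \code{\link{oscillatory_threshold}}.
#' @return object of class \code{threshold_curve}: data.frame with
#'   \code{tau_cyc} and \code{moff}.
#' @export
matched_period_curve <- function(cycle_lengths = c(1, 3, 5, 6),
                                 params = biofilm_params(),
                                 effects = biofilm_effects(), ...) {
  reference <- matrix_reference(params, effects = effects)
  moff <- vapply(cycle_lengths, function(tc)
    oscillatory_threshold(period = tc, g = log(2) / tc, params = params,
                          effects = effects, reference = reference, ...), 0)
  structure(data.frame(tau_cyc = cycle_lengths, moff = moff),
            class = c("threshold_curve", "data.frame"))
}

#' Power-law fit of a deactivation-threshold curve
#'
#' Nonlinear least squares of \eqn{M_{OFF} = a \tau_{cyc}^b + c} with
#' positivity bounds on a and c, multi-start to avoid local minima.
#'
#' @param curve a \code{threshold_curve} (or data.frame with
#'   \code{tau_cyc}, \code{moff}).
#' @param n_starts number of jittered starts.
#' @param start initial parameter guess.
#' @return object of class \code{powerlaw_fit}: list with \code{a},
#'   \code{b}, \code{c}, \code{r_squared}, \code{fitted}, \code{residuals}.
#' @export
power_law_fit <- function(curve, n_starts = 5,
                          start = c(a = 0.05, b = 2, c = 0.1)) {
  x <- curve$tau_cyc; y <- curve$moff
  if (length(x) < 4) stop("need at least 4 points to fit 3 parameters")
  best <- NULL
  set_rss <- Inf
  for (i in seq_len(n_starts)) {
    st <- start * if (i == 1) 1 else exp(stats::runif(3, -0.7, 0.7))
    fit <- try(minpack.lm::nlsLM(
      y ~ a * x^b + c,
      start = as.list(st),
      lower = c(a = 1e-8, b = -10, c = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < set_rss) { set_rss <- rss; best <- fit }
  }
  if (is.null(best)) stop("power-law fit failed from all starts")
  cf <- stats::coef(best)
  r2 <- 1 - set_rss / sum((y - mean(y))^2)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]), r_squared = r2,
                 fitted = stats::fitted(best),
                 residuals = stats::residuals(best),
                 data = data.frame(tau_cyc = x, moff = y)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("MOFF = %.4g * tau_cyc^%.3g + %.4g   (R^2 = %.4f)\n",
              x$a, x$b, x$c, x$r_squared))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}
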