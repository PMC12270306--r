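#' Fraction of matrix-ON cells over time
#'
#' Classifies each cell at each time as matrix-ON when its TapA count is
#' at or above the threshold (default 200 molecules, set at the antimode
#' of the bimodal TapA distribution) and returns
#' \eqn{F_{ON}(t) = N_{ON}/(N_{ON}+N_{OFF})}.
#'
#' @param ensemble an \code{ssa_ensemble}.
#' @param threshold ON classification threshold (molecules), inclusive.
#' @return object of class \code{on_fraction}: data.frame \code{time},
#'   \code{fon}; attributes \code{n_cells}, \code{threshold}.
#' @export
fraction_on <- function(ensemble, threshold = 200) {
  stopifnot(inherits(ensemble, "ssa_ensemble"))
  if (threshold <= 0) stop("threshold must be positive")
  fon <- colMeans(ensemble$tapA >= threshold)
  structure(data.frame(time = ensemble$times, fon = fon),
            class = c("on_fraction", "data.frame"),
            n_cells = ensemble$n_cells, threshold = threshold,
            initial = ensemble$initial)
}

#' Two-state occupancy probability
#'
#' Probability of the ON state of a memoryless ON/OFF switch with rates
#' kON, kOFF:
#' \eqn{P(t) = P_0 e^{-t(k_{ON}+k_{OFF})} + \frac{k_{ON}}{k_{ON}+k_{OFF}}
#' (1 - e^{-t(k_{ON}+k_{OFF})})}.
#' The initially-OFF and initially-ON special cases are \code{p0 = 0} and
#' \code{p0 = 1}; both approach kON/(kON+kOFF).
#'
#' @param t time (h), vectorized.
#' @param k_on,k_off switching rates (1/h), non-negative.
#' @param p0 initial ON probability.
#' @return P(t).
#' @export
pon <- function(t, k_on, k_off, p0 = 0) {
  if (k_on < 0 || k_off < 0) stop("rates must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  ks <- k_on + k_off
  if (ks == 0) {
    warning("k_on = k_off = 0: frozen chain, returning p0")
    return(rep(p0, length(t)))
  }
  e <- exp(-t * ks)
  p0 * e + (k_on / ks) * (1 - e)
}

#' Simultaneous kON/kOFF estimation from two ensembles
#'
#' Fits one (kON, kOFF) pair to the ON-fraction curves of an
#' initially-OFF ensemble (occupancy law with P0 = 0) and an initially-ON
#' ensemble (P0 = 1) by minimizing the pooled sum of squared residuals.
#' Bounded multi-start optimization; reports per-curve R-squared and the
#' pooled mean squared error.
#'
#' @param series_off \code{on_fraction} of the initially-OFF ensemble.
#' @param series_on \code{on_fraction} of the initially-ON ensemble.
#' @param bounds box constraints on both rates (1/h).
#' @param n_starts number of optimization starts.
#' @return object of class \code{twostate_fit} with elements \code{k_on},
#'   \code{k_off}, \code{r2_off}, \code{r2_on}, \code{mse},
#'   \code{pon_inf}, and the input series.
#' @export
fit_rates <- function(series_off, series_on, bounds = c(1e-6, 10),
                      n_starts = 12) {
  if (!isTRUE(all.equal(series_off$time, series_on$time)))
    stop("the two series must share one time grid")
  t <- series_off$time
  y_off <- series_off$fon; y_on <- series_on$fon
  if (max(y_off) < 1e-12 && min(y_on) > 1 - 1e-12)
    warning("degenerate series (constant 0 and constant 1): ",
            "rates lie at the search boundary")
  obj <- function(par) {
    k <- exp(par)
    sum((pon(t, k[1], k[2], 0) - y_off)^2) +
      sum((pon(t, k[1], k[2], 1) - y_on)^2)
  }
  lb <- log(bounds[1]); ub <- log(bounds[2])
  starts <- rbind(c(-3, -3),
                  as.matrix(expand.grid(seq(lb + 1, ub - 1, length.out = 4),
                                        seq(lb + 1, ub - 1, length.out = 4))))
  starts <- starts[seq_len(min(nrow(starts), n_starts)), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                      lower = lb, upper = ub)
    if (is.null(best) || o$value < best$value) best <- o
  }
  k <- unname(exp(best$par))
  fit_off <- pon(t, k[1], k[2], 0); fit_on <- pon(t, k[1], k[2], 1)
  r2 <- function(y, f) 1 - sum((y - f)^2) / max(sum((y - mean(y))^2), 1e-300)
  structure(list(k_on = k[1], k_off = k[2],
                 r2_off = r2(y_off, fit_off), r2_on = r2(y_on, fit_on),
                 mse = best$value / (2 * length(t)),
                 pon_inf = k[1] / sum(k),
                 series_off = series_off, series_on = series_on,
                 fitted_off = fit_off, fitted_on = fit_on),
            class = "twostate_fit")
}

#' @export
print.twostate_fit <- function(x, ...) {
  cat(sprintf("two-state fit: kON = %.4g 1/h, kOFF = %.4g 1/h (PON(inf) = %.3f)\n",
              x$k_on, x$k_off, x$pon_inf))
  cat(sprintf("  R2 (initially OFF) = %.3f, R2 (initially ON) = %.3f, pooled MSE = %.2g\n",
              x$r2_off, x$r2_on, x$mse))
  invisible(x)
}

#' @export
coef.twostate_fit <- function(object, ...) {
  c(k_on = object$k_on, k_off = object$k_off)
}

#' Robustness of the fitted rates to the ON threshold
#'
#' Redoes the classification and fit for thresholds drawn uniformly from
#' a fraction range of the nominal 200-molecule value (default 25%-175%)
#' and summarizes the spread of the fitted rates.
#'
#' @param ensemble_off,ensemble_on the two \code{ssa_ensemble}s.
#' @param n_draws number of threshold draws.
#' @param range fraction range around the nominal threshold.
#' @param threshold nominal threshold (molecules).
#' @param seed RNG seed for the draws.
#' @return data.frame of draws with columns \code{threshold}, \code{k_on},
#'   \code{k_off}; summary means/sds as attributes.
#' @export
threshold_robustness <- function(ensemble_off, ensemble_on, n_draws = 100,
                                 range = c(0.25, 1.75), threshold = 200,
                                 seed = 1) {
  set.seed(seed)
  thr <- stats::runif(n_draws, range[1] * threshold, range[2] * threshold)
  res <- lapply(thr, function(th) {
    f <- fit_rates(fraction_on(ensemble_off, th),
                   fraction_on(ensemble_on, th))
    c(threshold = th, k_on = f$k_on, k_off = f$k_off)
  })
  out <- as.data.frame(do.call(rbind, res))
  attr(out, "mean") <- colMeans(out[, c("k_on", "k_off")])
  attr(out, "sd") <- apply(out[, c("k_on", "k_off")], 2, stats::sd)
  out
}
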