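#' Time-resolved Spo0A~P input signal
#'
#' A signal is a uniformly sampled, non-negative time series of Spo0A~P
#' level, consumed by both the deterministic biofilm model (units uM) and,
#' after count conversion, by the stochastic model (units molecules).
#'
#' @param times strictly increasing, uniformly spaced time grid (h).
#' @param values Spo0A~P level at each time; non-negative.
#' @param units unit tag, \code{"uM"} or \code{"molecules"}.
#' @return object of class \code{oap_signal}.
#' @export
oap_signal <- function(times, values, units = "uM") {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (length(times) < 2L) stop("a signal needs at least two samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) stop("time grid must be uniform")
  if (any(values < -1e-12)) stop("signal values must be non-negative")
  values[values < 0] <- 0
  structure(list(times = times, values = values, dt = mean(dt), units = units),
            class = "oap_signal")
}

#' @export
print.oap_signal <- function(x, ...) {
  cat(sprintf("Spo0A~P signal: %d samples on [%.3g, %.3g] h (dt = %.4g h, %s)\n",
              length(x$times), x$times[1], x$times[length(x$times)], x$dt,
              x$units))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# linear interpolation closure for ODE right-hand sides; constant beyond ends
signal_fun <- function(signal) {
  stopifnot(inherits(signal, "oap_signal"))
  stats::approxfun(signal$times, signal$values, rule = 2)
}

#' Cosine Spo0A~P oscillation with zero minimum
#'
#' \eqn{[0A\sim P](t) = A \cos(2\pi t / T) + A}: the offset equals the
#' amplitude so the oscillation minimum is 0 and the mean over whole
#' periods equals the amplitude.
#'
#' @param amplitude oscillation amplitude = offset = mean (uM).
#' @param period period T (h).
#' @param duration total signal length (h); must cover at least one period.
#' @param dt sampling step (h); must resolve the period (dt <= T/50).
#' @return an \code{oap_signal}.
#' @export
cosine_signal <- function(amplitude, period, duration, dt = 0.01) {
  if (period <= 0) stop("period must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (duration < period) stop("duration must cover at least one period")
  if (dt > period / 50) stop("dt too coarse to resolve the oscillation; need dt <= T/50")
  times <- seq(0, duration, by = dt)
  oap_signal(times, amplitude * cos(2 * pi * times / period) + amplitude)
}

#' Square-pulse Spo0A~P train with scheduled ON/OFF durations
#'
#' Alternating high/low plateaus starting with ON. The per-cycle ON and OFF
#' durations are given as equal-length vectors, so either phase can grow
#' from cycle to cycle independently of the other.
#'
#' @param high,low plateau levels (uM).
#' @param on_durations,off_durations per-cycle phase lengths (h), equal length.
#' @param dt sampling step (h).
#' @return an \code{oap_signal} whose attribute \code{"cycle_bounds"} holds
#'   the cycle end times.
#' @export
square_signal <- function(high, low, on_durations, off_durations, dt = 0.005) {
  if (length(on_durations) != length(off_durations))
    stop("on_durations and off_durations must have equal length")
  if (any(on_durations <= 0) || any(off_durations <= 0))
    stop("all durations must be positive")
  if (high < 0 || low < 0) stop("levels must be non-negative")
  total <- sum(on_durations) + sum(off_durations)
  times <- seq(0, total, by = dt)
  # phase boundaries: on1, on1+off1, ...
  edges <- cumsum(as.vector(rbind(on_durations, off_durations)))
  phase_idx <- findInterval(times, edges, left.open = TRUE) # 0-based phase count
  values <- ifelse(phase_idx %% 2L == 0L, high, low)
  sig <- oap_signal(times, values)
  attr(sig, "cycle_bounds") <- edges[seq(2, length(edges), by = 2)]
  sig
}

#' Per-cycle constant surrogate of a signal
#'
#' Replaces a signal, within each cell cycle, by a constant equal to the
#' cycle's time-average (the standard comparison input), maximum or
#' minimum. The mean mode preserves each cycle's time integral.
#'
#' @param signal an \code{oap_signal}.
#' @param boundaries cycle end times (h), within the signal support.
#' @param mode one of \code{"mean"}, \code{"max"}, \code{"min"}.
#' @return an \code{oap_signal} on the same grid.
#' @export
per_cycle_constant <- function(signal, boundaries, mode = c("mean", "max", "min")) {
  stopifnot(inherits(signal, "oap_signal"))
  mode <- match.arg(mode)
  bounds <- sort(unique(c(signal$times[1], boundaries,
                          signal$times[length(signal$times)])))
  out <- signal$values
  for (i in seq_len(length(bounds) - 1)) {
    sel <- signal$times >= bounds[i] & signal$times <= bounds[i + 1]
    if (sum(sel) < 2L) stop("empty cycle between boundaries ", bounds[i],
                            " and ", bounds[i + 1])
    seg_t <- signal$times[sel]; seg_v <- signal$values[sel]
    val <- switch(mode,
      # trapezoidal time-average so the per-cycle integral is preserved
      mean = sum(diff(seg_t) * (seg_v[-1] + seg_v[-length(seg_v)]) / 2) /
               (seg_t[length(seg_t)] - seg_t[1]),
      max = max(seg_v),
      min = min(seg_v))
    # half-open cycles [b_i, b_{i+1}) except the last, closed
    sel_assign <- signal$times >= bounds[i] &
      (if (i == length(bounds) - 1) signal$times <= bounds[i + 1]
       else signal$times < bounds[i + 1])
    out[sel_assign] <- val
  }
  oap_signal(signal$times, out, signal$units)
}

#' Natural once-per-cell-cycle Spo0A~P pulse train
#'
#' Runs the deterministic phosphorelay model and returns its Spo0A~P output:
#' the gene-dosage imbalance between terminus-proximal kinA and
#' oriC-proximal spo0F during DNA replication, together with Spo0F's
#' inhibition of KinA, produces one Spo0A~P pulse per cell cycle whose
#' amplitude grows as growth slows.
#'
#' @param g growth rate (1/h); ignored if \code{timing} given.
#' @param n_cycles number of cell cycles to return (after transient removal).
#' @param timing optional \code{cycle_timing} override (for cycle-phase
#'   scenarios where tau_rep/tau_post are set directly).
#' @param params phosphorelay parameters, see \code{\link{phosphorelay_params}}.
#' @param dt output sampling step (h).
#' @param transient_cycles cycles discarded before the trace is exported.
#' @return an \code{oap_signal} with attribute \code{"cycle_bounds"}.
#' @export
natural_pulse_signal <- function(g = NULL, n_cycles = 5, timing = NULL,
                                 params = phosphorelay_params(), dt = 0.005,
                                 transient_cycles = 3) {
  if (is.null(timing)) timing <- timing_from_growth(g)
  sim <- simulate_phosphorelay(params = params, timing = timing,
                               n_cycles = n_cycles + transient_cycles,
                               dt = dt)
  t_all <- sim$time
  start <- transient_cycles * timing$tau_cyc
  keep <- t_all >= start - 1e-9
  sig <- oap_signal(t_all[keep] - start, sim$Ap[keep])
  attr(sig, "cycle_bounds") <- seq_len(n_cycles) * timing$tau_cyc
  sig
}

#' Write / read a signal as two-column CSV (time_h, value)
#' @param signal an \code{oap_signal}.
#' @param path file path.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "oap_signal"))
  utils::write.csv(data.frame(time_h = signal$times, value = signal$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @param units unit tag for the signal read back.
#' @export
read_signal_csv <- function(path, units = "uM") {
  d <- utils::read.csv(path)
  oap_signal(d[[1]], d[[2]], units)
}
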