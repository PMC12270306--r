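#' Hill-type production-initiation rate
#'
#' Transcription-initiation rate of a phosphorelay gene as a function of the
#' Spo0A~P level x, scaled by the cell-size factor F(g):
#' \eqn{v_{pi} = (v_b + v_{max} x^m / (K^m + x^m)) F(g)}. With
#' \code{vmax = 0} the gene is constitutive.
#'
#' @param vb basal rate (uM/h).
#' @param vmax maximal induced rate above basal (uM/h).
#' @param K half-maximal activator level (uM); must be positive.
#' @param m Hill exponent (>= 1).
#' @param x activator (Spo0A~P) level (uM).
#' @param Fg cell-size factor, see \code{\link{size_factor}}.
#' @return rate in uM/h, bounded in [vb*Fg, (vb+vmax)*Fg].
#' @export
hill_production <- function(vb, vmax, K, m, x, Fg = 1) {
  if (any(K <= 0)) stop("K must be positive")
  if (any(c(vb, vmax, m, Fg) < 0) || any(x < 0)) stop("arguments must be >= 0")
  (vb + vmax * x^m / (K^m + x^m)) * Fg
}

#' First-order production delay
#'
#' The realised production rate vpc relaxes toward the initiation rate vpi
#' with time constant 1/kdel, representing the lag between transcription
#' initiation and finished protein.
#'
#' @param vpi target (initiation) rate.
#' @param vpc current realised rate.
#' @param kdel relaxation rate (1/h), positive.
#' @return d(vpc)/dt.
#' @export
delay_update <- function(vpi, vpc, kdel) {
  if (kdel <= 0) stop("kdel must be positive")
  kdel * (vpi - vpc)
}

#' Gene-dosage scaling of a production rate
#' @param vpc realised per-copy production rate.
#' @param n gene copy number (1 or 2 for discrete genes, [1,2] averaged).
#' @return n * vpc.
#' @export
dosage_scaled_rate <- function(vpc, n) n * vpc

#' Default phosphorelay parameter set
#'
#' Rate constants for the KinA -> Spo0F -> Spo0B -> Spo0A phosphotransfer
#' cascade with Rap / Spo0E phosphatases and Spo0F inhibition of KinA.
#' Transcription of spo0F and spo0A is Spo0A~P-activated (positive
#' feedback); kinA, spo0B, rap and spo0E are constitutive. Gene positions
#' p follow the chromosomal arrangement: spo0F oriC-proximal (p = 0),
#' kinA terminus-proximal (p = 1); the remaining loci use approximate
#' map positions. These defaults are the package's own calibration,
#' chosen so the model produces one Spo0A~P pulse per cell cycle with a
#' replication-period trough, a post-replication overshoot, and a pulse
#' amplitude that grows as growth slows.
#'
#' @param ... named overrides of any top-level element.
#' @return a list of class \code{phosphorelay_params}.
#' @export
phosphorelay_params <- function(...) {
  p <- list(
    genes = data.frame(
      name = c("kinA", "spo0F", "spo0B", "spo0A", "rap", "spo0E"),
      p    = c(1.00,   0.00,    0.66,    0.79,    0.05,  0.05),
      vb   = c(0.030,  0.010,   0.030,   0.010,   0.010, 0.002),
      vmax = c(0.000,  0.050,   0.000,   0.120,   0.000, 0.300),
      K    = c(1,      0.5,     1,       0.5,     1,     0.25),
      m    = c(1,      2,       1,       2,       1,     2),
      kdeg = c(0.2,    0.2,     0.2,     0.2,     0.2,   1.5)
    ),
    kdel  = 4,      # 1/h, production delay
    kauto = 8,      # 1/h, KinA autophosphorylation (before Spo0F inhibition)
    Kinh  = 3.5,    # uM, free-Spo0F level halving KinA activity
    hinh  = 2,      # Hill exponent of the Spo0F inhibition of KinA
    ktf   = 400,    # 1/uM/h, KinA~P -> Spo0F transfer
    ktb   = 20,     # 1/uM/h, Spo0F~P -> Spo0B transfer
    kta   = 400,    # 1/uM/h, Spo0B~P -> Spo0A transfer
    kRap  = 6,      # 1/h (with [Rap]: Vmax), Rap dephosphorylation of Spo0F~P
    KmR   = 0.05,   # uM, Michaelis constant of Rap (zero-order regime)
    kE    = 4.5,    # 1/h (with [Spo0E]: Vmax), Spo0E dephosphorylation of Spo0A~P
    KmE   = 0.05,   # uM, Michaelis constant of Spo0E
    kdeg  = 0.2,    # 1/h, protein degradation (dilution g added on top)
    size  = c(a = 3.5, b = -log(2), c = 3.7)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown phosphorelay parameter: ", nm)
    p[[nm]] <- dots[[nm]]
  }
  class(p) <- "phosphorelay_params"
  p
}

.phos_species <- c("KA", "KAp", "F0", "F0p", "B0", "B0p", "A0", "Ap",
                   "Rap", "E0")

# RHS given per-segment gene copy numbers (named vector) and growth rate g
phosphorelay_rhs <- function(t, y, parms) {
  p <- parms$params
  n <- parms$copies
  g <- if (is.null(parms$gfun)) parms$g else parms$gfun(t)
  Fg <- size_factor(g, p$size["a"], p$size["b"], p$size["c"])
  kd <- stats::setNames(p$genes$kdeg, p$genes$name) + g  # per-protein turnover
  y <- pmax(y, 0)
  s <- as.list(y[.phos_species])
  vpc <- y[paste0("vpc_", p$genes$name)]

  Ap <- s$Ap
  vpi <- hill_production(p$genes$vb, p$genes$vmax, p$genes$K, p$genes$m,
                         Ap, Fg)
  prod <- as.numeric(n[p$genes$name]) * vpc   # gene-dosage scaling

  # autophosphorylation with cooperative inhibition of KinA by free Spo0F;
  # the free pool is depleted by phosphotransfer, so rising kinase flux
  # disinhibits KinA (fast positive feedback -> excitable burst)
  r7  <- p$kauto * s$KA * p$Kinh^p$hinh / (p$Kinh^p$hinh + s$F0^p$hinh)
  r8  <- p$ktf * s$KAp * s$F0
  r10 <- p$ktb * s$F0p * s$B0
  r11 <- p$kta * s$B0p * s$A0
  # phosphatases operate near saturation (zero-order regime)
  r12 <- p$kRap * s$Rap * s$F0p / (p$KmR + s$F0p)
  r13 <- p$kE * s$E0 * Ap / (p$KmE + Ap)

  names(prod) <- p$genes$name
  d <- c(
    KA  = prod[["kinA"]] - r7 + r8 - kd[["kinA"]] * s$KA,
    KAp = r7 - r8 - kd[["kinA"]] * s$KAp,
    F0  = prod[["spo0F"]] - r8 + r10 + r12 - kd[["spo0F"]] * s$F0,
    F0p = r8 - r10 - r12 - kd[["spo0F"]] * s$F0p,
    B0  = prod[["spo0B"]] - r10 + r11 - kd[["spo0B"]] * s$B0,
    B0p = r10 - r11 - kd[["spo0B"]] * s$B0p,
    A0  = prod[["spo0A"]] - r11 + r13 - kd[["spo0A"]] * s$A0,
    Ap  = r11 - r13 - kd[["spo0A"]] * Ap,
    Rap = prod[["rap"]] - kd[["rap"]] * s$Rap,
    E0  = prod[["spo0E"]] - kd[["spo0E"]] * s$E0
  )
  dvpc <- delay_update(vpi, vpc, p$kdel)
  list(c(d, dvpc))
}

#' Simulate the deterministic phosphorelay
#'
#' Integrates the phosphorelay ODEs over successive cell cycles. Each
#' gene's copy number steps from 1 to 2 at its replication time
#' (\code{p * tau_rep} into the cycle) and resets to 1 at division; the
#' integration is restarted at every such discontinuity with the state
#' carried across (concentrations are not halved at division — dilution is
#' continuous through the growth-rate term). With a time-varying growth
#' schedule, each cycle's tau_rep is fixed from the growth rate at cycle
#' start and the cycle ends when the integral of g reaches ln 2.
#'
#' @param params a \code{phosphorelay_params} list.
#' @param timing a \code{cycle_timing} (fixed-cycle mode); or NULL with
#'   \code{growth} given.
#' @param growth either a scalar growth rate or a function g(t) (1/h).
#' @param n_cycles number of cell cycles to simulate (fixed-cycle mode).
#' @param t_end end time (h) for schedule mode; cycles are generated until
#'   t_end is passed.
#' @param dt output grid spacing (h).
#' @param state0 optional named initial state; default small positive seed.
#' @return data.frame with columns \code{time}, species concentrations (uM)
#'   and delayed rates; attributes \code{cycle_bounds} and \code{timing}.
#' @export
simulate_phosphorelay <- function(params = phosphorelay_params(),
                                  timing = NULL, growth = NULL,
                                  n_cycles = 8, t_end = NULL, dt = 0.01,
                                  state0 = NULL) {
  if (is.null(timing) && is.null(growth))
    stop("supply timing or growth")
  if (is.null(timing) && is.numeric(growth))
    timing <- timing_from_growth(growth)

  gnames <- params$genes$name
  if (is.null(state0)) {
    state0 <- c(stats::setNames(rep(0.05, length(.phos_species)),
                                .phos_species),
                stats::setNames(rep(0.01, length(gnames)),
                                paste0("vpc_", gnames)))
  }

  schedule_mode <- is.function(growth)
  if (schedule_mode && is.null(t_end))
    stop("t_end required with a growth schedule")

  out <- list(); bounds <- numeric(0)
  state <- state0; t0 <- 0
  cyc <- 0L
  repeat {
    cyc <- cyc + 1L
    if (schedule_mode) {
      g0 <- growth(t0)
      tim <- timing_from_growth(g0, allow_overlap = TRUE)
      # cycle ends when integral of g(t) accumulates ln 2
      f <- function(T) stats::integrate(function(u) vapply(u, growth, 0),
                                        t0, t0 + T)$value - log(2)
      up <- tim$tau_cyc
      while (f(up) < 0) up <- up * 1.5
      tau_cyc <- stats::uniroot(f, c(1e-3, up), tol = 1e-6)$root
      tau_rep <- tim$tau_rep
      g_cyc <- NULL
    } else {
      tau_cyc <- timing$tau_cyc; tau_rep <- timing$tau_rep
      g_cyc <- timing$g
    }
    rep_times <- pmin(params$genes$p * tau_rep, tau_cyc)
    edges <- sort(unique(c(0, rep_times[rep_times > 0 & rep_times < tau_cyc],
                           tau_cyc)))
    for (k in seq_len(length(edges) - 1)) {
      seg0 <- t0 + edges[k]; seg1 <- t0 + edges[k + 1]
      copies <- stats::setNames(ifelse(edges[k] >= rep_times - 1e-12, 2, 1),
                                gnames)
      # record on the global dt lattice; integrate to the exact segment end
      i0 <- ceiling((seg0 - 1e-9) / dt); i1 <- floor((seg1 + 1e-9) / dt)
      lattice <- (i0:i1) * dt
      lattice <- lattice[lattice >= seg0 - 1e-9 & lattice <= seg1 + 1e-9]
      tt <- sort(unique(round(c(seg0, lattice, seg1), 10)))
      parms <- list(params = params, copies = copies,
                    g = g_cyc, gfun = if (schedule_mode) growth else NULL)
      sol <- deSolve::lsoda(y = state, times = tt, func = phosphorelay_rhs,
                            parms = parms, rtol = 1e-8, atol = 1e-10)
      if (attr(sol, "istate")[1] < 0)
        stop("phosphorelay integration failed in cycle ", cyc,
             " segment [", seg0, ", ", seg1, "]")
      state <- pmax(sol[nrow(sol), -1], 0)
      keep <- abs(sol[, "time"] / dt - round(sol[, "time"] / dt)) < 1e-6
      out[[length(out) + 1L]] <- sol[keep, , drop = FALSE]
    }
    t0 <- t0 + tau_cyc
    bounds <- c(bounds, t0)
    done <- if (schedule_mode) t0 >= t_end else cyc >= n_cycles
    if (done) break
  }
  m <- do.call(rbind, out)
  df <- as.data.frame(m)
  names(df)[1] <- "time"
  df$time <- round(df$time / dt) * dt
  df <- df[!duplicated(df$time), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "cycle_bounds") <- bounds
  attr(df, "timing") <- timing
  df
}
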