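#' Default parameters of the biofilm matrix production network
#'
#' The deterministic SinI/SinR/SlrR/TapA model: Spo0A~P induces sinI; the
#' SinI dimer titrates the SinR dimer into an inactive complex; the SinR
#' tetramer represses slrR and tapA; SlrR also sequesters SinR, closing the
#' double-negative (bistable) loop; TapA reports matrix output. Transcription
#' factors out the translation/mRNA-degradation ratio ktran/kdegm explicitly
#' so the stochastic model's separate transcription and translation steps
#' reduce to these rates exactly in the quasi-steady-state mRNA limit.
#' RNA decay is 8.3/h and protein decay 0.2/h (SlrR 0.8/h, and the SinI
#' dimer is also treated as unstable); growth adds a dilution term. The
#' remaining constants are the package's own calibration, placing the
#' bistable region, its ~0.1 uM deactivation threshold at g = 0.2/h, and
#' the growth-rate trends of the switch.
#'
#' @param ... named overrides of any top-level element.
#' @return list of class \code{biofilm_params}.
#' @export
biofilm_params <- function(...) {
  p <- list(
    genes = data.frame(
      name = c("sinI", "sinR", "slrR", "tapA"),
      p    = c(0.83,   0.83,   0.27,   0.89)
    ),
    # transcription (uM/h mRNA-equivalent units, before n*F(g)*ktran/kdegm)
    vi0 = 0.001, vimax = 0.30, Ki = 0.3,   # sinI: Spo0A~P-activated
    vr0 = 0.10,                            # sinR: constitutive
    vl0 = 0.002, vlmax = 0.305, Kl = 0.04, # slrR: SinR-tetramer repressed
    vt0 = 0.001, vtmax = 0.08, Kt = 0.01,  # tapA: SinR-tetramer repressed
    # translation / mRNA decay
    ktran_i = 10, ktran_r = 10, ktran_l = 10, ktran_t = 10,  # 1/h
    kdegm = 8.3,                           # 1/h mRNA decay
    # protein decay (dilution added as g or g0)
    kdegpro = 0.2, kdegL = 0.8, kdegI = 2.0,
    # complex kinetics (1/uM/h forward, 1/h reverse)
    ktet_f = 10, ktet_r = 10,
    kir_f = 200, kir_r = 0.5,
    klr_f = 100, klr_r = 1,
    size = c(a = 3.5, b = -log(2), c = 3.7)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown biofilm parameter: ", nm)
    p[[nm]] <- dots[[nm]]
  }
  class(p) <- "biofilm_params"
  p
}

.biofilm_species <- c("Id", "R", "RT", "IR", "L", "LR", "TapA")

#' Production rate of SinI
#'
#' Michaelis (Hill-1) activation by Spo0A~P times gene dosage, cell size
#' and the translation/mRNA-decay ratio:
#' \eqn{v = (v_{i0} + v_{imax} c/(K_i + c)) \, n F(g) \, k_{tran}/k_{degm}}.
#'
#' @param c0A Spo0A~P concentration (uM).
#' @param n average gene copy number.
#' @param Fg cell size factor.
#' @param params \code{biofilm_params}.
#' @return rate (uM/h).
#' @export
sinI_rate <- function(c0A, n, Fg, params) {
  if (params$Ki <= 0) stop("Ki must be positive")
  if (any(c0A < 0)) stop("c0A must be >= 0")
  (params$vi0 + params$vimax * c0A / (params$Ki + c0A)) * n * Fg *
    params$ktran_i / params$kdegm
}

#' Production rates of SlrR and TapA (SinR-tetramer repressed)
#'
#' Repression form \eqn{(v_0 + v_{max} K/(K + R_T)) n F(g) k_{tran}/k_{degm}}:
#' maximal when no SinR tetramer is present, basal under full repression.
#'
#' @param RT SinR tetramer concentration (uM).
#' @inheritParams sinI_rate
#' @export
slrR_rate <- function(RT, n, Fg, params) {
  if (params$Kl <= 0) stop("Kl must be positive")
  if (any(RT < 0)) stop("RT must be >= 0")
  (params$vl0 + params$vlmax * params$Kl / (params$Kl + RT)) * n * Fg *
    params$ktran_l / params$kdegm
}

#' @rdname slrR_rate
#' @export
tapA_rate <- function(RT, n, Fg, params) {
  if (params$Kt <= 0) stop("Kt must be positive")
  if (any(RT < 0)) stop("RT must be >= 0")
  (params$vt0 + params$vtmax * params$Kt / (params$Kt + RT)) * n * Fg *
    params$ktran_t / params$kdegm
}

#' Effective protein removal rate
#'
#' Degradation plus dilution by growth: \code{kdegpro + g}. With
#' \code{fixed_g0} the dilution term is pinned at \code{g0} regardless of
#' the actual growth rate (used to switch off the growth effect on
#' protein dilution).
#'
#' @param kdegpro protein degradation rate (1/h).
#' @param g growth rate (1/h).
#' @param fixed_g0 if TRUE use \code{g0} instead of \code{g}.
#' @param g0 reference growth rate (1/h).
#' @export
effective_degradation <- function(kdegpro, g, fixed_g0 = FALSE, g0 = 0.2) {
  if (kdegpro < 0 || any(g < 0)) stop("rates must be >= 0")
  kdegpro + if (fixed_g0) g0 else g
}

#' Growth-effect switches for the biofilm models
#'
#' Controls which growth-rate couplings act on the matrix network:
#' \code{dilution = "fixed"} pins the dilution term at \code{g0}
#' (default 0.2/h); \code{dosage = "frozen"} evaluates gene copy numbers
#' at the reference cycle (tau_rep 1.53 h, tau_cyc 3.47 h).
#'
#' @param dilution \code{"growth"} (live g) or \code{"fixed"} (g0).
#' @param dosage \code{"live"} or \code{"frozen"}.
#' @param g0 reference growth rate (1/h).
#' @param frozen_timing optional \code{cycle_timing} for the frozen dosage.
#' @return list of switches consumed by the simulators.
#' @export
biofilm_effects <- function(dilution = c("growth", "fixed"),
                            dosage = c("live", "frozen"), g0 = 0.2,
                            frozen_timing = NULL) {
  list(dilution = match.arg(dilution), dosage = match.arg(dosage), g0 = g0,
       frozen_timing = if (is.null(frozen_timing)) timing_from_growth(0.2)
                       else frozen_timing)
}

biofilm_rhs <- function(t, y, parms) {
  p <- parms$params
  eff <- parms$effects
  c0A <- parms$input(t)
  g <- if (is.function(parms$g)) parms$g(t) else parms$g
  Fg <- size_factor(g, p$size["a"], p$size["b"], p$size["c"])
  tim <- if (eff$dosage == "frozen") eff$frozen_timing
         else timing_from_growth(g, allow_overlap = TRUE)
  n <- 2^(1 - min(tim$tau_rep / tim$tau_cyc, 1) * p$genes$p)
  names(n) <- p$genes$name

  keff <- effective_degradation(p$kdegpro, g, eff$dilution == "fixed", eff$g0)
  keffL <- effective_degradation(p$kdegL, g, eff$dilution == "fixed", eff$g0)
  keffI <- effective_degradation(p$kdegI, g, eff$dilution == "fixed", eff$g0)

  y <- pmax(y, 0)
  Id <- y[["Id"]]; R <- y[["R"]]; RT <- y[["RT"]]; IR <- y[["IR"]]
  L <- y[["L"]]; LR <- y[["LR"]]; TapA <- y[["TapA"]]

  vI <- sinI_rate(c0A, n[["sinI"]], Fg, p)
  vR <- p$vr0 * n[["sinR"]] * Fg * p$ktran_r / p$kdegm
  vL <- slrR_rate(RT, n[["slrR"]], Fg, p)
  vT <- tapA_rate(RT, n[["tapA"]], Fg, p)

  f_tet <- p$ktet_f * R^2 - p$ktet_r * RT
  f_ir  <- p$kir_f * Id * R - p$kir_r * IR
  f_lr  <- p$klr_f * L * R - p$klr_r * LR

  # the unstable partners (SinI, SlrR) are degraded inside their SinR
  # complexes at their own rates, releasing the stable SinR dimer; the
  # whole complex is additionally removed by dilution/basal decay
  rel_ir <- p$kdegI * IR
  rel_lr <- p$kdegL * LR

  list(c(
    Id   = vI - f_ir - keffI * Id,
    R    = vR - 2 * f_tet - f_ir - f_lr + rel_ir + rel_lr - keff * R,
    RT   = f_tet - keff * RT,
    IR   = f_ir - rel_ir - keff * IR,
    L    = vL - f_lr - keffL * L,
    LR   = f_lr - rel_lr - keff * LR,
    TapA = vT - keff * TapA
  ))
}

#' Simulate the biofilm matrix production network
#'
#' Stiff integration of the SinI/SinR/SlrR/TapA ODEs under a Spo0A~P input
#' (a \code{\link{oap_signal}}, a constant, or a function of time).
#'
#' @param params \code{biofilm_params}.
#' @param input Spo0A~P input: \code{oap_signal}, single number, or function.
#' @param g growth rate (1/h), scalar or function of time.
#' @param duration simulated time (h).
#' @param state0 named initial state (uM); defaults to all zero (OFF).
#' @param effects growth-effect switches, see Details; a list from
#'   \code{biofilm_effects()}.
#' @param dt output grid step (h).
#' @details The \code{effects} list controls which growth-rate couplings
#'   are active: \code{dilution = "fixed"} replaces the dilution term g by
#'   the reference g0 (default 0.2/h); \code{dosage = "frozen"} evaluates
#'   the average gene copy number at the reference cycle
#'   (tau_rep = 1.53 h, tau_cyc = 3.47 h) regardless of g.
#' @return data.frame \code{time} + species (uM).
#' @export
simulate_biofilm <- function(params = biofilm_params(), input, g,
                             duration, state0 = NULL,
                             effects = biofilm_effects(), dt = 0.01,
                             rtol = 1e-8, atol = 1e-10) {
  if (duration < 0) stop("duration must be >= 0")
  input_fun <- if (inherits(input, "oap_signal")) signal_fun(input)
               else if (is.function(input)) input
               else { cc <- input; function(t) rep(cc, length(t)) }
  if (is.null(state0))
    state0 <- stats::setNames(rep(0, length(.biofilm_species)),
                              .biofilm_species)
  state0 <- state0[.biofilm_species]
  if (duration == 0)
    return(data.frame(time = 0, as.list(state0)))
  times <- seq(0, duration, by = dt)
  parms <- list(params = params, input = input_fun, g = g, effects = effects)
  sol <- deSolve::lsoda(y = state0, times = times, func = biofilm_rhs,
                        parms = parms, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("biofilm integration failed")
  df <- as.data.frame(sol)
  names(df)[1] <- "time"
  df
}

# integrate under constant input until near-steady; returns final state
biofilm_steady <- function(params, c0A, g, state0,
                           effects = biofilm_effects(),
                           block = 100, max_time = 400, tol = 1e-6) {
  t_done <- 0; state <- state0
  repeat {
    sim <- simulate_biofilm(params, c0A, g, block, state, effects, dt = 0.5)
    state <- unlist(sim[nrow(sim), .biofilm_species])
    t_done <- t_done + block
    d <- unlist(biofilm_rhs(0, state, list(params = params,
           input = function(t) c0A, g = g, effects = effects))[[1]])
    if (max(abs(d) / (abs(state) + 1e-9)) < tol) break
    if (t_done >= max_time) break
    block <- 50
  }
  state
}

#' ON/OFF classification reference for the matrix switch
#'
#' Computes the two stable TapA branch levels at a reference condition
#' (growth rate and constant Spo0A~P level inside the bistable range) and
#' returns their geometric mean as the ON/OFF midpoint, together with the
#' branch states. A trajectory end state is classified ON when its TapA
#' exceeds the midpoint.
#'
#' @param params \code{biofilm_params}.
#' @param g reference growth rate (1/h).
#' @param c0A reference constant Spo0A~P level (uM).
#' @param effects growth-effect switches.
#' @return list with \code{midpoint}, \code{tapA_on}, \code{tapA_off},
#'   \code{state_on}, \code{state_off}.
#' @export
matrix_reference <- function(params = biofilm_params(), g = 0.2, c0A = 0.2,
                             effects = biofilm_effects()) {
  s_off <- biofilm_steady(params, c0A, g, .matrix_off_init(), effects)
  s_on <- biofilm_steady(params, c0A, g, .matrix_on_init(), effects)
  if (s_on[["TapA"]] < 2 * s_off[["TapA"]])
    warning("reference condition does not look bistable; midpoint degenerate")
  list(midpoint = sqrt(max(s_on[["TapA"]], 1e-12) *
                       max(s_off[["TapA"]], 1e-12)),
       tapA_on = s_on[["TapA"]], tapA_off = s_off[["TapA"]],
       state_on = s_on, state_off = s_off)
}

#' Minimum cell-cycle length deactivating matrix production
#'
#' Starting from the matrix-ON state at the reference cycle (growth rate
#' 0.2/h: tau_rep 1.53 h, tau_post 1.94 h), the cycle length is increased
#' in 0.1 h steps. At each candidate the Spo0A~P input is regenerated from
#' the phosphorelay model, the network is integrated to its long-run
#' attractor (at least 100 h), and the end state is classified against the
#' ON/OFF midpoint. Returns the first cycle length classified OFF.
#'
#' @param params \code{biofilm_params}.
#' @param phos_params \code{phosphorelay_params} used for the input.
#' @param scenario how the cycle lengthens: \code{"growth"} follows the
#'   growth-rate family (tau_rep from the replication-period law),
#'   \code{"replication"} grows tau_rep at fixed tau_post,
#'   \code{"post"} grows tau_post at fixed tau_rep.
#' @param input \code{"pulsing"} for the natural pulse, or
#'   \code{"constant"} for its per-cycle mean.
#' @param effects growth-effect switches (dilution/dosage).
#' @param tau_start,tau_ceiling search range of cycle length (h).
#' @param step grid step (h).
#' @param horizon minimum integration time per candidate (h).
#' @param reference optional precomputed \code{matrix_reference()}.
#' @return list of class \code{deactivation_search}: \code{tau_deact}
#'   (NA if none up to the ceiling), \code{tested} data.frame with
#'   per-candidate TapA and classification, \code{midpoint}.
#' @export
find_deactivation_cycle <- function(params = biofilm_params(),
                                    phos_params = phosphorelay_params(),
                                    scenario = c("growth", "replication", "post"),
                                    input = c("pulsing", "constant"),
                                    effects = biofilm_effects(),
                                    tau_start = NULL, tau_ceiling = 20,
                                    step = 0.1, horizon = 120,
                                    reference = NULL) {
  scenario <- match.arg(scenario); input <- match.arg(input)
  base <- timing_from_growth(0.2)
  if (is.null(tau_start)) tau_start <- base$tau_cyc
  if (is.null(reference)) reference <- matrix_reference(params, effects = effects)

  taus <- seq(tau_start, tau_ceiling, by = step)
  state <- reference$state_on
  rows <- list(); tau_deact <- NA_real_
  for (tau in taus) {
    tim <- switch(scenario,
      growth = timing_from_growth(log(2) / tau),
      replication = timing_from_growth(tau_rep = tau - base$tau_post,
                                       tau_post = base$tau_post),
      post = timing_from_growth(tau_rep = base$tau_rep,
                                tau_post = tau - base$tau_rep))
    sig <- natural_pulse_cycle(phos_params, tim, dt = 0.01)
    if (input == "constant") {
      cyc_mean <- mean_of_cycle(sig)
      in_fun <- function(t) rep(cyc_mean, length(t))
    } else {
      in_fun <- tile_signal_fun(sig, tim$tau_cyc)
    }
    n_cyc <- ceiling(horizon / tim$tau_cyc)
    # classification only needs moderate accuracy; looser tolerances keep
    # the grid search fast
    sim <- simulate_biofilm(params, in_fun, tim$g, n_cyc * tim$tau_cyc,
                            state, effects, dt = 0.05,
                            rtol = 1e-6, atol = 1e-9)
    # mean TapA over the final full cycle
    t_end <- sim$time[nrow(sim)]
    lastc <- sim$time >= t_end - tim$tau_cyc - 1e-9
    tapA <- mean(sim$TapA[lastc])
    on <- tapA >= reference$midpoint
    rows[[length(rows) + 1L]] <- data.frame(tau_cyc = tau, g = tim$g,
                                            tau_rep = tim$tau_rep,
                                            tapA = tapA, on = on)
    if (!on) { tau_deact <- tau; break }
    # warm start the next candidate from the current attractor
    state <- unlist(sim[nrow(sim), .biofilm_species])
  }
  structure(list(tau_deact = tau_deact, tested = do.call(rbind, rows),
                 midpoint = reference$midpoint, scenario = scenario,
                 input = input),
            class = "deactivation_search")
}

#' @export
print.deactivation_search <- function(x, ...) {
  cat(sprintf("deactivation-cycle search (%s scenario, %s input): ",
              x$scenario, x$input))
  if (is.na(x$tau_deact)) cat("no deactivation found\n")
  else cat(sprintf("matrix deactivates at tau_cyc = %.2f h\n", x$tau_deact))
  invisible(x)
}

#' One post-transient cycle of the natural Spo0A~P pulse
#'
#' Simulates the phosphorelay at fixed timing and extracts the last full
#' cycle as a signal starting at the cycle boundary (used to tile periodic
#' inputs for long biofilm runs).
#'
#' @param phos_params phosphorelay parameters.
#' @param timing a \code{cycle_timing}.
#' @param dt sampling step (h).
#' @param transient_cycles cycles discarded before extraction.
#' @return an \code{oap_signal} covering one cycle.
#' @export
natural_pulse_cycle <- function(phos_params, timing, dt = 0.005,
                                transient_cycles = 5) {
  sim <- simulate_phosphorelay(phos_params, timing = timing,
                               n_cycles = transient_cycles + 1, dt = dt)
  tb <- attr(sim, "cycle_bounds")
  keep <- sim$time >= tb[transient_cycles] - 1e-9
  oap_signal(sim$time[keep] - sim$time[keep][1], sim$Ap[keep])
}

#' Trapezoidal time-average of a signal
#' @param sig an \code{oap_signal}.
#' @return the time-averaged value.
#' @export
mean_of_cycle <- function(sig) {
  tt <- sig$times; vv <- sig$values
  sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2) / (tt[length(tt)] - tt[1])
}

#' Periodic extension of a one-cycle signal
#' @param sig an \code{oap_signal} covering one cycle.
#' @param period the cycle length (h).
#' @return a function of time returning the tiled signal.
#' @export
tile_signal_fun <- function(sig, period) {
  f <- signal_fun(sig)
  function(t) f(t %% period)
}
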