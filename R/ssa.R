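#' Generic mass-action Gillespie simulation
#'
#' Exact direct-method SSA over an arbitrary integer-stoichiometry
#' network. One reaction may be modulated by a piecewise-constant external
#' input (its rate is multiplied by the input level, refreshed on the
#' input grid; the algorithm is exact within refresh intervals).
#'
#' @param reactants,products reaction x species stoichiometry matrices.
#' @param rates per-reaction rate constants on the count scale (1/h).
#' @param x0 integer initial counts.
#' @param record_times increasing times (h) at which to record the state.
#' @param input optional \code{oap_signal} modulating one reaction.
#' @param input_reaction index of the modulated reaction (0 = none).
#' @param seed optional integer seed (applied via \code{set.seed}).
#' @return matrix \code{length(record_times)} x n_species of counts.
#' @export
ssa_simulate <- function(reactants, products, rates, x0, record_times,
                         input = NULL, input_reaction = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(input)) {
    it <- c(0, max(record_times) + 1); iv <- c(1, 1)
  } else {
    it <- input$times; iv <- input$values
  }
  out <- ssa_run_cpp(as.matrix(reactants), as.matrix(products),
                     as.numeric(rates), as.integer(input_reaction),
                     as.numeric(it), as.numeric(iv),
                     as.numeric(record_times), as.integer(x0))
  colnames(out) <- colnames(reactants)
  out
}

.ssa_species <- c("PIf", "PIo", "PIl", "PLf", "PLo", "PTf", "PTo",
                  "mI", "mR", "mL", "mT",
                  "Id", "R", "RT", "IR", "L", "LR", "TapA")

#' Build the stochastic biofilm matrix model
#'
#' Translates the deterministic network into integer-count reactions with
#' explicit promoter states: Spo0A~P binding/unbinding at the sinI
#' promoter (binding propensity proportional to the current input level)
#' and SinR-tetramer binding/unbinding at the slrR and tapA promoters;
#' per-gene transcription and translation (SinI is translated as its
#' dimer); complex formation/dissociation and partner degradation inside
#' complexes; first-order removal of every species (degradation plus
#' dilution at the fixed growth rate). Rates reduce exactly to the
#' deterministic model under quasi-steady-state mRNA and fast promoter
#' equilibration. Optionally the sinI promoter can enter a transcriptionally
#' dead 'locked' state (three extra reactions) emulating supercoiling-type
#' noise.
#'
#' @param params \code{biofilm_params}.
#' @param g fixed growth rate (1/h).
#' @param omega molecules per uM (count conversion).
#' @param burst translation burst size (protein per mRNA lifetime), one
#'   value or per-gene vector (sinI, sinR, slrR, tapA).
#' @param k_unbind promoter unbinding rates (1/h): 0A~P at sinI and RT at
#'   slrR/tapA; equilibrium constants come from Ki, Kl, Kt.
#' @param locked enable the locked-promoter extension.
#' @param k_lock,k_unlock locked-state entry/exit rates (1/h).
#' @param effects growth-effect switches (as in the deterministic model).
#' @return list of class \code{ssa_model}: stoichiometry, rates, species,
#'   index of the input-modulated reaction, and bookkeeping.
#' @export
biofilm_ssa_model <- function(params = biofilm_params(), g = 0.4,
                              omega = 600, burst = 10, k_unbind = 5,
                              locked = FALSE, k_lock = 1, k_unlock = 1,
                              effects = biofilm_effects()) {
  p <- params
  burst <- rep(burst, length.out = 4)
  Fg <- size_factor(g, p$size["a"], p$size["b"], p$size["c"])
  tim <- if (effects$dosage == "frozen") effects$frozen_timing
         else timing_from_growth(g, allow_overlap = TRUE)
  n <- 2^(1 - min(tim$tau_rep / tim$tau_cyc, 1) * p$genes$p)
  names(n) <- p$genes$name
  keff <- effective_degradation(p$kdegpro, g, effects$dilution == "fixed",
                                effects$g0)
  keffL <- effective_degradation(p$kdegL, g, effects$dilution == "fixed",
                                 effects$g0)
  keffI <- effective_degradation(p$kdegI, g, effects$dilution == "fixed",
                                 effects$g0)

  ktl <- burst * p$kdegm                      # translation rates (1/h)
  # transcription rates (mRNA/h) reproducing the deterministic fluxes
  tr_suffix <- c(sinI = "i", sinR = "r", slrR = "l", tapA = "t")
  q <- function(v, gene, b) v * n[[gene]] * Fg *
    p[[paste0("ktran_", tr_suffix[[gene]])]] * omega / (b * p$kdegm)
  qI0 <- q(p$vi0, "sinI", burst[1]);  qI1 <- q(p$vimax + p$vi0, "sinI", burst[1])
  qR  <- q(p$vr0, "sinR", burst[2])
  qL1 <- q(p$vlmax + p$vl0, "slrR", burst[3]); qL0 <- q(p$vl0, "slrR", burst[3])
  qT1 <- q(p$vtmax + p$vt0, "tapA", burst[4]); qT0 <- q(p$vt0, "tapA", burst[4])

  S <- .ssa_species
  rx <- list(); rates <- numeric(0)
  add <- function(from, to, rate, name) {
    r <- stats::setNames(integer(length(S)), S)
    pr <- r
    for (s in names(from)) r[s] <- from[[s]]
    for (s in names(to)) pr[s] <- to[[s]]
    rx[[length(rx) + 1L]] <<- list(r = r, p = pr, name = name)
    rates <<- c(rates, rate)
  }
  # promoter switching (R1-R3); sinI binding is input-modulated (uM^-1 h^-1)
  add(c(PIf = 1), c(PIo = 1), k_unbind / p$Ki, "bind_sinI")
  add(c(PIo = 1), c(PIf = 1), k_unbind, "unbind_sinI")
  add(c(PLf = 1, RT = 1), c(PLo = 1), k_unbind / (p$Kl * omega), "bind_slrR")
  add(c(PLo = 1), c(PLf = 1, RT = 1), k_unbind, "unbind_slrR")
  add(c(PTf = 1, RT = 1), c(PTo = 1), k_unbind / (p$Kt * omega), "bind_tapA")
  add(c(PTo = 1), c(PTf = 1, RT = 1), k_unbind, "unbind_tapA")
  # transcription (R4-R7)
  add(c(PIo = 1), c(PIo = 1, mI = 1), qI1, "tx_sinI_act")
  add(c(PIf = 1), c(PIf = 1, mI = 1), qI0, "tx_sinI_bas")
  add(c(), c(mR = 1), qR, "tx_sinR")
  add(c(PLf = 1), c(PLf = 1, mL = 1), qL1, "tx_slrR_free")
  add(c(PLo = 1), c(PLo = 1, mL = 1), qL0, "tx_slrR_rep")
  add(c(PTf = 1), c(PTf = 1, mT = 1), qT1, "tx_tapA_free")
  add(c(PTo = 1), c(PTo = 1, mT = 1), qT0, "tx_tapA_rep")
  # translation (R8-R11); SinI emerges as dimer
  add(c(mI = 1), c(mI = 1, Id = 1), ktl[1], "tl_sinI")
  add(c(mR = 1), c(mR = 1, R = 1), ktl[2], "tl_sinR")
  add(c(mL = 1), c(mL = 1, L = 1), ktl[3], "tl_slrR")
  add(c(mT = 1), c(mT = 1, TapA = 1), ktl[4], "tl_tapA")
  # mRNA decay
  for (m in c("mI", "mR", "mL", "mT"))
    add(stats::setNames(1, m), c(), p$kdegm, paste0("deg_", m))
  # complexes
  add(c(R = 2), c(RT = 1), 2 * p$ktet_f / omega, "tetramerize")
  add(c(RT = 1), c(R = 2), p$ktet_r, "untetramerize")
  add(c(Id = 1, R = 1), c(IR = 1), p$kir_f / omega, "form_IR")
  add(c(IR = 1), c(Id = 1, R = 1), p$kir_r, "dissoc_IR")
  add(c(L = 1, R = 1), c(LR = 1), p$klr_f / omega, "form_LR")
  add(c(LR = 1), c(L = 1, R = 1), p$klr_r, "dissoc_LR")
  # partner degradation inside complexes releases the stable SinR dimer
  add(c(IR = 1), c(R = 1), p$kdegI, "degI_in_IR")
  add(c(LR = 1), c(R = 1), p$kdegL, "degL_in_LR")
  # protein removal (degradation + dilution)
  add(c(Id = 1), c(), keffI, "deg_Id")
  add(c(R = 1), c(), keff, "deg_R")
  add(c(RT = 1), c(), keff, "deg_RT")
  add(c(IR = 1), c(), keff, "deg_IR")
  add(c(L = 1), c(), keffL, "deg_L")
  add(c(LR = 1), c(), keff, "deg_LR")
  add(c(TapA = 1), c(), keff, "deg_TapA")
  if (locked) {
    add(c(PIf = 1), c(PIl = 1), k_lock, "lock_sinI")
    add(c(PIl = 1), c(PIf = 1), k_unlock, "unlock_sinI")
    add(c(PIo = 1), c(PIl = 1), k_lock, "lock_sinI_occ")
  }

  reactants <- do.call(rbind, lapply(rx, `[[`, "r"))
  products <- do.call(rbind, lapply(rx, `[[`, "p"))
  rownames(reactants) <- rownames(products) <- vapply(rx, `[[`, "", "name")
  colnames(reactants) <- colnames(products) <- S
  x0 <- stats::setNames(integer(length(S)), S)
  x0[c("PIf", "PLf", "PTf")] <- 1L
  # start in a SinR-dominated (matrix-OFF) configuration: from an empty
  # cell the derepressed slrR promoter would win the race to ON even
  # without input, which is not a physiological initial condition
  x0[["R"]] <- as.integer(round(0.4 * omega))
  x0[["RT"]] <- as.integer(round(0.25 * omega))
  structure(list(reactants = reactants, products = products, rates = rates,
                 species = S, input_reaction = 1L, x0 = x0,
                 omega = omega, g = g, params = params, locked = locked),
            class = "ssa_model")
}

#' @export
print.ssa_model <- function(x, ...) {
  cat(sprintf("stochastic biofilm model: %d reactions, %d species, g = %g/h, omega = %g%s\n",
              nrow(x$reactants), length(x$species), x$g, x$omega,
              if (x$locked) ", locked-promoter extension" else ""))
  invisible(x)
}

# convert a uM signal to the SSA propensity grid (kept in uM: the binding
# rate constant is per uM)
ssa_input <- function(input, duration, dt = 0.005) {
  if (inherits(input, "oap_signal")) {
    f <- signal_fun(input)
    tt <- seq(0, duration, by = dt)
    oap_signal(tt, f(tt))
  } else if (is.function(input)) {
    tt <- seq(0, duration, by = dt)
    oap_signal(tt, input(tt))
  } else {
    oap_signal(c(0, duration), rep(input, 2))
  }
}

#' Simulate one cell of the stochastic biofilm model
#'
#' @param model an \code{ssa_model}.
#' @param input Spo0A~P input (uM): \code{oap_signal}, constant, or function.
#' @param duration simulated time (h).
#' @param seed integer seed.
#' @param x0 optional initial counts (default the model's).
#' @param dt_record recording grid (h).
#' @return data.frame \code{time} + species counts.
#' @export
gillespie_simulate <- function(model, input, duration, seed = NULL,
                               x0 = NULL, dt_record = 0.1) {
  stopifnot(inherits(model, "ssa_model"))
  if (is.null(x0)) x0 <- model$x0
  sig <- ssa_input(input, duration)
  rec <- seq(0, duration, by = dt_record)
  m <- ssa_simulate(model$reactants, model$products, model$rates, x0, rec,
                    input = sig, input_reaction = model$input_reaction,
                    seed = seed)
  data.frame(time = rec, m)
}

#' Burn-in to a stationary single-cell state
#'
#' Runs the model for \code{duration} hours (default 60) under the given
#' input and returns the final state, used to initialize ensemble members
#' in a macro-state consistent with that input (zero input settles OFF,
#' a high constant settles ON).
#'
#' @inheritParams gillespie_simulate
#' @return named integer vector of counts.
#' @export
ssa_burn_in <- function(model, input, duration = 60, seed = NULL) {
  sim <- gillespie_simulate(model, input, duration, seed = seed,
                            dt_record = duration / 4)
  unlist(sim[nrow(sim), model$species])
}

#' Ensemble of stochastic biofilm simulations
#'
#' Simulates \code{n_cells} independent cells under a common input for
#' \code{duration} hours. Each cell is initialized from its own burn-in
#' (seeded \code{seed_base + index}) under a constant input chosen by the
#' requested initial macro-state: 0 uM for initially-OFF cells, or
#' \code{c_on} uM for initially-ON cells.
#'
#' @param model \code{ssa_model}.
#' @param input the common Spo0A~P input for the recorded phase.
#' @param n_cells ensemble size.
#' @param duration recorded simulation length (h).
#' @param initial \code{"off"} or \code{"on"} starting macro-state.
#' @param seed_base base seed; cell i uses \code{seed_base + i}.
#' @param c_on burn-in input for the ON macro-state (uM).
#' @param burn_duration burn-in length (h).
#' @param dt_record recording grid (h).
#' @return object of class \code{ssa_ensemble}: \code{times}, matrix
#'   \code{tapA} (cells x times), \code{initial}, \code{seeds}.
#' @export
run_ensemble <- function(model, input, n_cells, duration = 40,
                         initial = c("off", "on"), seed_base = 1,
                         c_on = 0.5, burn_duration = 60, dt_record = 0.1) {
  initial <- match.arg(initial)
  rec <- seq(0, duration, by = dt_record)
  tapA <- matrix(NA_integer_, n_cells, length(rec))
  seeds <- seed_base + seq_len(n_cells)
  burn_c <- if (initial == "off") 0 else c_on
  for (i in seq_len(n_cells)) {
    st <- ssa_burn_in(model, burn_c, burn_duration, seed = seeds[i])
    sim <- gillespie_simulate(model, input, duration, seed = NULL,
                              x0 = st, dt_record = dt_record)
    tapA[i, ] <- sim$TapA
  }
  structure(list(times = rec, tapA = tapA, initial = initial, seeds = seeds,
                 n_cells = n_cells),
            class = "ssa_ensemble")
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  cat(sprintf("ssa_ensemble: %d cells (initially %s), %d time points on [0, %g] h\n",
              x$n_cells, toupper(x$initial), length(x$times),
              max(x$times)))
  invisible(x)
}

#' Ensemble with stochastic cell-cycle dynamics
#'
#' Each cell runs cycle by cycle: at each cycle start the cycle length is
#' drawn from a truncated normal around ln2/g (coefficient of variation
#' \code{cv}), the cycle's Spo0A~P input is the phosphorelay pulse for the
#' implied growth rate (looked up from a precomputed library), and at
#' division every molecular count is partitioned Binomial(n, 1/2), with one
#' daughter carried on. Promoters are reset to free with bound regulators
#' returned to the pool.
#'
#' @param model \code{ssa_model}.
#' @param phos_params phosphorelay parameters for the input library.
#' @param n_cells number of cells.
#' @param duration total time per cell (h).
#' @param g mean growth rate (1/h).
#' @param cv coefficient of variation of the cycle length.
#' @param initial starting macro-state, as in \code{\link{run_ensemble}}.
#' @param seed_base base seed.
#' @param pulse_scale multiplies the input signal (uM), default 1.
#' @param dt_record recording grid (h).
#' @param n_lib size of the precomputed pulse library across the cycle
#'   length range (+- 3 sd).
#' @return an \code{ssa_ensemble}.
#' @export
stochastic_cycle_ensemble <- function(model, phos_params = phosphorelay_params(),
                                      n_cells, duration = 40, g = 0.4,
                                      cv = 0.1, initial = c("off", "on"),
                                      seed_base = 1, pulse_scale = 1,
                                      dt_record = 0.1, n_lib = 13) {
  initial <- match.arg(initial)
  tau_mean <- log(2) / g
  # pulse library over the plausible cycle-length range
  tau_grid <- seq(tau_mean * max(1 - 3.5 * cv, 0.3), tau_mean * (1 + 3.5 * cv),
                  length.out = n_lib)
  lib <- lapply(tau_grid, function(tau)
    natural_pulse_cycle(phos_params, timing_from_growth(log(2) / tau)))

  rec <- seq(0, duration, by = dt_record)
  tapA <- matrix(NA_integer_, n_cells, length(rec))
  seeds <- seed_base + seq_len(n_cells)
  burn_c <- if (initial == "off") 0 else 0.5
  promoter_species <- c("PIf", "PIo", "PIl", "PLf", "PLo", "PTf", "PTo")
  for (i in seq_len(n_cells)) {
    set.seed(seeds[i])
    st <- ssa_burn_in(model, burn_c, 60, seed = NULL)
    t_now <- 0; trace <- numeric(0); tt <- numeric(0)
    while (t_now < duration) {
      tau <- max(0.2 * tau_mean,
                 stats::rnorm(1, tau_mean, cv * tau_mean))
      k <- which.min(abs(tau_grid - tau))
      sig <- lib[[k]]
      cyc_len <- min(tau, duration - t_now)
      seg <- gillespie_simulate(model, oap_signal(sig$times * (tau / max(sig$times)),
                                                  sig$values * pulse_scale),
                                cyc_len, seed = NULL, x0 = st,
                                dt_record = dt_record)
      tt <- c(tt, t_now + seg$time[-1])
      trace <- c(trace, seg$TapA[-1])
      st <- unlist(seg[nrow(seg), model$species])
      # division: release promoter-bound regulators, reset promoters,
      # then binomial partition of every molecular species
      st[["RT"]] <- st[["RT"]] + st[["PLo"]] + st[["PTo"]]
      st[promoter_species] <- 0L
      st[c("PIf", "PLf", "PTf")] <- 1L
      mol <- setdiff(model$species, promoter_species)
      st[mol] <- stats::rbinom(length(mol), st[mol], 0.5)
      t_now <- t_now + cyc_len
    }
    tapA[i, ] <- stats::approx(c(0, tt), c(trace[1], trace), xout = rec,
                               method = "constant", rule = 2)$y
  }
  structure(list(times = rec, tapA = tapA, initial = initial, seeds = seeds,
                 n_cells = n_cells),
            class = "ssa_ensemble")
}
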