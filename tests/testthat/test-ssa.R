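# small helper networks for the generic SSA engine
birth_death <- function() {
  re <- matrix(c(0, 1), 2, 1, dimnames = list(c("birth", "death"), "X"))
  pr <- matrix(c(1, 0), 2, 1, dimnames = list(c("birth", "death"), "X"))
  list(re = re, pr = pr)
}

test_that("zero propensities freeze the state", {
  bd <- birth_death()
  m <- ssa_simulate(bd$re, bd$pr, rates = c(0, 0), x0 = 7,
                    record_times = 0:10, seed = 1)
  expect_true(all(m[, 1] == 7))
})

test_that("birth-death stationary law is Poisson (mean = variance = k/gamma)", {
  bd <- birth_death()
  k <- 50; gam <- 2
  m <- ssa_simulate(bd$re, bd$pr, c(k, gam), x0 = 25,
                    record_times = seq(0, 4000, by = 0.4), seed = 11)
  x <- m[-(1:250), 1]
  n_eff <- length(x) / 5          # autocorrelation-adjusted sample size
  se <- sqrt(k / gam / n_eff)
  expect_lt(abs(mean(x) - k / gam), 3 * se)
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)   # Fano factor 1
})

test_that("telegraph-gene stationary mRNA mean matches the closed form", {
  sp <- c("G0", "G1", "M")
  re <- rbind(on = c(1, 0, 0), off = c(0, 1, 0), tx = c(0, 1, 0),
              dg = c(0, 0, 1))
  pr <- rbind(on = c(0, 1, 0), off = c(1, 0, 0), tx = c(0, 1, 1),
              dg = c(0, 0, 0))
  colnames(re) <- colnames(pr) <- sp
  kon <- 1; koff <- 3; ktx <- 40; gam <- 2
  m <- ssa_simulate(re, pr, c(kon, koff, ktx, gam), c(1, 0, 0),
                    seq(0, 6000, by = 0.5), seed = 5)
  x <- m[-(1:400), "M"]
  expected <- ktx * kon / ((kon + koff) * gam)
  se <- sd(x) / sqrt(length(x) / 10)
  expect_lt(abs(mean(x) - expected), 3 * se)
  # promoter occupancy matches kon/(kon+koff)
  occ <- mean(m[-(1:400), "G1"])
  expect_equal(occ, kon / (kon + koff), tolerance = 0.03)
})

test_that("input modulation follows a piecewise-constant signal", {
  # pure birth with rate modulated by a two-level input
  bd <- birth_death()
  input <- oap_signal(seq(0, 10, by = 0.5), rep(c(2, 0), each = 10, length.out = 21))
  m <- ssa_simulate(bd$re, bd$pr, c(100, 0), x0 = 0,
                    record_times = c(4.99, 9.99), input = input,
                    input_reaction = 1, seed = 3)
  # first 5 h at rate 200 (about 1000 births), then the rate drops to 0;
  # only the 0.01 h sliver before the switch can still fire
  expect_gt(m[1, 1], 850)
  expect_lt(m[1, 1], 1150)
  expect_lt(m[2, 1] - m[1, 1], 10)
})

test_that("the biofilm SSA conserves promoter copies and stays ON when it should", {
  mod <- biofilm_ssa_model(g = 0.4)
  sim <- gillespie_simulate(mod, input = 0.4, duration = 30, seed = 2)
  expect_true(all(sim$PIf + sim$PIo + sim$PIl == 1))
  expect_true(all(sim$PLf + sim$PLo == 1))
  expect_true(all(sim$PTf + sim$PTo == 1))
  expect_true(all(as.matrix(sim[mod$species]) >= 0))
})

test_that("ensemble means track the deterministic model on the ON branch", {
  # deep in the ON region switching is negligible and the count-scaled
  # stochastic mean should match the ODE trajectory
  g <- 0.4; c0A <- 0.4
  mod <- biofilm_ssa_model(g = g)
  det <- spopulse:::biofilm_steady(biofilm_params(), c0A, g,
                                   spopulse:::.matrix_on_init())
  x0 <- mod$x0
  for (s in names(det)) x0[[s]] <- as.integer(round(det[[s]] * mod$omega))
  means <- numeric(0)
  for (i in 1:25) {
    sim <- gillespie_simulate(mod, c0A, 12, seed = 100 + i, x0 = x0,
                              dt_record = 0.5)
    means <- c(means, mean(sim$TapA[sim$time > 4]))
  }
  expect_equal(mean(means), det[["TapA"]] * mod$omega, tolerance = 0.1)
})

test_that("burn-in settles the requested macro-state and seeds differ", {
  mod <- biofilm_ssa_model(g = 0.4)
  off_state <- ssa_burn_in(mod, 0, duration = 40, seed = 1)
  expect_lt(off_state[["TapA"]], 200)
  on_state <- ssa_burn_in(mod, 0.5, duration = 40, seed = 1)
  expect_gte(on_state[["TapA"]], 200)
  s2 <- ssa_burn_in(mod, 0.5, duration = 40, seed = 2)
  expect_false(identical(on_state, s2))
})

test_that("a one-cell ensemble reduces to a single simulation", {
  mod <- biofilm_ssa_model(g = 0.4)
  ens <- run_ensemble(mod, 0.2, n_cells = 1, duration = 5, initial = "off",
                      seed_base = 7, burn_duration = 10)
  st <- ssa_burn_in(mod, 0, duration = 10, seed = 8)
  sim <- gillespie_simulate(mod, 0.2, 5, x0 = st, dt_record = 0.1)
  expect_equal(as.integer(ens$tapA[1, ]), sim$TapA)
})

test_that("locking the sinI promoter shuts down activation", {
  mod <- biofilm_ssa_model(g = 0.4, locked = TRUE, k_lock = 50,
                           k_unlock = 0.01)
  sim <- gillespie_simulate(mod, input = 0.5, duration = 30, seed = 4)
  expect_lt(sim$TapA[nrow(sim)], 200)
  expect_true(all(sim$PIf + sim$PIo + sim$PIl == 1))
})

test_that("stochastic cell-cycle ensembles run and are reproducible", {
  mod <- biofilm_ssa_model(g = 0.4)
  e1 <- stochastic_cycle_ensemble(mod, n_cells = 2, duration = 8, g = 0.4,
                                  seed_base = 3, n_lib = 3)
  e2 <- stochastic_cycle_ensemble(mod, n_cells = 2, duration = 8, g = 0.4,
                                  seed_base = 3, n_lib = 3)
  expect_equal(e1$tapA, e2$tapA)
  expect_true(all(e1$tapA >= 0))
  expect_equal(dim(e1$tapA), c(2, length(e1$times)))
})
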