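# build an ssa_ensemble by hand from a TapA count matrix
fake_ensemble <- function(tapA, times = seq(0, 1, length.out = ncol(tapA)),
                          initial = "off") {
  structure(list(times = times, tapA = tapA, initial = initial,
                 seeds = seq_len(nrow(tapA)), n_cells = nrow(tapA)),
            class = "ssa_ensemble")
}

test_that("ON fractions count inclusively at the threshold", {
  tapA <- matrix(c(rep(500L, 5), rep(0L, 15)), 20, 3)
  f <- fraction_on(fake_ensemble(tapA))
  expect_equal(f$fon, rep(0.25, 3))
  # 200 is ON, 199 is OFF
  edge <- fake_ensemble(matrix(c(200L, 199L), 2, 1))
  expect_equal(fraction_on(edge)$fon, 0.5)
  expect_equal(fraction_on(edge, threshold = 199)$fon, 1)
  expect_error(fraction_on(edge, threshold = 0), "positive")
})

test_that("two-state occupancy law satisfies its ODE and limits", {
  k_on <- 0.4; k_off <- 1.1
  expect_equal(pon(0, k_on, k_off, 0.3), 0.3)
  expect_equal(pon(1e6, k_on, k_off, 0), k_on / (k_on + k_off))
  expect_equal(pon(1, 0.5, 0.5, 0), 0.5 * (1 - exp(-1)))

  # dP/dt = kON (1 - P) - kOFF P by central finite differences
  tt <- seq(0.05, 8, by = 0.05)
  h <- 1e-5
  for (p0 in c(0, 1, 0.3)) {
    num <- (pon(tt + h, k_on, k_off, p0) - pon(tt - h, k_on, k_off, p0)) /
      (2 * h)
    ana <- k_on * (1 - pon(tt, k_on, k_off, p0)) -
      k_off * pon(tt, k_on, k_off, p0)
    expect_lt(max(abs(num - ana)), 1e-6)
  }
  # the initially-OFF and initially-ON curves converge
  tl <- 20 / (k_on + k_off)
  expect_lt(abs(pon(tl * 1.05, k_on, k_off, 0) -
                pon(tl * 1.05, k_on, k_off, 1)), 1e-6)
  expect_warning(pon(1, 0, 0, 0.4), "frozen")
})

test_that("rate fitting is exact on noiseless occupancy curves", {
  tt <- seq(0, 40, by = 0.1)
  k_on <- 0.02; k_off <- 0.20
  s_off <- structure(data.frame(time = tt, fon = pon(tt, k_on, k_off, 0)),
                     class = c("on_fraction", "data.frame"))
  s_on <- structure(data.frame(time = tt, fon = pon(tt, k_on, k_off, 1)),
                    class = c("on_fraction", "data.frame"))
  fit <- fit_rates(s_off, s_on)
  expect_equal(fit$k_on, k_on, tolerance = 0.01)
  expect_equal(fit$k_off, k_off, tolerance = 0.01)
  expect_lt(fit$mse, 1e-10)
  expect_equal(fit$pon_inf, k_on / (k_on + k_off), tolerance = 0.01)
})

test_that("rates are recovered from simulated telegraph ensembles", {
  tt <- seq(0, 40, by = 0.1)
  k_on <- 0.05; k_off <- 0.2
  e_off <- simulate_telegraph(2000, k_on, k_off, tt, FALSE, seed = 2)
  e_on <- simulate_telegraph(2000, k_on, k_off, tt, TRUE, seed = 3)
  fit <- fit_rates(fraction_on(e_off), fraction_on(e_on))
  expect_lt(abs(fit$k_on - k_on) / k_on, 0.10)
  expect_lt(abs(fit$k_off - k_off) / k_off, 0.10)
  expect_gt(fit$r2_off, 0.95)
  expect_gt(fit$r2_on, 0.95)
})

test_that("threshold robustness is deterministic under a seed and collapses", {
  tt <- seq(0, 10, by = 0.5)
  set.seed(4)
  mk <- function(seed) {
    e <- simulate_telegraph(80, 0.1, 0.3, tt, FALSE, seed = seed)
    # give ON cells variable counts so the threshold matters mildly
    e$tapA <- e$tapA + matrix(stats::rpois(length(e$tapA), 30), nrow(e$tapA))
    e
  }
  e_off <- mk(5); e_on <- mk(6); e_on$initial <- "on"
  r1 <- threshold_robustness(e_off, e_on, n_draws = 8, seed = 42)
  r2 <- threshold_robustness(e_off, e_on, n_draws = 8, seed = 42)
  expect_equal(r1, r2)
  # a collapsed draw range has zero spread
  r0 <- threshold_robustness(e_off, e_on, n_draws = 5, range = c(1, 1),
                             seed = 1)
  expect_equal(unname(attr(r0, "sd")), c(0, 0))
})

test_that("degenerate series trigger the boundary warning", {
  tt <- seq(0, 10, by = 0.5)
  s0 <- structure(data.frame(time = tt, fon = rep(0, length(tt))),
                  class = c("on_fraction", "data.frame"))
  s1 <- structure(data.frame(time = tt, fon = rep(1, length(tt))),
                  class = c("on_fraction", "data.frame"))
  expect_warning(fit_rates(s0, s1), "boundary")
})
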