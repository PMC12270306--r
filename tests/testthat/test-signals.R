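test_that("cosine signals have zero minimum and mean equal to amplitude", {
  sig <- cosine_signal(amplitude = 0.5, period = 2, duration = 6, dt = 0.01)
  expect_equal(sig$values[1], 1.0)                     # 2A at t = 0
  expect_equal(min(sig$values), 0, tolerance = 1e-9)   # offset = amplitude
  half <- which.min(abs(sig$times - 1))                # t = T/2
  expect_equal(sig$values[half], 0, tolerance = 1e-9)
  # time-average over whole periods equals the amplitude
  for (k in 1:3) {
    in_k <- sig$times <= 2 * k + 1e-12
    expect_equal(mean_of_cycle(oap_signal(sig$times[in_k], sig$values[in_k])),
                 0.5, tolerance = 1e-4)
  }
  expect_error(cosine_signal(0.5, 2, 6, dt = 0.1), "coarse")
  expect_error(cosine_signal(0.5, 2, duration = 1), "period")
})

test_that("square trains follow the scheduled ON/OFF durations", {
  sig <- square_signal(high = 1, low = 0.1, on_durations = rep(1, 3),
                       off_durations = c(1, 2, 3))
  expect_equal(attr(sig, "cycle_bounds"), c(2, 5, 9))
  f <- signal_fun(sig)
  expect_equal(f(0.5), 1)     # first ON phase
  expect_equal(f(1.5), 0.1)   # first OFF phase
  expect_equal(f(2.5), 1)     # second ON
  expect_equal(f(4.0), 0.1)   # second OFF (2 h long)
  # degenerate: high = low is a constant signal
  cs <- square_signal(0.3, 0.3, c(1, 1), c(2, 2))
  expect_true(all(cs$values == 0.3))
  # duty cycle d on a fixed cycle: time-average = low + d (high - low)
  d <- 0.25
  sq <- square_signal(1, 0, on_durations = rep(d, 4), off_durations = rep(1 - d, 4))
  expect_equal(mean_of_cycle(sq), d, tolerance = 0.02)
  expect_error(square_signal(1, 0, c(1, 1), c(1)), "equal length")
  expect_error(square_signal(1, 0, c(1, -1), c(1, 1)), "positive")
})

test_that("per-cycle surrogates average, bound, and preserve integrals", {
  # constant input: all three modes are the identity
  const <- oap_signal(seq(0, 6, 0.01), rep(0.4, 601))
  for (m in c("mean", "max", "min"))
    expect_equal(per_cycle_constant(const, c(2, 4), m)$values, const$values)

  # cosine over one full period: mean mode gives the offset
  sig <- cosine_signal(0.5, 2, 4, dt = 0.01)
  pc <- per_cycle_constant(sig, c(2, 4), "mean")
  expect_equal(unique(round(pc$values, 6)), 0.5, tolerance = 1e-3)

  # triangular pulse 0 -> 2 -> 0 over one cycle
  tt <- seq(0, 2, by = 0.01)
  tri <- oap_signal(tt, 2 - 2 * abs(tt - 1))
  expect_equal(unique(per_cycle_constant(tri, 2, "mean")$values), 1,
               tolerance = 1e-3)
  expect_equal(unique(per_cycle_constant(tri, 2, "max")$values), 2)
  expect_equal(unique(per_cycle_constant(tri, 2, "min")$values), 0)

  # mean mode preserves each cycle's time integral (quadrature tolerance)
  set.seed(1)
  wig <- oap_signal(seq(0, 9, 0.01), abs(sin(seq(0, 9, 0.01)) + 0.2))
  pcm <- per_cycle_constant(wig, c(3, 6), "mean")
  intg <- function(s, a, b) {
    sel <- s$times >= a & s$times <= b
    sum(diff(s$times[sel]) * (s$values[sel][-1] + head(s$values[sel], -1)) / 2)
  }
  for (w in list(c(0, 3), c(3, 6), c(6, 9)))
    expect_equal(intg(pcm, w[1], w[2]), intg(wig, w[1], w[2]),
                 tolerance = 0.01)
})

test_that("signal constructor validates its grid", {
  expect_error(oap_signal(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(oap_signal(c(0, 1, 3), c(1, 2, 3)), "uniform")
  expect_error(oap_signal(c(0, 1), c(-2, 1)), "non-negative")
})

test_that("signals survive a CSV round trip", {
  sig <- cosine_signal(0.3, 1.5, 3, dt = 0.01)
  path <- tempfile(fileext = ".csv")
  write_signal_csv(sig, path)
  back <- read_signal_csv(path)
  expect_equal(back$times, sig$times)
  expect_equal(back$values, sig$values)
  unlink(path)
})

test_that("the natural pulse is periodic, non-negative, and needs phosphoflux", {
  sig <- natural_pulse_signal(g = 0.2, n_cycles = 4)
  expect_true(all(sig$values >= 0))
  tau <- timing_from_growth(0.2)$tau_cyc
  # successive post-transient cycles are near-identical
  f <- signal_fun(sig)
  tt <- seq(0, tau, by = 0.01)
  c1 <- f(2 * tau + tt); c2 <- f(3 * tau + tt)
  expect_gt(stats::cor(c1, c2), 0.99)
  # with no autophosphorylation there is no Spo0A~P at all
  flat <- natural_pulse_signal(g = 0.2, n_cycles = 2,
                               params = phosphorelay_params(kauto = 0))
  expect_lt(max(flat$values), 1e-3)
})
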