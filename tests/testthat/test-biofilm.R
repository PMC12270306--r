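bp <- biofilm_params()

test_that("production-rate forms match their limits and half points", {
  # sinI: basal, half-saturation, saturation
  base <- bp$ktran_i / bp$kdegm
  expect_equal(sinI_rate(0, 1, 1, bp), bp$vi0 * base)
  expect_equal(sinI_rate(bp$Ki, 1, 1, bp), (bp$vi0 + bp$vimax / 2) * base)
  expect_equal(sinI_rate(1e9, 1, 1, bp), (bp$vi0 + bp$vimax) * base,
               tolerance = 1e-6)
  # slrR / tapA: fully derepressed, half-repressed, fully repressed
  expect_equal(slrR_rate(0, 1, 1, bp), (bp$vl0 + bp$vlmax) * base)
  expect_equal(slrR_rate(bp$Kl, 1, 1, bp), (bp$vl0 + bp$vlmax / 2) * base)
  expect_equal(slrR_rate(1e9, 1, 1, bp), bp$vl0 * base, tolerance = 1e-6)
  expect_equal(tapA_rate(bp$Kt, 1, 1, bp), (bp$vt0 + bp$vtmax / 2) * base)
  # effective degradation: sum, and the pinned-dilution variant
  expect_equal(effective_degradation(0.2, 0.2), 0.4)
  expect_equal(effective_degradation(0.2, 0.05, fixed_g0 = TRUE, g0 = 0.2), 0.4)
  expect_equal(effective_degradation(0.2, 0.9, fixed_g0 = TRUE, g0 = 0.2), 0.4)
})

test_that("matrix network relaxes to OFF without input and holds ON above threshold", {
  # from an empty cell with no Spo0A~P the system settles at low TapA
  sim <- simulate_biofilm(bp, input = 0, g = 0.2, duration = 150, dt = 0.5)
  expect_lt(sim$TapA[nrow(sim)], 0.2)
  expect_true(all(as.matrix(sim[spopulse:::.biofilm_species]) >= -1e-9))

  # from the ON branch, a constant input inside the bistable range holds
  ref <- matrix_reference(bp)
  sim_on <- simulate_biofilm(bp, input = 0.2, g = 0.2, duration = 150,
                             state0 = ref$state_on, dt = 0.5)
  expect_gt(sim_on$TapA[nrow(sim_on)], ref$midpoint)

  # zero duration returns the initial state
  s0 <- ref$state_on
  expect_equal(unlist(simulate_biofilm(bp, 0.2, 0.2, 0, s0)[1, names(s0)]),
               s0)
})

test_that("SinR sequestration is required for matrix output", {
  # without complex formation SinR stays active and TapA is pinned at basal
  bp_nc <- biofilm_params(kir_f = 0, kir_r = 0, klr_f = 0, klr_r = 0)
  sim <- simulate_biofilm(bp_nc, input = 1, g = 0.2, duration = 200, dt = 0.5)
  basal_level <- tapA_rate(sim$RT[nrow(sim)], 1.5, size_factor(0.2), bp_nc) / 0.4
  expect_lt(sim$TapA[nrow(sim)], 2 * basal_level)
  expect_lt(sim$TapA[nrow(sim)], 0.2)
})

test_that("SinR moieties are conserved when synthesis and decay are frozen", {
  bp0 <- biofilm_params(vi0 = 0, vimax = 0, vr0 = 0, vl0 = 0, vlmax = 0,
                        vt0 = 0, vtmax = 0, kdegpro = 0, kdegL = 0, kdegI = 0)
  state <- c(Id = 0.5, R = 0.8, RT = 0.3, IR = 0.2, L = 0.6, LR = 0.25,
             TapA = 0.1)
  sim <- simulate_biofilm(bp0, input = 0, g = 0, duration = 20,
                          state0 = state, dt = 0.2,
                          effects = biofilm_effects(dosage = "frozen"))
  total_R <- sim$R + 2 * sim$RT + sim$IR + sim$LR
  expect_equal(max(abs(total_R - total_R[1])), 0, tolerance = 1e-6)
  total_L <- sim$L + sim$LR
  expect_equal(max(abs(total_L - total_L[1])), 0, tolerance = 1e-6)
})

test_that("the switch is bistable in the reference window with >10x separation", {
  ss <- constant_input_steady_states(0.2, g = 0.2, params = bp)
  expect_equal(nrow(ss), 2)
  expect_gt(ss$tapA[ss$branch == "ON"], 10 * ss$tapA[ss$branch == "OFF"])
  # below the deactivation threshold: monostable OFF
  ss_lo <- constant_input_steady_states(0.03, g = 0.2, params = bp)
  expect_equal(nrow(ss_lo), 1)
  expect_lt(ss_lo$tapA, 0.5)
  # no input at all: single OFF state
  ss0 <- constant_input_steady_states(0, g = 0.2, params = bp)
  expect_equal(nrow(ss0), 1)
})

test_that("ON-branch TapA responds monotonically to the input level", {
  ref <- matrix_reference(bp)
  cs <- c(0.12, 0.16, 0.2, 0.3)
  tapA <- vapply(cs, function(cc)
    spopulse:::biofilm_steady(bp, cc, 0.2, ref$state_on)[["TapA"]], 0)
  expect_true(all(tapA > ref$midpoint))
  expect_true(all(diff(tapA) > -1e-6))
})
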