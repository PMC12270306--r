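# Vectorized simulator of the two-state (telegraph) Markov chain: an
# independent oracle for the occupancy-fit machinery. Cells alternate
# exponential dwell times; the ON indicator is reported as a TapA-like
# count matrix wrapped as an ssa_ensemble.
simulate_telegraph <- function(n_cells, k_on, k_off, t_grid,
                               start_on = FALSE, seed = 1,
                               max_switches = 120) {
  set.seed(seed)
  r1 <- if (start_on) k_off else k_on     # rate out of the initial state
  r2 <- if (start_on) k_on else k_off
  waits <- matrix(0, n_cells, max_switches)
  odd <- seq(1, max_switches, by = 2)
  waits[, odd] <- stats::rexp(n_cells * length(odd), r1)
  waits[, -odd] <- stats::rexp(n_cells * (max_switches - length(odd)), r2)
  switch_times <- t(apply(waits, 1, cumsum))
  tapA <- matrix(0L, n_cells, length(t_grid))
  for (j in seq_along(t_grid)) {
    n_sw <- rowSums(switch_times <= t_grid[j])
    on <- xor(start_on, n_sw %% 2L == 1L)
    tapA[, j] <- ifelse(on, 400L, 0L)
  }
  structure(list(times = t_grid, tapA = tapA,
                 initial = if (start_on) "on" else "off",
                 seeds = seq_len(n_cells), n_cells = n_cells),
            class = "ssa_ensemble")
}
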