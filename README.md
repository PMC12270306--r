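# spopulse

Deterministic and stochastic models of how *Bacillus subtilis* decides to
stop making biofilm matrix as growth slows — and in particular of how the
**pulsing frequency of Spo0A~P**, rather than only its average level,
controls that decision.

Under starvation, the phosphorelay KinA → Spo0F → Spo0B → Spo0A sets the
level of the phosphorylated master regulator Spo0A~P. Because *spo0F* sits
near the replication origin and *kinA* near the terminus, every round of
DNA replication creates a transient kinA:spo0F gene-dosage imbalance that,
together with Spo0F's inhibition of KinA, produces **one Spo0A~P pulse per
cell cycle**: a trough during the replication period, an overshoot
afterwards, with period τ_cyc = ln2/g and amplitude growing as growth
slows (τ_rep = 0.78 + 0.15/g h). Spo0A~P induces SinI, which together with
SlrR sequesters the repressor SinR; the SinR/SlrR double-negative loop
makes matrix output (reported by TapA) a bistable switch. The package
implements:

* `cellcycle` arithmetic (`timing_from_growth`, `discrete_copy_number`,
  `average_copy_number`, `size_factor`);
* the phosphorelay ODE model with copy-number events
  (`simulate_phosphorelay`, `natural_pulse_signal`);
* synthetic inputs (`cosine_signal`, `square_signal`,
  `per_cycle_constant`);
* the deterministic matrix network (`simulate_biofilm`,
  `find_deactivation_cycle`) and its steady-state structure
  (`constant_input_steady_states`, `bistable_threshold_constant`,
  `oscillatory_threshold`, `matched_period_curve` + `power_law_fit` of
  M_OFF = a·τ_cyc^b + c);
* an exact Gillespie implementation with explicit promoter states
  (`biofilm_ssa_model`, `gillespie_simulate`, `run_ensemble`,
  `stochastic_cycle_ensemble`);
* two-state (telegraph) rate estimation from ensemble ON-fractions
  (`fraction_on`, `pon`, `fit_rates`, `threshold_robustness`), where the
  occupancy law P(t) = P0·e^{−t(kON+kOFF)} + kON/(kON+kOFF)·(1−e^{−t(kON+kOFF)})
  is fitted jointly to initially-OFF and initially-ON ensembles;
* scenario drivers `run_fig2` … `run_fig6` for the slowdown, ensemble,
  bifurcation, cycle-phase and five-condition analyses.

All rate constants are the package's own calibration (see the methods
vignette, `vignettes/matrix-deactivation-methods.Rmd`, for what was fixed
by published values and what was calibrated, and why).

## Worked example

```r
library(spopulse)

print(timing_from_growth(0.2))
#> cell cycle at g = 0.2 1/h: tau_rep = 1.53 h, tau_post = 1.94 h, tau_cyc = 3.47 h

pulse <- natural_pulse_cycle(phosphorelay_params(), timing_from_growth(0.2))
sprintf("pulse: mean %.3f uM, range [%.3f, %.3f] uM",
        mean_of_cycle(pulse), min(pulse$values), max(pulse$values))
#> "pulse: mean 0.233 uM, range [0.157, 0.291] uM"

ref <- matrix_reference()
bistable_threshold_constant(0.2, reference = ref)
#> 0.106

constant_input_steady_states(0.2, g = 0.2)
#>   branch       tapA
#> 1    OFF 0.06486206
#> 2     ON 2.08546977
```

Reading: at the reference growth rate 0.2/h the DNA replication period is
1.53 h of a 3.47 h cycle; the phosphorelay emits a once-per-cycle Spo0A~P
pulse averaging 0.23 µM; the matrix switch under a constant input
deactivates below ≈0.11 µM and is bistable at 0.2 µM, with the ON and OFF
TapA branches separated thirty-fold. Longer-period inputs need higher
means to keep the matrix ON (`oscillatory_threshold`), which is why the
lengthening of the cell cycle — mostly its replication period — eventually
deactivates matrix production even though the pulse amplitude keeps
rising.

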