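---
title: "Models and methods: Spo0A~P pulsing and biofilm matrix deactivation"
author: "spopulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: Spo0A~P pulsing and biofilm matrix deactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question

Starving *B. subtilis* cells choose between two mutually exclusive fates —
biofilm matrix production and sporulation — both activated by the
phosphorylated master regulator Spo0A (Spo0A~P). Spo0A~P is not constant:
the chromosomal arrangement of the phosphorelay genes (*spo0F* near the
replication origin, *kinA* near the terminus) creates a transient gene-dosage
imbalance during each round of DNA replication, and together with Spo0F's
inhibition of KinA this produces one Spo0A~P pulse per cell cycle whose
period equals the cell-cycle length and whose amplitude grows as growth
slows. This package implements coupled deterministic and stochastic models
to ask how the *frequency* of that pulse controls the deactivation of
matrix production, separately from the previously studied growth-rate
effects on gene dosage and protein dilution.

## Cell-cycle arithmetic

The replication period lengthens as growth slows, `tau_rep = 0.78 + 0.15/g`
(hours; `g` in 1/h), while the cycle length is `tau_cyc = ln 2 / g`;
the post-replication period is the difference. At the reference growth
rate 0.2/h these are 1.53, 3.47 and 1.94 h. Replication initiates at cycle
start; a locus at fractional position `p` (0 = origin, 1 = terminus)
doubles its copy number at `p * tau_rep` into the cycle and halves at
division. The population-average copy number is `2^(1 - p*tau_rep/tau_cyc)`.
Overlapping replication rounds (g above ~0.63/h) are not modelled; the
constructor rejects them unless explicitly overridden, in which case the
kinA:spo0F dosage ratio is capped at 1:2. Cell size follows
`F(g) = 3.5 exp(-ln 2 * g) + 3.7` and multiplies all transcription rates.

## The phosphorelay model and its calibration

The deterministic phosphorelay tracks KinA, Spo0F, Spo0B, Spo0A (each with
its phosphoform) and the phosphatases Rap and Spo0E. Production of each
protein is a Hill function of Spo0A~P times `F(g)` and the current gene
copy number, low-pass filtered with a first-order delay (`kdel = 4`/h).
Phosphoryl groups flow KinA~P -> Spo0F~P -> Spo0B~P -> Spo0A~P by mass
action; Rap and Spo0E drain Spo0F~P and Spo0A~P through saturating
(zero-order) Michaelis kinetics, and free Spo0F inhibits KinA
autophosphorylation cooperatively. Because the free Spo0F pool is itself
depleted by phosphotransfer, rising kinase flux disinhibits KinA — a fast
positive feedback that converts the once-per-cycle kinA dosage step into an
excitable burst. An unstable, Spo0A~P-inducible Spo0E (turnover 1.5/h + g)
terminates each burst, and Spo0A~P-induced spo0F provides a slower
refractory feedback.

The numerical rate constants are this package's own calibration (the
published model's full constant table is not reproduced here); they were
chosen once so that the model shows the qualitative signature of the
natural signal — a single Spo0A~P pulse per cell cycle for g at or below
0.4/h, a trough during the DNA replication window, an overshoot that peaks
between the end of replication and division, pulse amplitude and mean that
increase as growth slows, and a nearly flat low signal at fast growth
(0.6/h) — and so that the downstream matrix switch operates in a
biologically sensible window (see below). Phosphatase genes are placed
origin-proximally so that their dosage does not cancel the kinA dosage
signal; the phosphorelay gene positions for the remaining loci are
approximate map positions.

## The biofilm matrix network

SinI (produced as a dimer under Spo0A~P control), the SinR dimer `R`, its
tetramer `R_T`, SlrR `L`, the complexes `IR` and `LR`, and TapA follow mass
action with transcription factored as
`(basal + regulated Hill term) * n * F(g) * ktran/kdegm`, so that the
stochastic model's separate transcription (per-promoter) and translation
(per-mRNA) steps reduce exactly to the deterministic rates in the
quasi-steady-state mRNA limit. The SinR tetramer represses *slrR* and
*tapA*; SinI and SlrR sequester the SinR dimer. mRNA decay is 8.3/h,
protein decay 0.2/h with dilution `+g`; SlrR is unstable (0.8/h) and the
SinI dimer is likewise treated as a fast-turnover protein (2/h). The
unstable partners are degraded inside their complexes at their own rates,
releasing the stable SinR dimer back to the pool, so SinR is removed only
by dilution and basal decay. This makes the total SinR inventory scale as
production over effective decay: as growth slows, dilution weakens and
SinR accumulates faster than the unstable SlrR pool can, which is the
mechanistic reason the deactivation threshold rises with slowing growth.

With the default calibration at g = 0.2/h the network is bistable for
constant Spo0A~P inputs above about 0.11 uM (the deactivation threshold
MOFF); the OFF branch is stable well beyond the reference window, so
deterministic activation from OFF requires a high sustained input, and
in the stochastic model activation is noise-driven. ON/OFF classification everywhere in
the package uses one fixed midpoint — the geometric mean of the two TapA
branch levels at the reference condition (g = 0.2/h, constant 0.2 uM) —
because the branches separate by more than an order of magnitude there
and a single classifier keeps all threshold searches comparable.

## Threshold searches

* Constant-input threshold: bisection on the input level (tolerance 1e-3
  uM, bracket [0, 2] uM) of the ON-branch survival, continuing the ON
  branch from the converged reference ON state (a naive "ON-like" initial
  guess can die transiently near the fold and bias the threshold).
* Oscillatory thresholds: cosine inputs with zero minimum (offset =
  amplitude = mean). The ON state is simulated for max(200 h, 25 periods)
  and classified by the final full period's mean TapA. The threshold is
  the smallest sustaining mean.
* Matched-period curve: for cycle lengths 1, 3, 5 and 6 h the oscillation
  period is set equal to the cycle length and the growth rate to
  ln 2 / tau_cyc, mimicking one pulse per cycle; the resulting thresholds
  are fitted with `MOFF = a * tau_cyc^b + c` by bounded
  Levenberg-Marquardt least squares with five jittered starts.
* Cell-cycle deactivation threshold: starting from the matrix-ON attractor
  at the reference cycle (tau_rep 1.53 h, tau_post 1.94 h), the cycle
  length grows in 0.1 h steps — through the growth-rate law (slowdown),
  through the replication period only, or through the post-replication
  period only. At each step the phosphorelay input is regenerated (one
  post-transient cycle, tiled periodically), the network integrated for at
  least 120 h warm-started from the previous step, and the end state
  classified. The growth effects on dilution (replace g by g0 = 0.2/h) and
  on dosage (freeze tau_rep/tau_cyc at the reference cycle in the
  copy-number law) can be switched off independently, and the pulsatile
  input can be replaced by its per-cycle mean — the five-condition
  decomposition.

## The stochastic model

The Gillespie implementation (direct method, C++ core) makes the promoter
states explicit: Spo0A~P binds the *sinI* promoter with propensity
proportional to the current input level — so promoter occupancy follows
input changes with a relaxation time of about 1/(k_unbind) rather than
instantaneously — and the SinR tetramer binds the *slrR* and *tapA*
promoters. Transcription and translation are separate reactions per gene;
the translation burst size (default 10 proteins per mRNA lifetime) sets
the noise level and was chosen so that single cells activate and
deactivate matrix production spontaneously on the tens-of-hours scale at
g = 0.4/h. Counts convert to concentrations via omega = 600 molecules/uM,
which places the TapA ON mode near 800 molecules and the OFF mode near 50,
consistent with a 200-molecule classification threshold at the antimode.
Time-varying inputs enter as piecewise-constant propensities refreshed
every 0.005 h; within a refresh interval the algorithm is exact. Ensembles
initialize every cell from its own 60 h burn-in (zero input for
initially-OFF, a high constant for initially-ON), use seeds base+index,
and record TapA on a 0.1 h grid for 40 h. The locked-promoter extension
adds three reactions letting the sinI promoter enter a transcriptionally
dead state. The stochastic cell-cycle variant draws each cycle length from
a truncated normal (CV 0.1: the cycle-length spread is specified as a
coefficient of variation, matching typical B. subtilis cycle-length
variability), regenerates the cycle's input from a
precomputed pulse library, and partitions all molecular counts binomially
at division, carrying one daughter onward with promoters reset and bound
regulators released.

## Two-state analysis

Ensemble ON-fractions (TapA at or above 200 molecules, inclusive) are
fitted simultaneously for the initially-OFF (P0 = 0) and initially-ON
(P0 = 1) arms with the memoryless telegraph occupancy law, one (kON, kOFF)
pair minimizing the pooled squared error, by bounded multi-start
optimization in log-rate space (rates in [1e-6, 10]/h). R-squared is
reported per curve against each curve's own mean and the pooled MSE over
both. The threshold-robustness check redoes classification and fit for 100
thresholds drawn uniformly from 25%-175% of 200 molecules. The fitted time
grid is 0.1 h over [0, 40] h.

## What the generator emulates, and what it does not

The synthetic-input module produces the four input classes used throughout:
the natural phosphorelay pulse (the model's own output), per-cycle
constants (mean, max or min of the pulse over each cycle), zero-minimum
cosines, and square trains with independently scheduled ON/OFF durations.
For slowdown scenarios the growth schedule defaults to a linear ramp
(0.6 -> 0.15/h) with cycle boundaries found by accumulating growth to ln 2;
the published schedule is shown only graphically, so the ramp is a choice.
Real cells differ in ways the generator ignores: extrinsic noise in rate
constants, replication-initiation timing variability beyond the cycle-length
draw, lineage correlations (only one daughter is followed), and any
coupling from the matrix network back onto growth. Passing tests therefore
validate the mechanisms as implemented, not quantitative agreement with
any particular experiment.

## Numerical choices and problem sizes

Stiff integration uses lsoda with rtol 1e-8 / atol 1e-10, restarted at
every copy-number discontinuity with state carried across (concentrations
are not halved at division; dilution is continuous). Signals feeding the
SSA are sampled at 0.005 h, ODE inputs at 0.01 h with linear
interpolation. Deactivation-cycle candidates are integrated at least
120 h; steady states are accepted when the relative right-hand side falls
below 1e-6 or after 400 h. The shipped test-suite problem sizes (ensemble
sizes of a few hundred cells, 8-10 cell cycles per deterministic run) are
the package's default verification scale; all are arguments and scale up
linearly in cost. The first three simulated cycles of any phosphorelay run
are discarded as transient before a signal is exported.

## Known limitations

The two-state description is an effective model; the underlying switching
is not perfectly memoryless and no correction for that is attempted. The
rate constants are a calibration, not fitted to data: quantities tied to
the absolute scale of the published constant tables (exact deactivation
cycle lengths, absolute switching-rate differences) reproduce in sign and
ordering but not necessarily in magnitude. Multi-fork replication,
kinases beyond KinA, and competence or sporulation downstream networks
are out of scope.
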