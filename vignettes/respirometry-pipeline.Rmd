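---
title: "Coupling-control respirometry of platelets: model and methods"
author: "respilab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling-control respirometry of platelets: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

High-resolution respirometry (HRR) measures cellular oxygen consumption as
the decline of dissolved O2 concentration in a closed, stirred chamber.
A substrate-uncoupler-inhibitor titration (SUIT) protocol steps the cells
through defined respiratory states; the coupling-control and
cell-viability (CCV) variant used here runs, in order: endogenous ROUTINE
respiration of living platelets (ce1), pyruvate addition (ce1P), stepwise
oligomycin titration to LEAK respiration (ce2Omy), stepwise FCCP
titration to electron-transfer (ET) capacity (ce3U), rotenone (ce4Rot),
succinate as a plasma-membrane-integrity probe (ce5S), stepwise digitonin
permeabilization (1Dig), cytochrome c as an outer-mitochondrial-membrane
probe (1c), and antimycin A for residual oxygen consumption (2Ama).

The package addresses a concrete comparative question: platelets isolated
by clinical apheresis (PA) respire differently from platelets isolated by
density-gradient centrifugation (DC) — higher ROUTINE and ET capacity in
living cells, strongly reduced succinate-linked ET capacity after
permeabilization, and larger effective inhibitor/uncoupler/detergent
concentrations — and washing the apheresis platelets in phosphate buffer
with EGTA (WA) restores DC-like behaviour. respilab provides (i) a
forward simulator that plants exactly these effects into synthetic
chamber traces, (ii) the analysis chain that recovers per-state fluxes
and derived quality metrics from any trace in its CSV dialect, and (iii)
cohort-level contrasts and the activation-vs-respiration regression.
Because every analysis stage can be run against simulated data with
known ground truth, the whole pipeline is testable end to end.

## Forward model

Between titration events the chamber O2 concentration obeys

    dc/dt = -(J_cells(t) + J_bg(c)) / 1000        [umol L^-1 s^-1]

with `J_cells` the volume-specific cellular flux (pmol s^-1 mL^-1) of the
active protocol state and `J_bg(c) = a + b c` a linear instrumental
background. `J_cells` is the planted per-cell flow of the state (amol
s^-1 x^-1) plus the residual per-cell flow, times the cell concentration
(cells distribute over working + stopper-capillary volume; 108e6
platelets in 0.5 + 0.04 mL give 200e6 cells/mL). Each event is followed
by an exponential transition ramp with time constant `rampDuration/5`
(the nominal 20 s ramp is five time constants), representing mixing and
metabolic settling. Because the equation is linear with exponential
forcing, every segment is integrated in closed form — the simulated trace
is exact to floating-point, which lets the test suite assert oxygen
bookkeeping (planted cumulative consumption equals the trace drop) at
1e-9 umol/L.

Dead cells — the fraction with a permeable plasma membrane — matter only
for the viability module, and the model keeps that scoping explicit: the
planted state flows are population averages, and the dead fraction `d`
enters through succinate accessibility alone. Before digitonin,
externally added succinate reaches only the mitochondria of
membrane-damaged cells, so the ce5S cellular flux is `d` times the
S-linked capacity (on top of the post-rotenone flow); after full
permeabilization all cells express that capacity. The post-rotenone
mitochondrial flow defaults to zero (without a permeant substrate,
rotenone reduces intact-cell flux to the residual flow), which makes the
respirometric viability index recover `1 - d` exactly on noiseless runs.
Residual (non-mitochondrial) consumption `roxFlow` is added to every
state for all cells.

Titration dose-responses are piecewise linear: oligomycin descends from
ROUTINE to LEAK, reaching LEAK exactly at the sample's effective
threshold and flat beyond; FCCP rises from LEAK to ET capacity at its
optimum and declines by 5% of E per further step (over-uncoupling);
digitonin raises the succinate-supported flow to the S-linked capacity at
its optimum, declining 5% per step beyond (membrane damage). Gaussian
sensor noise (default sd 0.2 umol/L) is added to the sampled
concentrations, not to the dynamics.

Injection volume effects are ignored by default (titration volumes are
below 1% of the chamber); `simulateTrace(..., dilution = TRUE)` enables
exact dilution arithmetic from an `injection_ul` event column for stress
tests.

If a run would consume all chamber oxygen the trace is truncated at the
first non-positive sample and flagged, mirroring real chamber anoxia.
The default protocol is designed not to get there: runs start at air
saturation of the MiR05 assay medium at 37 C (191 umol/L) and use 180 s
single states with 120 s titration steps, so even high-respiration
apheresis samples finish the full CCV sequence within the oxygen budget.

## Key parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `workingVolume`, `deadVolume` | mL | 0.5, 0.04 | chamber + stopper capillary; cells distribute over 0.54 mL |
| `sampleInterval` | s | 2 | instrument recording interval |
| `backgroundA`, `backgroundB` | pmol s^-1 mL^-1, per umol/L | -2.0, 0.025 | small linear instrumental background; no printed calibration exists, chosen small relative to cellular flux |
| `o2Init` | umol/L | 191 | air saturation of MiR05 at 37 C |
| `stateFlux` (DC baseline) | amol s^-1 x^-1 | ce1 0.10, ce1P 0.13, L 0.04, E 0.26, S 0.34 | typical platelet flows with coupling order E >= R >= L and S-capacity above living-cell E |
| `roxFlow` | amol s^-1 x^-1 | 0.008 | small residual consumption |
| `deadFraction` | — | DC/WA 0.13, PA 0.17 | plants viability indices of 87% and 83% |
| `omyThreshold` / `fccpOptimum` / `digOptimum` | nmol/L, umol/L, ug/mL | DC 10 / 1.0 / 5.0 | oligomycin from the 5–10 nmol/L working range; FCCP and digitonin optima typical for platelets in assay medium |
| method multipliers (PA) | — | R 1.22, E 1.16, S 0.57; optima 2.2/3.5/2.5; WA = DC | the planted between-method contrasts whose recovery the tests check |
| `donorCV`, `pathwayCV` | — | 0.15, 0.10 | log-normal (median-1) donor baseline and per-record pathway variation; flows are positive and right-skewed |
| activation model | %CD62P | 20 + 25 * FCR_S + noise | noise variance tuned so the population r^2 is 0.27 |
| `window_s` | s | 40 | slope window (21 points at 2 s); exact on linear declines, robust at this sampling |
| `settle_s` | s | 60 | excludes injection mixing and the transition ramp |

Titration grids step 5 nmol/L (oligomycin), 0.5 umol/L (FCCP) and
2.5 ug/mL (digitonin). The FCCP step is coarser than the 0.1 umol/L of
the bench protocol so that both the DC and the 3.5x apheresis optimum
sit on a short grid; the oligomycin schedule adds one confirmation step
beyond the threshold, FCCP two overshoot steps (making the maximum
identifiable as a peak), and digitonin stops at its optimum so the
cytochrome-c state continues from optimally permeabilized flux — an
overshoot there would plant outer-membrane-like damage and a spuriously
negative cytochrome-c effect.

## From trace to metrics

`computeFlux()` estimates volume-specific flux at every interior sample
as minus 1000 times the ordinary-least-squares slope of the
concentration over a centered window; edge samples without a full window
are flagged invalid rather than one-sided-differenced (one-sided stencils
bias end fluxes). On an exactly linear trace the OLS slope is exact for
any window width — the anchor test of the whole chain.
`correctBackground()` subtracts `a + b c(t)`. `extractStepFlux()` opens
an evaluation window 60 s after each event and takes the median flux
(robust to single-point injection artifacts), with the median absolute
deviation as dispersion. `buildProfile()` then applies the titration
rules and computes the derived metrics:

* viability index `VI_R = 1 - (J_ce5S - J_ce4Rot) / (J_1Dig - J_2Ama)`,
  reported clipped to [0, 1] with the raw value attached;
* cytochrome-c control efficiency
  `j_c = (J_1c - J_1Dig) / (J_1c - J_2Ama)`;
* flux control ratios `R/E`, `L/E`, `S_E/E` with the living-cell ET
  capacity `E_ce3U` as reference — an internal normalization independent
  of cell count;
* effective concentrations: oligomycin by a stabilization rule (smallest
  concentration after which every later step changes flow by strictly
  less than 5%), FCCP and digitonin by argmax with the lowest
  concentration as tie-break (the conventional "minimal dose achieving
  maximal flux" optimum);
* residual-corrected flows (state minus Rox, floored at 0 and flagged)
  reported alongside raw flows; `VI_R` and `j_c` always use raw flows
  because their formulas embed their own baselines.

Two deliberate estimator behaviours are worth knowing. First, the
measured 2Ama flux can come out slightly negative under sensor noise
(the true residual flux is of the same order as the estimator's noise);
since residual consumption is physically non-negative the profile clamps
it to zero and flags the run. Second, the oligomycin stabilization rule
is noise-limited at LEAK-scale flows: with 0.2 umol/L sensor noise the
relative step-to-step changes near LEAK are dominated by estimation
noise, so per-run effective oligomycin concentrations from noisy traces
tend toward the last titrated step. On noiseless traces the detector is
exact, and the FCCP/digitonin argmax detectors are robust in both
regimes.

## Cohort analysis

Group contrasts are reported as ratio of group medians (matching
median/IQR reporting) with seeded bootstrap percentile intervals;
per-donor pairing is available through the Wilcoxon matched-pairs
signed-rank test, and one-way ANOVA with Tukey comparisons across the
three methods — both delegated to the standard stats routines, not
re-derived.

The activation-vs-respiration relation uses an axis-symmetric dual
regression: the ordinary Y-on-X line, the ordinate projection of the
X-on-Y line (slope `var(y)/cov(x,y)` in Y-on-X coordinates), and a mean
regression line. The mean line is implemented as the geometric mean of
the two slopes — the standardized major axis, `sign(cov) sd(y)/sd(x)` —
because a geometric-mean line is the only slope choice that is exactly
self-consistent under axis inversion; an arithmetic mean of slopes is
not. All three lines pass through the centroid, and `r^2` is invariant
under swapping the axes (asserted to 1e-12 in the property tests).

## What the simulator does and does not emulate

The generator reproduces: 2 s sampling, piecewise respiratory states
with transition ramps, linear instrumental background, sensor noise, a
planted dead-cell fraction visible only through the succinate module,
log-normal donor variation, multiplicative method effects including
scaled titration optima, and activation markers correlated with the
S-pathway flux control ratio at a tuned r^2.

It does not emulate: chamber reoxygenation, O2 solubility and
temperature corrections (traces are assumed already calibrated to
umol/L), fluorometric channels, drift beyond the linear background,
cell sedimentation or clumping, real dose-response curvature
(responses are piecewise linear by construction), or donor covariates
(age, BMI, medication). Passing recovery tests therefore demonstrates
that the analysis chain is correct and unbiased under the stated model,
not that it is robust to every artifact of bench data; in particular the
titration detectors see the planted optima on their own grid, so their
"exact recovery" is a consistency property, not an instrument
validation.

## Numerical choices

* Closed-form per-segment integration (no ODE solver); a guard nudges
  the ramp time constant if it ever resonates with the background rate.
* Trace times must be uniform to 1e-6 s; file round trips write floats
  with 17 significant digits so write-read is bit-exact.
* Oligomycin stabilization uses a strictly-less 5% boundary: a step that
  changes flow by exactly 5% does not count as stable.
* Argmax ties in FCCP/digitonin titrations resolve to the lowest
  concentration.
* Flows scale out of every derived ratio: metrics are identical for
  per-cell and volume-specific inputs (property-tested).
* Test problem sizes: cohort recovery uses 29 donors x 2 methods x 10
  seeds at sensor noise 0.2 umol/L; the activation calibration uses 17
  donors x 3 methods x 20 seeds on generator ground truth.

## Trace file dialect

One plain-text file per run:

```
#respilab-trace v1
#meta,donor_id,D01
#meta,method,DC
#meta,n_cells,1.08e+08
#meta,...chamber parameters...
#event,180,ce1P,pyruvate,10,mmol/L,1
time_s,o2_conc
0,191
2,190.95...
```

`#meta` lines carry run metadata (donor, method, cell count, chamber
geometry, background coefficients); `#event` lines embed the titration
table (time, state label, substance, cumulative concentration, units,
step index) so a single file is portable. Instrument exports can be
converted by mapping the software's time and concentration columns to
`time_s`/`o2_conc` and its event marks to `#event` lines; the
proprietary binary format itself is not parsed.

## A complete run

```{r, eval = FALSE}
library(respilab)
sp  <- cellSampleParams()                 # DC defaults
run <- simulateTrace(ccvProtocol(sp), sp, chamberConfig(), noiseParams(0))
prof <- analyzeTrace(run$trace)
profileMetrics(prof)

# whole cohort, with planted method effects, analyzed end to end
sim <- simulateCohort(nDonors = 6, sigmaO2 = 0.2, seed = 42)
rec <- analyzeCohort(lapply(sim$runs, `[[`, "trace"))$records
summarizeGroups(rec, "flow_1Dig", seed = 1)
```

## Limitations

Simulated effective concentrations land on the protocol's titration
grid, so fold-changes between methods are recovered to within one grid
step, not exactly, unless the planted optimum is a grid multiple. The
oligomycin stabilization rule needs either low noise or flux well above
the noise floor. The activation model generates a single marker family
with one planted correlation; it is a calibration target, not a model of
platelet biology. Cohort records are cross-sectionally exchangeable —
there is no longitudinal or batch structure.
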