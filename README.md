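# respilab

Simulation and analysis of high-resolution respirometry (HRR)
coupling-control protocols on human platelets.

HRR measures cellular oxygen consumption as the decline of dissolved O2
in a closed oxygraph chamber while a substrate-uncoupler-inhibitor
titration (SUIT) protocol steps the cells through defined respiratory
states — ROUTINE respiration *R*, LEAK respiration *L* after oligomycin,
ET capacity *E* at optimum FCCP, succinate-linked states around digitonin
permeabilization, and residual consumption *Rox* after antimycin A. The
package is built for the comparison of platelet isolation methods
(density-gradient centrifugation DC, apheresis PA, washed apheresis WA):
it simulates chamber traces with planted method effects, recovers
per-state per-cell oxygen flows from any trace in its CSV dialect, and
derives the study-level metrics.

For a chamber trace c(t) sampled every 2 s, the analysis chain computes

* volume-specific flux `J_V(t) = -1000 * dc/dt` (windowed least-squares
  slope, background-corrected by `J_bg(c) = a + b c`),
* per-cell oxygen flow `I_O2 = J_V / C_cell` in amol·s⁻¹·x⁻¹ (cell
  concentration `C_cell` in 10⁶ x·mL⁻¹),
* flux control ratios `FCR = I_state / E_ce3U`,
* the respirometric viability index
  `VI_R = 1 − (J_ce5S − J_ce4Rot) / (J_1Dig − J_2Ama)`,
* the cytochrome-c control efficiency
  `j_c = (J_1c − J_1Dig) / (J_1c − J_2Ama)`,
* effective oligomycin / FCCP / digitonin concentrations from per-run
  titration series, and
* cohort contrasts (ratio of group medians with bootstrap intervals,
  Wilcoxon / ANOVA glue) plus an axis-symmetric dual regression of
  platelet activation (%CD62P) against the S-pathway FCR.

## Worked example

A noiseless DC run, simulated and analyzed end to end:

```r
library(respilab)
sp   <- cellSampleParams()                 # DC sample, dead fraction 0.13
run  <- simulateTrace(ccvProtocol(sp), sp, chamberConfig(), noiseParams(0))
run$trace
#> TraceSeries: 1081 samples, 0-2160 s, 15 events | donor sim (DC)
#>   O2: 191.0 -> 122.9 umol/L
profileMetrics(analyzeTrace(run$trace))
#> MetricSet:
#>   FCR  R/E 0.515  L/E 0.179  S/E 1.299
#>   VI_R 0.870  j_c 0.000
#>   effective conc: oligomycin 10, FCCP 1, digitonin 5
```

`VI_R = 0.870` recovers the planted 13% dead-cell fraction; the
effective concentrations equal the planted titration optima; S/E above 1
reflects an S-linked ET capacity exceeding the ET capacity of living
cells. A small noisy cohort with the planted apheresis effects:

```r
sim <- simulateCohort(nDonors = 6, sigmaO2 = 0.2, seed = 42)
rec <- analyzeCohort(lapply(sim$runs, `[[`, "trace"))$records
s   <- summarizeGroups(rec, "flow_1Dig", seed = 1)   # S-linked ET capacity
s$ratios
#>  comparison     ratio     ci_lo     ci_hi
#>       PA/DC 0.6262444 0.4849454 0.6839448
#>       WA/DC 1.0391756 0.7825856 1.2019257
```

The apheresis group's succinate-linked capacity falls toward the planted
57% of DC (6 donors; larger cohorts tighten it), while washing restores
DC behaviour (WA/DC near 1).

`runPipeline()` chains everything from a YAML or list configuration, and
`inst/scripts/respilab.R` exposes `simulate`, `analyze`, `cohort` and
`all` subcommands for shell use. The methods vignette
(`vignettes/respirometry-pipeline.Rmd`) documents the forward model, the
estimator choices and the trace CSV dialect.

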