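#' @include AllClasses.R simulate.R
NULL

.default_method_effects <- function() {
  data.frame(
    method = c("DC", "PA", "WA"),
    rMult = c(1, 1.22, 1), eMult = c(1, 1.16, 1), sMult = c(1, 0.57, 1),
    omyMult = c(1, 2.2, 1), fccpMult = c(1, 3.5, 1), digMult = c(1, 2.5, 1),
    deadFraction = c(0.13, 0.17, 0.13),
    stringsAsFactors = FALSE)
}

#' Construct the generative truth of a donor cohort
#'
#' Defaults plant the study's contrasts between platelet isolation
#' methods: relative to density-gradient centrifugation (DC), apheresis
#' (PA) samples get 22% higher ROUTINE respiration, 16% higher ET
#' capacity, an S-linked ET capacity at 57% of DC, effective oligomycin /
#' FCCP / digitonin concentrations raised 2.2- / 3.5- / 2.5-fold, and a
#' slightly larger dead-cell fraction (0.17 vs 0.13, i.e. planted
#' viability 83% vs 87%). Washed-apheresis (WA) effects equal DC: washing
#' restores DC behaviour. Donor baselines vary log-normally (median 1)
#' with `donorCV`; each record additionally gets independent log-normal
#' pathway-level variation with `pathwayCV` so flux control ratios vary
#' within a method.
#'
#' The activation model generates %CD62P-positive as
#' `intercept + slope * FCR_S + noise`, with the noise variance tuned so
#' the population squared correlation equals `targetR2`.
#'
#' @param baseline DC baseline [CellSampleParams-class].
#' @param methodEffects data.frame of per-method multipliers; see
#'   [CohortTruth-class].
#' @param donorCV donor-level log-normal coefficient of variation.
#' @param pathwayCV per-record pathway-level coefficient of variation.
#' @param activation list(intercept, slope, targetR2).
#' @return a [CohortTruth-class].
#' @export
cohortTruth <- function(baseline = cellSampleParams(),
                        methodEffects = .default_method_effects(),
                        donorCV = 0.15, pathwayCV = 0.10,
                        activation = list(intercept = 20, slope = 25,
                                          targetR2 = 0.27)) {
  new("CohortTruth", baseline = baseline, methodEffects = methodEffects,
      donorCV = donorCV, pathwayCV = pathwayCV, activation = activation)
}

## log-normal multiplier with median 1 and coefficient of variation cv
.ln_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog))
}

#' Simulate a donor cohort of SUIT runs
#'
#' Draws `nDonors` donors; each donor contributes one run per isolation
#' method, all sharing the donor's log-normal baseline with the method's
#' multiplicative effects applied to the ROUTINE, ET-capacity and
#' S-pathway flows, to the three effective titration concentrations, and
#' to the dead-cell fraction. Activation markers (%CD62P, CD62P MFI,
#' %CD63, CD63 MFI) are emitted per record, %CD62P tied linearly to the
#' planted S-pathway flux control ratio with noise tuned to the truth's
#' target squared correlation.
#'
#' @param nDonors number of donors (>= 2).
#' @param truth a [CohortTruth-class].
#' @param chamber a [ChamberConfig-class].
#' @param sigmaO2 sensor noise SD, umol L^-1.
#' @param seed integer seed for the whole cohort (donors, noise, markers).
#' @param methods subset of c("DC", "PA", "WA") to simulate.
#' @param emitTraces when FALSE only the ground-truth record table is
#'   generated (fast; e.g. for calibrating the activation model).
#' @param stateDuration,stepDuration,rampDuration protocol timing, s.
#' @return list with `runs` (named list of `simulateTrace()` results,
#'   keyed `donor.method`; empty when `emitTraces = FALSE`), `records`
#'   (ground-truth data.frame: one row per donor x method with planted
#'   per-cell flows, optima, dead fraction, planted FCR_S and activation
#'   markers) and `truth` (the [CohortTruth-class] used).
#' @export
simulateCohort <- function(nDonors = 29, truth = cohortTruth(),
                           chamber = chamberConfig(), sigmaO2 = 0.2,
                           seed = 1L, methods = c("DC", "PA", "WA"),
                           emitTraces = TRUE, stateDuration = 180,
                           stepDuration = 120, rampDuration = 20) {
  stopifnot(is(truth, "CohortTruth"))
  if (!is.numeric(nDonors) || nDonors < 2) stop("nDonors must be >= 2")
  nDonors <- as.integer(nDonors)
  methods <- match.arg(methods, c("DC", "PA", "WA"), several.ok = TRUE)
  withr::with_seed(as.integer(seed), {
    base <- truth@baseline
    me <- truth@methodEffects
    g_donor <- .ln_mult(nDonors, truth@donorCV)
    rows <- list(); runs <- list()
    for (d in seq_len(nDonors)) {
      donor <- sprintf("D%02d", d)
      for (m in methods) {
        eff <- me[me$method == m, ]
        jit <- .ln_mult(3, truth@pathwayCV)   # R, E, S pathway jitter
        sf <- base@stateFlux
        g <- g_donor[d]
        sf[["ce1"]]  <- sf[["ce1"]]  * eff$rMult * g * jit[1]
        sf[["ce1P"]] <- sf[["ce1P"]] * eff$rMult * g * jit[1]
        sf[["ce2Omy"]] <- sf[["ce2Omy"]] * g
        sf[["ce3U"]] <- max(sf[["ce3U"]] * eff$eMult * g * jit[2],
                            sf[["ce1P"]])          # keep E >= R
        sf[["1Dig"]] <- sf[["1Dig"]] * eff$sMult * g * jit[3]
        sp <- cellSampleParams(
          nCells = base@nCells, deadFraction = eff$deadFraction,
          stateFlux = sf, roxFlow = base@roxFlow * g,
          omyThreshold = base@omyThreshold * eff$omyMult,
          fccpOptimum = base@fccpOptimum * eff$fccpMult,
          digOptimum = base@digOptimum * eff$digMult,
          omyStep = base@omyStep, fccpStep = base@fccpStep,
          digStep = base@digStep,
          overstepDecline = base@overstepDecline,
          cytcDelta = base@cytcDelta)
        rows[[length(rows) + 1L]] <- data.frame(
          donor_id = donor, method = m,
          r_ce1 = sf[["ce1"]], r_ce1P = sf[["ce1P"]], l_ce2Omy = sf[["ce2Omy"]],
          e_ce3U = sf[["ce3U"]], s_1Dig = sf[["1Dig"]],
          rox = base@roxFlow * g, dead_fraction = eff$deadFraction,
          omy_threshold = sp@omyThreshold, fccp_optimum = sp@fccpOptimum,
          dig_optimum = sp@digOptimum,
          fcr_s_true = sf[["1Dig"]] / sf[["ce3U"]],
          stringsAsFactors = FALSE)
        if (emitTraces) {
          pr <- ccvProtocol(sp, stateDuration = stateDuration,
                            stepDuration = stepDuration)
          runs[[paste(donor, m, sep = ".")]] <-
            simulateTrace(pr, sp, chamber, noiseParams(sigmaO2, NA),
                          rampDuration = rampDuration,
                          donorId = donor, method = m)
        }
      }
    }
    records <- do.call(rbind, rows)
    act <- truth@activation
    signal <- act$intercept + act$slope * records$fcr_s_true
    vs <- stats::var(act$slope * records$fcr_s_true)
    sigma_act <- sqrt(vs * (1 / act$targetR2 - 1))
    records$cd62p_pct <- pmin(pmax(
      signal + stats::rnorm(nrow(records), 0, sigma_act), 0), 100)
    records$cd62p_mfi <- exp(stats::rnorm(nrow(records), log(6), 0.25))
    records$cd63_pct <- pmin(pmax(
      0.5 * records$cd62p_pct + stats::rnorm(nrow(records), 0, 5), 0), 100)
    records$cd63_mfi <- exp(stats::rnorm(nrow(records), log(4), 0.25))
    list(runs = runs, records = records, truth = truth)
  })
}
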