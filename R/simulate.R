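#' @include AllClasses.R chamber.R protocol.R
NULL

#' Construct planted cell-sample parameters
#'
#' Defaults describe a density-gradient-centrifugation (DC) platelet sample:
#' 108e6 platelets (200e6 cells per mL in a 0.54 mL chamber), a 13%
#' dead-cell fraction, per-cell flows with the coupling order
#' E >= R >= L, an S-linked ET capacity above the ET capacity of living
#' cells, and effective titration concentrations of 10 nmol/L oligomycin,
#' 1.0 umol/L FCCP and 5.0 ug/mL digitonin.
#'
#' `stateFlux` entries are population-average mitochondrial/endogenous
#' per-cell flows (amol s^-1 x^-1) excluding the residual flow `roxFlow`,
#' which the simulator adds to every state. The `ce4Rot` and `ce5S`
#' (intact-cell) flows default to 0: after rotenone, with no permeant
#' substrate, the cellular flux of intact cells reduces to the residual
#' flow, and externally added succinate only reaches the mitochondria of
#' membrane-damaged cells.
#'
#' @param nCells platelets added to the chamber.
#' @param deadFraction fraction of membrane-permeable ("dead") cells.
#' @param stateFlux named per-cell flows, amol s^-1 x^-1; see Details.
#' @param roxFlow residual per-cell flow after antimycin A.
#' @param omyThreshold,fccpOptimum,digOptimum effective concentrations
#'   (nmol/L, umol/L, ug/mL).
#' @param omyStep,fccpStep,digStep titration step sizes.
#' @param overstepDecline fractional flow loss per step beyond the FCCP or
#'   digitonin optimum.
#' @param cytcDelta per-cell flow gained on cytochrome-c addition.
#' @return a [CellSampleParams-class].
#' @export
cellSampleParams <- function(nCells = 108e6, deadFraction = 0.13,
                             stateFlux = c(ce1 = 0.10, ce1P = 0.13,
                                           ce2Omy = 0.04, ce3U = 0.26,
                                           ce4Rot = 0, ce5S = 0,
                                           "1Dig" = 0.34),
                             roxFlow = 0.008,
                             omyThreshold = 10, fccpOptimum = 1.0,
                             digOptimum = 5.0,
                             omyStep = 5, fccpStep = 0.5, digStep = 2.5,
                             overstepDecline = 0.05, cytcDelta = 0) {
  new("CellSampleParams", nCells = nCells, deadFraction = deadFraction,
      stateFlux = stateFlux, roxFlow = roxFlow, omyThreshold = omyThreshold,
      fccpOptimum = fccpOptimum, digOptimum = digOptimum, omyStep = omyStep,
      fccpStep = fccpStep, digStep = digStep,
      overstepDecline = overstepDecline, cytcDelta = cytcDelta)
}

#' Per-cell flow response to a titration
#'
#' Dose-response shapes of the three titrated substances, for live cells
#' with intact membranes: oligomycin descends linearly from ROUTINE
#' (ce1P) to LEAK, reached at the sample's `omyThreshold` and flat beyond;
#' FCCP rises linearly from LEAK to ET capacity at `fccpOptimum` and
#' declines by `overstepDecline` of E per further step (over-uncoupling);
#' digitonin raises the succinate-supported flow linearly from 0 to the
#' S-linked capacity at `digOptimum`, declining by `overstepDecline` per
#' further step (mitochondrial damage).
#'
#' @param substance `"oligomycin"`, `"FCCP"` or `"digitonin"`.
#' @param cumulativeConc cumulative concentration(s), >= 0, in the
#'   substance's native units (nmol/L, umol/L, ug/mL).
#' @param sample a [CellSampleParams-class].
#' @return per-cell flow(s) in amol s^-1 x^-1 (excluding residual flow).
#' @examples
#' sp <- cellSampleParams()
#' simulateTitrationResponse("FCCP", sp@fccpOptimum, sp)  # exactly E
#' @export
simulateTitrationResponse <- function(substance, cumulativeConc, sample) {
  stopifnot(is(sample, "CellSampleParams"))
  if (any(!is.finite(cumulativeConc)) || any(cumulativeConc < 0))
    stop("cumulativeConc must be finite and >= 0")
  sf <- sample@stateFlux
  q <- cumulativeConc
  dec <- sample@overstepDecline
  switch(tolower(substance),
    oligomycin = {
      R <- sf[["ce1P"]]; L <- sf[["ce2Omy"]]
      R - (R - L) * pmin(q / sample@omyThreshold, 1)
    },
    fccp = {
      L <- sf[["ce2Omy"]]; E <- sf[["ce3U"]]; opt <- sample@fccpOptimum
      ifelse(q <= opt,
             L + (E - L) * q / opt,
             pmax(E * (1 - dec * (q - opt) / sample@fccpStep), 0))
    },
    digitonin = {
      S <- sf[["1Dig"]]; opt <- sample@digOptimum
      ifelse(q <= opt,
             S * q / opt,
             pmax(S * (1 - dec * (q - opt) / sample@digStep), 0))
    },
    stop("unknown substance: ", substance))
}

## Population succinate-supported per-cell flow during digitonin titration:
## intact cells follow the digitonin response, already-permeable (dead)
## cells are at full S capacity until overstepping damages everyone.
.dig_population_flow <- function(q, sample) {
  S <- sample@stateFlux[["1Dig"]]
  d <- sample@deadFraction
  live <- simulateTitrationResponse("digitonin", q, sample)
  dead <- if (q <= sample@digOptimum) S else live
  (1 - d) * live + d * dead
}

## Per-cell mitochondrial/endogenous flow (excl. residual) of one protocol
## segment. `lastDig` is the population flow at the final digitonin step,
## carried into the cytochrome-c state.
.segment_cell_flow <- function(label, q, sample, lastDig) {
  sf <- sample@stateFlux
  d <- sample@deadFraction
  switch(label,
    ce1   = sf[["ce1"]],
    ce1P  = sf[["ce1P"]],
    ce2Omy = simulateTitrationResponse("oligomycin", q, sample),
    ce3U  = simulateTitrationResponse("FCCP", q, sample),
    ce4Rot = sf[["ce4Rot"]],
    ce5S  = sf[["ce5S"]] + d * sf[["1Dig"]],
    "1Dig" = .dig_population_flow(q, sample),
    "1c"  = (if (is.na(lastDig)) sf[["1Dig"]] else lastDig) + sample@cytcDelta,
    "2Ama" = 0,
    stop("unknown state label: ", label))
}

## Exact solution of dc/dt = -(Jc(t) + a + b c)/1000 on one segment, with
## Jc(t) = j_target + (j_prev - j_target) exp(-t/tau). `t_rel` vectorized.
.integrate_segment <- function(c0, t_rel, j_target, j_prev, tau, a, b) {
  k <- b / 1000
  m0 <- (j_target + a) / 1000
  m1 <- if (tau > 0) (j_prev - j_target) / 1000 else 0
  if (abs(k) < 1e-14) {
    out <- c0 - m0 * t_rel
    if (m1 != 0) out <- out - m1 * tau * (1 - exp(-t_rel / tau))
    out
  } else {
    if (tau > 0 && abs(1 / tau - k) < 1e-12) tau <- tau * (1 + 1e-9)
    cp1 <- -m0 / k
    cp2 <- if (m1 != 0) m1 / (1 / tau - k) else 0
    (c0 - cp1 - cp2) * exp(-k * t_rel) + cp1 +
      if (m1 != 0) cp2 * exp(-t_rel / tau) else 0
  }
}

#' Simulate one chamber O2 trace under a SUIT protocol
#'
#' Forward model of a closed oxygraph chamber: between titration events the
#' O2 concentration obeys dc/dt = -(J_cells(t) + J_bg(c)) / 1000 in
#' umol L^-1 s^-1, where J_cells is the planted volume-specific cellular
#' flux of the active protocol state (pmol s^-1 mL^-1, the per-cell state
#' flow plus residual flow times the cell concentration) and
#' J_bg(c) = a + b c is the linear instrumental background. Each event is
#' followed by an exponential transition ramp of nominal duration
#' `rampDuration` (five time constants). The equation is integrated in
#' closed form per segment, then Gaussian sensor noise is added.
#'
#' Before digitonin, externally added succinate (state ce5S) drives
#' respiration only in the dead-cell fraction; after permeabilization
#' (1Dig) all cells respire on succinate; after antimycin A (2Ama) only
#' the residual flow remains.
#'
#' If the chamber would run anoxic the trace is truncated at the first
#' non-positive sample and flagged.
#'
#' @param protocol a [SuitProtocol-class] (or event data.frame).
#' @param sample a [CellSampleParams-class].
#' @param chamber a [ChamberConfig-class].
#' @param noise a [NoiseParams-class].
#' @param rampDuration nominal post-event transition duration, s.
#' @param dilution when TRUE and the event table carries an
#'   `injection_ul` column, each injection instantaneously dilutes both
#'   the O2 concentration and the cell concentration by
#'   `1 - injection_ul/1000/workingVolume` (injectate assumed O2- and
#'   cell-free, displaced volume leaves through the stopper capillary).
#'   Off by default: titration volumes are below 1% of the chamber.
#' @param donorId,method metadata stored in the trace.
#' @return a list with elements `trace` (a [TraceSeries-class]) and
#'   `truth` (data.frame of exact post-ramp cellular volume-specific flux
#'   `j_cells` and per-cell flow `i_o2` for every state/step, with the
#'   planted sample parameters in its attributes).
#' @examples
#' pr <- suitProtocol(data.frame(time_s = 0, state_label = "ce1",
#'   substance = "sample", cumulative_conc = NA, units = "",
#'   step_index = 1L), duration_s = 300)
#' sp <- cellSampleParams(stateFlux = c(ce1 = 0.1, ce1P = 0.13,
#'   ce2Omy = 0.04, ce3U = 0.26, ce4Rot = 0, ce5S = 0, "1Dig" = 0.34))
#' run <- simulateTrace(pr, sp, chamberConfig(backgroundA = 0,
#'   backgroundB = 0), noiseParams(0))
#' head(o2Concentration(run$trace))
#' @export
simulateTrace <- function(protocol, sample, chamber = chamberConfig(),
                          noise = noiseParams(), rampDuration = 20,
                          dilution = FALSE, donorId = "sim", method = "DC") {
  if (is.data.frame(protocol)) protocol <- suitProtocol(protocol)
  stopifnot(is(protocol, "SuitProtocol"), is(sample, "CellSampleParams"),
            is(chamber, "ChamberConfig"), is(noise, "NoiseParams"))
  ev <- protocol@events
  conc <- cellConcentration(sample@nCells, chamber)
  dt <- chamber@sampleInterval
  a <- chamber@backgroundA
  b <- chamber@backgroundB
  tau <- if (rampDuration > 0) rampDuration / 5 else 0

  ## per-event dilution factors (identity unless enabled)
  dil <- rep(1, nrow(ev))
  if (dilution && "injection_ul" %in% names(ev)) {
    v <- ev$injection_ul
    v[is.na(v)] <- 0
    dil <- 1 - v / 1000 / chamber@workingVolume
    if (any(dil <= 0)) stop("injection volume exceeds the chamber volume")
  }
  cellDil <- cumprod(dil)   # cells diluted by every injection so far

  ## per-segment planted cellular volume flux (incl. residual, excl.
  ## instrumental background)
  lastDig <- NA_real_
  jseg <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    f <- .segment_cell_flow(ev$state_label[i], ev$cumulative_conc[i],
                            sample, lastDig)
    if (ev$state_label[i] == "1Dig") lastDig <- f
    jseg[i] <- conc * cellDil[i] * (f + sample@roxFlow)
  }

  tgrid <- seq(0, protocol@duration_s, by = dt)
  o2 <- numeric(length(tgrid))
  seg_end <- c(ev$time_s[-1], protocol@duration_s)
  if (ev$time_s[1] > tgrid[1])
    stop("simulated duration must start at or before the first event")

  c_cur <- chamber@o2Init
  idx_before <- tgrid <= ev$time_s[1] + 1e-12
  o2[idx_before] <- chamber@o2Init   # pre-protocol samples, if any
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$time_s[i]; t1 <- seg_end[i]
    c_cur <- c_cur * dil[i]   # instantaneous mixing at the injection
    jp <- if (i == 1) jseg[i] else jseg[i - 1]   # no ramp into the run
    sel <- tgrid > t0 + 1e-12 & tgrid <= t1 + 1e-12
    if (any(sel))
      o2[sel] <- .integrate_segment(c_cur, tgrid[sel] - t0, jseg[i], jp,
                                    tau, a, b)
    c_cur <- .integrate_segment(c_cur, t1 - t0, jseg[i], jp, tau, a, b)
  }

  truncated <- FALSE
  if (any(o2 <= 0)) {
    cut <- which(o2 <= 0)[1] - 1L
    if (cut < 2L) stop("chamber anoxic before the second sample")
    tgrid <- tgrid[seq_len(cut)]
    o2 <- o2[seq_len(cut)]
    truncated <- TRUE
    warning("chamber ran anoxic; trace truncated at t = ", tgrid[cut], " s")
  }

  if (noise@sigmaO2 > 0) {
    addNoise <- function() o2 + stats::rnorm(length(o2), 0, noise@sigmaO2)
    o2 <- if (!is.na(noise@seed)) withr::with_seed(noise@seed, addNoise())
          else addNoise()
  }

  keep <- ev$time_s <= tgrid[length(tgrid)] + 1e-9
  meta <- list(donor_id = donorId, method = method, n_cells = sample@nCells,
               working_volume = chamber@workingVolume,
               dead_volume = chamber@deadVolume,
               sample_interval = dt, background_a = a, background_b = b,
               o2_init = chamber@o2Init, temperature = chamber@temperature)
  trace <- new("TraceSeries", time = tgrid, o2 = o2,
               events = ev[keep, , drop = FALSE], metadata = meta,
               truncated = truncated)

  truth <- data.frame(state_label = ev$state_label,
                      step_index = ev$step_index,
                      cumulative_conc = ev$cumulative_conc,
                      units = ev$units, substance = ev$substance,
                      j_cells = jseg, i_o2 = jseg / conc,
                      t_start = ev$time_s, t_end = seg_end,
                      stringsAsFactors = FALSE)
  attr(truth, "dead_fraction") <- sample@deadFraction
  attr(truth, "rox_flow") <- sample@roxFlow
  attr(truth, "omy_threshold") <- sample@omyThreshold
  attr(truth, "fccp_optimum") <- sample@fccpOptimum
  attr(truth, "dig_optimum") <- sample@digOptimum
  attr(truth, "cell_concentration") <- conc
  attr(truth, "ramp_tau") <- tau
  list(trace = trace, truth = truth)
}
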