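#' @import methods
NULL

## SUIT-003 CCV state vocabulary, in protocol order.
.STATE_LABELS <- c("ce1", "ce1P", "ce2Omy", "ce3U", "ce4Rot",
                   "ce5S", "1Dig", "1c", "2Ama")

## States titrated in several steps.
.TITRATION_STATES <- c("ce2Omy", "ce3U", "1Dig")

## States that must be present before a profile can be assembled.
.MANDATORY_STATES <- c("ce1P", "ce3U", "1Dig", "2Ama")

.EVENT_COLS <- c("time_s", "state_label", "substance",
                 "cumulative_conc", "units", "step_index")

.scalarNum <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

#' ChamberConfig: oxygraph chamber geometry and instrument parameters
#'
#' Describes one closed oxygraph chamber: the working volume enclosed when
#' the stopper is inserted, the dead volume of the stopper capillary over
#' which the cell suspension also distributes, the recording interval, the
#' linear instrumental background flux, and the oxygen concentration at the
#' start of the run.
#'
#' @slot workingVolume chamber working volume in mL.
#' @slot deadVolume stopper-capillary dead volume in mL.
#' @slot temperature assay temperature in degrees C (informational).
#' @slot sampleInterval recording interval in s.
#' @slot backgroundA background flux intercept, pmol s^-1 mL^-1.
#' @slot backgroundB background flux slope per umol L^-1 of O2.
#' @slot o2Init starting O2 concentration, umol L^-1.
#' @exportClass ChamberConfig
setClass("ChamberConfig",
  representation(workingVolume = "numeric", deadVolume = "numeric",
                 temperature = "numeric", sampleInterval = "numeric",
                 backgroundA = "numeric", backgroundB = "numeric",
                 o2Init = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("workingVolume", "deadVolume", "temperature",
                "sampleInterval", "backgroundA", "backgroundB", "o2Init"))
      if (!.scalarNum(slot(object, s)))
        msg <- c(msg, paste0("'", s, "' must be a finite numeric scalar"))
    if (length(msg)) return(msg)
    if (object@workingVolume <= 0) msg <- c(msg, "workingVolume must be > 0")
    if (object@deadVolume < 0) msg <- c(msg, "deadVolume must be >= 0")
    if (object@sampleInterval <= 0) msg <- c(msg, "sampleInterval must be > 0")
    if (object@o2Init <= 0) msg <- c(msg, "o2Init must be > 0")
    if (length(msg)) msg else TRUE
  })

#' SuitProtocol: ordered titration schedule of one SUIT run
#'
#' Holds the ordered table of protocol events (one row per titration) and
#' the total run duration. Event rows carry the time of the addition, the
#' respiratory state it establishes, the substance, the cumulative
#' concentration reached in the chamber, its units, and a step index for
#' multi-step titrations.
#'
#' @slot events data.frame with columns `time_s`, `state_label`,
#'   `substance`, `cumulative_conc`, `units`, `step_index`.
#' @slot duration_s total simulated/recorded duration in s.
#' @exportClass SuitProtocol
setClass("SuitProtocol",
  representation(events = "data.frame", duration_s = "numeric"),
  validity = function(object) {
    ev <- object@events
    msg <- character()
    missing_cols <- setdiff(.EVENT_COLS, names(ev))
    if (length(missing_cols))
      return(paste("events table lacks columns:",
                   paste(missing_cols, collapse = ", ")))
    if (nrow(ev) == 0) return("protocol has no events")
    if (any(diff(ev$time_s) <= 0))
      msg <- c(msg, "event times must be strictly increasing")
    bad <- setdiff(ev$state_label, .STATE_LABELS)
    if (length(bad))
      msg <- c(msg, paste("unknown state labels:", paste(bad, collapse = ", ")))
    rank <- match(ev$state_label, .STATE_LABELS)
    if (!any(is.na(rank)) && any(diff(rank) < 0))
      msg <- c(msg, "state labels out of protocol order")
    for (sub in unique(ev$substance)) {
      cc <- ev$cumulative_conc[ev$substance == sub]
      cc <- cc[!is.na(cc)]
      if (length(cc) > 1 && any(diff(cc) < 0))
        msg <- c(msg, paste0("cumulative concentration of '", sub,
                             "' must be non-decreasing"))
    }
    if (!.scalarNum(object@duration_s) ||
        object@duration_s < max(ev$time_s))
      msg <- c(msg, "duration_s must cover the last event")
    if (length(msg)) msg else TRUE
  })

#' CellSampleParams: planted respiratory parameters of one cell sample
#'
#' Ground-truth description of the cells in one chamber: how many platelets
#' were added, what fraction of them has a permeable (damaged) plasma
#' membrane, the per-cell oxygen flow of each protocol state, the residual
#' (non-mitochondrial) flow, and the effective concentrations at which the
#' three titrations saturate. Per-cell flows are population-average
#' mitochondrial/endogenous flows in amol s^-1 x^-1, excluding the residual
#' flow which is added to every state.
#'
#' @slot nCells number of platelets added to the chamber.
#' @slot deadFraction fraction of membrane-permeable cells in [0, 1].
#' @slot stateFlux named numeric: per-cell flow of states `ce1`, `ce1P`,
#'   `ce2Omy` (LEAK at the effective oligomycin concentration), `ce3U`
#'   (ET capacity at the uncoupler optimum), `ce4Rot`, `ce5S` (intact
#'   cells), `1Dig` (S-linked ET capacity after permeabilization).
#' @slot roxFlow residual per-cell flow after antimycin A, amol s^-1 x^-1.
#' @slot omyThreshold effective oligomycin concentration, nmol L^-1.
#' @slot fccpOptimum optimum FCCP concentration, umol L^-1.
#' @slot digOptimum optimum digitonin concentration, ug mL^-1.
#' @slot omyStep,fccpStep,digStep titration step sizes in the same units.
#' @slot overstepDecline fractional flow loss per titration step beyond the
#'   uncoupler/digitonin optimum (over-uncoupling, membrane damage).
#' @slot cytcDelta per-cell flow gained on cytochrome-c addition (0 for an
#'   intact outer mitochondrial membrane).
#' @exportClass CellSampleParams
setClass("CellSampleParams",
  representation(nCells = "numeric", deadFraction = "numeric",
                 stateFlux = "numeric", roxFlow = "numeric",
                 omyThreshold = "numeric", fccpOptimum = "numeric",
                 digOptimum = "numeric", omyStep = "numeric",
                 fccpStep = "numeric", digStep = "numeric",
                 overstepDecline = "numeric", cytcDelta = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.scalarNum(object@nCells) || object@nCells <= 0)
      msg <- c(msg, "nCells must be > 0")
    if (!.scalarNum(object@deadFraction) || object@deadFraction < 0 ||
        object@deadFraction > 1)
      msg <- c(msg, "deadFraction must lie in [0, 1]")
    need <- c("ce1", "ce1P", "ce2Omy", "ce3U", "ce4Rot", "ce5S", "1Dig")
    miss <- setdiff(need, names(object@stateFlux))
    if (length(miss))
      msg <- c(msg, paste("stateFlux lacks:", paste(miss, collapse = ", ")))
    else {
      sf <- object@stateFlux
      if (any(!is.finite(sf)) || any(sf < 0))
        msg <- c(msg, "all state flows must be finite and >= 0")
      else if (!(sf[["ce3U"]] >= sf[["ce1P"]] &&
                 sf[["ce1P"]] >= sf[["ce2Omy"]]))
        msg <- c(msg, "coupling order violated: need E (ce3U) >= R (ce1P) >= L (ce2Omy)")
    }
    if (!.scalarNum(object@roxFlow) || object@roxFlow < 0)
      msg <- c(msg, "roxFlow must be >= 0")
    for (s in c("omyThreshold", "fccpOptimum", "digOptimum",
                "omyStep", "fccpStep", "digStep"))
      if (!.scalarNum(slot(object, s)) || slot(object, s) <= 0)
        msg <- c(msg, paste0("'", s, "' must be > 0"))
    if (!.scalarNum(object@overstepDecline) || object@overstepDecline < 0 ||
        object@overstepDecline >= 1)
      msg <- c(msg, "overstepDecline must lie in [0, 1)")
    if (!.scalarNum(object@cytcDelta) || object@cytcDelta < 0)
      msg <- c(msg, "cytcDelta must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' NoiseParams: measurement noise model of the simulated sensor
#'
#' @slot sigmaO2 Gaussian standard deviation added to each sampled O2
#'   concentration, umol L^-1.
#' @slot seed integer random seed (NA to draw from the current RNG stream).
#' @exportClass NoiseParams
setClass("NoiseParams",
  representation(sigmaO2 = "numeric", seed = "integer"),
  validity = function(object) {
    if (!is.numeric(object@sigmaO2) || length(object@sigmaO2) != 1L ||
        is.na(object@sigmaO2) || object@sigmaO2 < 0)
      return("sigmaO2 must be a single number >= 0")
    if (length(object@seed) != 1L) return("seed must be a single integer or NA")
    TRUE
  })

#' TraceSeries: one sampled chamber O2 trace with event marks
#'
#' The raw observable of a respirometry run: uniformly sampled O2
#' concentration, the titration event table, and run metadata (donor,
#' isolation method, cell count, chamber parameters).
#'
#' @slot time seconds from run start, uniformly spaced.
#' @slot o2 O2 concentration, umol L^-1.
#' @slot events event table (see [SuitProtocol-class]).
#' @slot metadata named list; must contain `donor_id`, `method`, `n_cells`
#'   and the chamber parameters.
#' @slot truncated TRUE when the simulated chamber ran anoxic and the trace
#'   was cut short.
#' @exportClass TraceSeries
setClass("TraceSeries",
  representation(time = "numeric", o2 = "numeric", events = "data.frame",
                 metadata = "list", truncated = "logical"),
  validity = function(object) {
    msg <- character()
    n <- length(object@time)
    if (n < 2) return("trace needs at least two samples")
    if (length(object@o2) != n) return("time and o2 lengths differ")
    dt <- diff(object@time)
    if (any(dt <= 0)) return("time must be strictly increasing")
    off <- which(abs(dt - dt[1]) > 1e-6)
    if (length(off))
      return(sprintf("non-uniform sampling first at index %d", off[1] + 1L))
    if (any(!is.finite(object@o2)))
      msg <- c(msg, "o2 concentrations must all be finite")
    ev <- object@events
    miss <- setdiff(.EVENT_COLS, names(ev))
    if (length(miss))
      return(paste("events table lacks columns:", paste(miss, collapse = ", ")))
    if (nrow(ev)) {
      bad <- setdiff(ev$state_label, .STATE_LABELS)
      if (length(bad))
        msg <- c(msg, paste("unknown state labels:",
                            paste(bad, collapse = ", ")))
      if (any(ev$time_s < object@time[1] - 1e-9) ||
          any(ev$time_s > object@time[n] + 1e-9))
        msg <- c(msg, "event times must lie within the recorded time range")
    }
    needMeta <- c("donor_id", "method", "n_cells",
                  "working_volume", "dead_volume", "sample_interval",
                  "background_a", "background_b", "o2_init")
    missMeta <- setdiff(needMeta, names(object@metadata))
    if (length(missMeta))
      msg <- c(msg, paste("metadata keys missing:",
                          paste(missMeta, collapse = ", ")))
    if (length(object@truncated) != 1L || is.na(object@truncated))
      msg <- c(msg, "truncated must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
  })

#' FluxSeries: volume-specific O2 flux derived from a trace
#'
#' @slot time seconds, same grid as the source trace.
#' @slot jv volume-specific flux, pmol s^-1 mL^-1 (consumption positive);
#'   NA at edge points without a full differentiation window.
#' @slot valid FALSE at edge points; such points carry no flux estimate.
#' @slot corrected TRUE after instrumental background subtraction.
#' @exportClass FluxSeries
setClass("FluxSeries",
  representation(time = "numeric", jv = "numeric", valid = "logical",
                 corrected = "logical"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@jv) != n || length(object@valid) != n)
      return("time, jv and valid must have equal length")
    if (any(object@valid & !is.finite(object@jv)))
      return("valid points must carry finite flux")
    if (length(object@corrected) != 1L) return("corrected must be a flag")
    TRUE
  })

#' MetricSet: derived respiratory metrics of one run
#'
#' Flux control ratios relative to ET capacity of living cells, the
#' respirometric viability index, the cytochrome-c control efficiency, the
#' effective titration concentrations, and residual-corrected state flows
#' reported alongside the raw ones.
#'
#' @slot fcrR,fcrL,fcrS flux control ratios R/E, L/E, S_E/E.
#' @slot viR viability index (clipped to [0, 1]); `viRaw` is unclipped.
#' @slot viRaw unclipped viability index.
#' @slot jc cytochrome-c control efficiency.
#' @slot omyEffective,fccpEffective,digEffective effective concentrations.
#' @slot flows named raw per-cell state flows, amol s^-1 x^-1.
#' @slot roxCorrected flows minus the residual flow, floored at 0.
#' @slot flags character vector of quality flags.
#' @exportClass MetricSet
setClass("MetricSet",
  representation(fcrR = "numeric", fcrL = "numeric", fcrS = "numeric",
                 viR = "numeric", viRaw = "numeric", jc = "numeric",
                 omyEffective = "numeric", fccpEffective = "numeric",
                 digEffective = "numeric", flows = "numeric",
                 roxCorrected = "numeric", flags = "character"),
  validity = function(object) {
    for (s in c("fcrR", "fcrL", "fcrS", "viR", "viRaw", "jc",
                "omyEffective", "fccpEffective", "digEffective"))
      if (length(slot(object, s)) != 1L)
        return(paste0("'", s, "' must be a scalar (NA allowed)"))
    if (!is.na(object@viR) && (object@viR < 0 || object@viR > 1))
      return("viR must lie in [0, 1]")
    TRUE
  })

#' SuitProfile: per-state flux profile of one SUIT run
#'
#' One flow value per protocol state for one chamber run, the titration
#' series of the multi-step states, the per-step extraction table, and the
#' derived [MetricSet-class].
#'
#' @slot flows named per-cell flows (amol s^-1 x^-1) of the states, with
#'   the multi-step states at their chosen (effective) step.
#' @slot titrations named list of data.frames (`conc`, `flow`, `units`) for
#'   ce2Omy, ce3U and 1Dig.
#' @slot steps the full per-step extraction table (one row per state/step).
#' @slot metrics derived [MetricSet-class].
#' @slot flags quality flags (e.g. unconverged oligomycin titration).
#' @exportClass SuitProfile
setClass("SuitProfile",
  representation(flows = "numeric", titrations = "list", steps = "data.frame",
                 metrics = "MetricSet", flags = "character"),
  validity = function(object) {
    if (any(!is.finite(object@flows)))
      return("state flows must be finite")
    if (!is.na(object@flows["2Ama"]) && object@flows[["2Ama"]] < 0)
      return("residual flow (2Ama) must be >= 0")
    for (tt in object@titrations) {
      if (!all(c("conc", "flow") %in% names(tt)))
        return("titration series need 'conc' and 'flow' columns")
      if (is.unsorted(tt$conc, strictly = FALSE))
        return("titration series must be concentration-sorted")
    }
    TRUE
  })

#' CohortTruth: generative model of a donor cohort
#'
#' Parameters from which whole cohorts are simulated: a baseline cell
#' sample, per-isolation-method multiplicative effects, donor-level and
#' pathway-level biological variation, and the linear activation-marker
#' model tying %CD62P to the S-pathway flux control ratio.
#'
#' @slot baseline a [CellSampleParams-class] giving the DC baseline.
#' @slot methodEffects data.frame, one row per method (DC, PA, WA) with
#'   multipliers `rMult`, `eMult`, `sMult`, `omyMult`, `fccpMult`,
#'   `digMult` and the method's `deadFraction`.
#' @slot donorCV coefficient of variation of the log-normal donor baseline.
#' @slot pathwayCV per-record CV of independent pathway-level variation.
#' @slot activation list with `intercept`, `slope` (%CD62P per unit FCR)
#'   and `targetR2`, the squared correlation the marker noise is tuned to.
#' @exportClass CohortTruth
setClass("CohortTruth",
  representation(baseline = "CellSampleParams", methodEffects = "data.frame",
                 donorCV = "numeric", pathwayCV = "numeric",
                 activation = "list"),
  validity = function(object) {
    me <- object@methodEffects
    need <- c("method", "rMult", "eMult", "sMult", "omyMult", "fccpMult",
              "digMult", "deadFraction")
    miss <- setdiff(need, names(me))
    if (length(miss))
      return(paste("methodEffects lacks:", paste(miss, collapse = ", ")))
    if (!all(c("DC", "PA", "WA") %in% me$method))
      return("methodEffects must cover DC, PA and WA")
    mul <- as.matrix(me[, c("rMult", "eMult", "sMult", "omyMult",
                            "fccpMult", "digMult")])
    if (any(mul <= 0)) return("all method multipliers must be > 0")
    dc <- me[me$method == "DC", need[-1]]
    wa <- me[me$method == "WA", need[-1]]
    if (!isTRUE(all.equal(as.numeric(dc[1, ]), as.numeric(wa[1, ]))))
      return("WA effects must equal DC effects (washing restores DC behaviour)")
    act <- object@activation
    if (!all(c("intercept", "slope", "targetR2") %in% names(act)))
      return("activation needs intercept, slope and targetR2")
    if (act$targetR2 <= 0 || act$targetR2 >= 1)
      return("targetR2 must lie in (0, 1)")
    if (object@donorCV < 0 || object@pathwayCV < 0)
      return("CVs must be >= 0")
    TRUE
  })

#' RegressionResult: axis-symmetric dual regression of two variables
#'
#' Holds the ordinary Y-on-X line, the ordinate projection of the X-on-Y
#' line (reciprocal slope), the mean (standardized major axis) line, and
#' the squared correlation, which is invariant under axis inversion.
#'
#' @slot slopeYX,interceptYX ordinary least-squares Y on X.
#' @slot slopeXYInv,interceptXYInv X-on-Y regression projected into Y-on-X
#'   coordinates.
#' @slot slopeMean,interceptMean mean regression (SMA) line.
#' @slot r2 squared correlation.
#' @slot n number of points used.
#' @slot flags e.g. "zero-covariance".
#' @exportClass RegressionResult
setClass("RegressionResult",
  representation(slopeYX = "numeric", interceptYX = "numeric",
                 slopeXYInv = "numeric", interceptXYInv = "numeric",
                 slopeMean = "numeric", interceptMean = "numeric",
                 r2 = "numeric", n = "integer", flags = "character"),
  validity = function(object) {
    if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1 + 1e-12))
      return("r2 must lie in [0, 1]")
    TRUE
  })
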