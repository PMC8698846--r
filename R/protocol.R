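#' @include AllClasses.R
NULL

#' Construct a SUIT protocol from an event table
#'
#' @param events data.frame with columns `time_s`, `state_label`,
#'   `substance`, `cumulative_conc`, `units`, `step_index`. Times must be
#'   strictly increasing, labels in protocol order (`ce1`, `ce1P`,
#'   `ce2Omy`, `ce3U`, `ce4Rot`, `ce5S`, `1Dig`, `1c`, `2Ama`) and
#'   cumulative concentrations non-decreasing within one substance.
#' @param duration_s total run duration; defaults to the last event time
#'   plus `tail_s`.
#' @param tail_s recording time kept after the last event when
#'   `duration_s` is missing.
#' @return a [SuitProtocol-class].
#' @export
suitProtocol <- function(events, duration_s = NULL, tail_s = 240) {
  events <- as.data.frame(events)
  if (is.null(duration_s)) duration_s <- max(events$time_s) + tail_s
  events$step_index <- as.integer(events$step_index)
  new("SuitProtocol", events = events, duration_s = duration_s)
}

.titration_grid <- function(step, target, extra) {
  step * seq_len(ceiling(target / step - 1e-9) + extra)
}

#' Default coupling-control and cell-viability (CCV) protocol
#'
#' Builds the SUIT-003 CCV event schedule for one sample: endogenous
#' ROUTINE (ce1), pyruvate (ce1P), stepwise oligomycin titration to LEAK
#' (ce2Omy), stepwise uncoupler (FCCP) titration to ET capacity (ce3U),
#' rotenone (ce4Rot), succinate for the membrane-integrity test (ce5S),
#' stepwise digitonin permeabilization (1Dig), cytochrome c (1c) and
#' antimycin A for residual oxygen consumption (2Ama).
#'
#' Titration grids are derived from the sample's effective concentrations:
#' oligomycin is stepped until the first grid multiple at or above the
#' sample's threshold plus `omyConfirmSteps` confirmation steps; FCCP until
#' the optimum plus `fccpExtraSteps` overshoot steps; digitonin stops at
#' the first multiple at or above its optimum (`digExtraSteps = 0`), so the
#' cytochrome-c state continues from the optimally permeabilized flux.
#'
#' @param sample a [CellSampleParams-class]; its titration thresholds,
#'   optima and step sizes shape the grids.
#' @param stateDuration duration of each single-state segment, s.
#' @param stepDuration duration of each titration step, s.
#' @param omyConfirmSteps oligomycin steps added beyond the threshold.
#' @param fccpExtraSteps FCCP steps titrated beyond the optimum.
#' @param digExtraSteps digitonin steps titrated beyond the optimum.
#' @return a [SuitProtocol-class].
#' @examples
#' pr <- ccvProtocol(cellSampleParams())
#' head(pr@events)
#' @export
ccvProtocol <- function(sample = cellSampleParams(), stateDuration = 180,
                        stepDuration = 120, omyConfirmSteps = 1,
                        fccpExtraSteps = 2, digExtraSteps = 0) {
  stopifnot(is(sample, "CellSampleParams"))
  omy <- .titration_grid(sample@omyStep, sample@omyThreshold, omyConfirmSteps)
  fcc <- .titration_grid(sample@fccpStep, sample@fccpOptimum, fccpExtraSteps)
  dig <- .titration_grid(sample@digStep, sample@digOptimum, digExtraSteps)

  rows <- list()
  t <- 0
  add <- function(label, substance, conc, units, step = 1L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time_s = t, state_label = label, substance = substance,
      cumulative_conc = conc, units = units, step_index = as.integer(step),
      stringsAsFactors = FALSE)
  }
  add("ce1", "sample", NA_real_, "")
  t <- stateDuration
  add("ce1P", "pyruvate", 10, "mmol/L")
  t <- t + stateDuration
  for (i in seq_along(omy)) {
    add("ce2Omy", "oligomycin", omy[i], "nmol/L", i)
    t <- t + stepDuration
  }
  for (i in seq_along(fcc)) {
    add("ce3U", "FCCP", fcc[i], "umol/L", i)
    t <- t + stepDuration
  }
  add("ce4Rot", "rotenone", 1, "umol/L")
  t <- t + stateDuration
  add("ce5S", "succinate", 10, "mmol/L")
  t <- t + stateDuration
  for (i in seq_along(dig)) {
    add("1Dig", "digitonin", dig[i], "ug/mL", i)
    t <- t + stepDuration
  }
  add("1c", "cytochrome c", 10, "umol/L")
  t <- t + stateDuration
  add("2Ama", "antimycin A", 2.5, "umol/L")
  t <- t + stateDuration
  suitProtocol(do.call(rbind, rows), duration_s = t)
}
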