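# Shared fixture builders: all synthetic, generated in code.

# A one-state protocol (endogenous ROUTINE only).
single_state_protocol <- function(duration = 300, label = "ce1") {
  suitProtocol(data.frame(time_s = 0, state_label = label,
                          substance = "sample", cumulative_conc = NA_real_,
                          units = "", step_index = 1L),
               duration_s = duration)
}

# A sample whose only consumer is a flat ce1 flow of `j_percell`
# amol/s/x (volume flux = 200 * j_percell pmol/s/mL at default cell count).
flat_sample <- function(j_percell, nCells = 108e6) {
  cellSampleParams(nCells = nCells, deadFraction = 0,
                   stateFlux = c(ce1 = j_percell, ce1P = j_percell,
                                 ce2Omy = 0, ce3U = j_percell,
                                 ce4Rot = 0, ce5S = 0, "1Dig" = j_percell),
                   roxFlow = 0)
}

# Chamber without instrumental background (isolates cellular flux).
clean_chamber <- function(...) {
  chamberConfig(backgroundA = 0, backgroundB = 0, ...)
}

# One noiseless default DC run, end to end.
dc_run <- function(deadFraction = 0.13, sigma = 0, seed = NA_integer_,
                   chamber = chamberConfig(), ...) {
  sp <- cellSampleParams(deadFraction = deadFraction, ...)
  simulateTrace(ccvProtocol(sp), sp, chamber, noiseParams(sigma, seed))
}
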