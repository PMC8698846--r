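#' @include AllClasses.R
NULL

setMethod("show", "ChamberConfig", function(object) {
  cat("ChamberConfig:", object@workingVolume, "+", object@deadVolume,
      "mL,", object@sampleInterval, "s sampling,",
      "background", object@backgroundA, "+", object@backgroundB,
      "* c, O2 start", object@o2Init, "umol/L\n")
})

setMethod("show", "TraceSeries", function(object) {
  n <- length(object@time)
  cat("TraceSeries:", n, "samples,",
      sprintf("%.0f-%.0f s,", object@time[1], object@time[n]),
      nrow(object@events), "events |",
      "donor", object@metadata$donor_id,
      paste0("(", object@metadata$method, ")"),
      if (object@truncated) "| TRUNCATED (anoxia)" else "", "\n")
  cat("  O2:", sprintf("%.1f -> %.1f umol/L", object@o2[1], object@o2[n]),
      "\n")
})

setMethod("show", "FluxSeries", function(object) {
  v <- object@jv[object@valid]
  cat("FluxSeries:", length(object@time), "points (",
      sum(object@valid), "valid ),",
      if (object@corrected) "background-corrected" else "raw", "\n")
  if (length(v))
    cat("  j_v range:", sprintf("%.2f to %.2f pmol/s/mL", min(v), max(v)),
        "\n")
})

setMethod("show", "SuitProfile", function(object) {
  cat("SuitProfile with states:",
      paste(names(object@flows), collapse = ", "), "\n")
  print(round(object@flows, 4))
  if (length(object@flags)) cat("  flags:",
                                paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "MetricSet", function(object) {
  cat("MetricSet:\n")
  cat(sprintf("  FCR  R/E %.3f  L/E %.3f  S/E %.3f\n",
              object@fcrR, object@fcrL, object@fcrS))
  cat(sprintf("  VI_R %.3f  j_c %.3f\n", object@viR, object@jc))
  cat(sprintf("  effective conc: oligomycin %.3g, FCCP %.3g, digitonin %.3g\n",
              object@omyEffective, object@fccpEffective,
              object@digEffective))
  if (length(object@flags)) cat("  flags:",
                                paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "CohortTruth", function(object) {
  cat("CohortTruth: donor CV", object@donorCV, ", pathway CV",
      object@pathwayCV, "\n")
  print(object@methodEffects)
  cat("  activation: %CD62P =", object@activation$intercept, "+",
      object@activation$slope, "* FCR_S, target r2",
      object@activation$targetR2, "\n")
})

setMethod("show", "RegressionResult", function(object) {
  cat("Dual regression (n =", object@n, "):\n")
  cat(sprintf("  Y/X:      slope %.4g, intercept %.4g\n",
              object@slopeYX, object@interceptYX))
  cat(sprintf("  X/Y-inv:  slope %.4g, intercept %.4g\n",
              object@slopeXYInv, object@interceptXYInv))
  cat(sprintf("  mean:     slope %.4g, intercept %.4g\n",
              object@slopeMean, object@interceptMean))
  cat(sprintf("  r2 = %.4g (axis-inversion invariant)\n", object@r2))
})

#' Plot a trace with its titration events
#'
#' Base-graphics diagnostic plot: the O2 concentration trace with vertical
#' marks and state labels at each titration event.
#'
#' @param x a [TraceSeries-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
setMethod("plot", signature(x = "TraceSeries", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@time, x@o2, type = "l", xlab = "time [s]",
                   ylab = "O2 concentration [umol/L]", ...)
    if (nrow(x@events)) {
      graphics::abline(v = x@events$time_s, col = "grey70", lty = 3)
      graphics::mtext(x@events$state_label, side = 3, at = x@events$time_s,
                      cex = 0.6, las = 2)
    }
    invisible(x)
  })
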