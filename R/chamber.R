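#' @include AllClasses.R
NULL

#' Construct a chamber configuration
#'
#' Defaults describe a 0.5 mL oxygraph glass chamber with a 0.04 mL stopper
#' capillary dead volume, 2 s recording interval and a small linear
#' instrumental background flux.
#'
#' @param workingVolume chamber working volume in mL.
#' @param deadVolume stopper-capillary dead volume in mL.
#' @param temperature assay temperature, degrees C (informational).
#' @param sampleInterval recording interval in s.
#' @param backgroundA background flux intercept, pmol s^-1 mL^-1.
#' @param backgroundB background flux slope per umol L^-1 O2.
#' @param o2Init O2 concentration at run start, umol L^-1.
#' @return a [ChamberConfig-class] object.
#' @examples
#' ch <- chamberConfig()
#' cellConcentration(108e6, ch)  # 200 (in 1e6 cells per mL)
#' @export
chamberConfig <- function(workingVolume = 0.5, deadVolume = 0.04,
                          temperature = 37, sampleInterval = 2,
                          backgroundA = -2.0, backgroundB = 0.025,
                          o2Init = 191) {
  new("ChamberConfig", workingVolume = workingVolume,
      deadVolume = deadVolume, temperature = temperature,
      sampleInterval = sampleInterval, backgroundA = backgroundA,
      backgroundB = backgroundB, o2Init = o2Init)
}

#' Construct a sensor noise model
#'
#' @param sigmaO2 Gaussian standard deviation on each sampled O2
#'   concentration, umol L^-1. Use 0 for a noiseless trace.
#' @param seed integer random seed, or NA to draw from the active RNG
#'   stream (e.g. inside a seeded cohort simulation).
#' @return a [NoiseParams-class] object.
#' @export
noiseParams <- function(sigmaO2 = 0.2, seed = NA_integer_) {
  new("NoiseParams", sigmaO2 = sigmaO2, seed = as.integer(seed))
}

#' Cell concentration in the chamber
#'
#' Cells added by partial volume replacement distribute over the full
#' chamber volume including the stopper capillary, so the concentration is
#' the cell count divided by working plus dead volume.
#'
#' @param nCells number of cells added (>= 0).
#' @param chamber a [ChamberConfig-class].
#' @return concentration in 1e6 cells per mL: adding 108e6 platelets to a
#'   0.5 + 0.04 mL chamber gives 200.
#' @export
cellConcentration <- function(nCells, chamber = chamberConfig()) {
  stopifnot(is(chamber, "ChamberConfig"))
  if (!is.numeric(nCells) || length(nCells) != 1L || is.na(nCells))
    stop("nCells must be a single number")
  if (nCells < 0) stop("nCells must be >= 0")
  nCells / (chamber@workingVolume + chamber@deadVolume) / 1e6
}
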