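#' @include AllClasses.R chamber.R
NULL

#' Volume-specific O2 flux from a concentration trace
#'
#' Estimates the volume-specific oxygen flux at every interior sample as
#' minus 1000 times the slope of an ordinary least-squares line fitted to
#' the O2 concentration over a centered window of width `window_s`
#' (consumption positive, pmol s^-1 mL^-1). On an exactly linear trace the
#' OLS slope is exact for any window width. Edge samples without a full
#' window carry no estimate and are flagged invalid rather than
#' one-sided-differenced.
#'
#' @param trace a [TraceSeries-class].
#' @param window_s differentiation window width in s; must span at least
#'   5 samples and fit inside the trace.
#' @return a [FluxSeries-class].
#' @examples
#' # a noiseless linear decline of 0.02 umol/L/s reads as 20 pmol/s/mL
#' @export
computeFlux <- function(trace, window_s = 40) {
  stopifnot(is(trace, "TraceSeries"))
  dt <- trace@time[2] - trace@time[1]
  half <- floor(window_s / (2 * dt))
  npts <- 2L * half + 1L
  if (npts < 5L) stop("window_s must span at least 5 samples")
  n <- length(trace@o2)
  if (npts > n) stop("window larger than trace")
  ## OLS slope over the centered window as a linear filter:
  ## slope_i = sum_j w_j c_{i+j}, w_j = j*dt / sum(j^2 dt^2)
  j <- seq(-half, half)
  w <- (j * dt) / sum((j * dt)^2)
  slope <- stats::filter(trace@o2, rev(w), method = "convolution", sides = 2)
  jv <- -1000 * as.numeric(slope)
  valid <- !is.na(jv)
  new("FluxSeries", time = trace@time, jv = jv, valid = valid,
      corrected = FALSE)
}

#' Subtract the instrumental background flux
#'
#' The measured flux contains the chamber's own oxygen consumption (sensor
#' and back-diffusion), modeled as J_bg(c) = a + b c. The corrected
#' cellular flux is j_v(t) - (a + b c_O2(t)).
#'
#' @param flux a [FluxSeries-class].
#' @param trace the source [TraceSeries-class] (supplies c_O2(t)).
#' @param a,b background intercept (pmol s^-1 mL^-1) and slope (per
#'   umol L^-1); default to the trace's chamber metadata.
#' @return a background-corrected [FluxSeries-class].
#' @export
correctBackground <- function(flux, trace, a = NULL, b = NULL) {
  stopifnot(is(flux, "FluxSeries"), is(trace, "TraceSeries"))
  if (length(flux@jv) != length(trace@o2))
    stop("flux and trace lengths differ")
  if (is.null(a)) a <- trace@metadata$background_a
  if (is.null(b)) b <- trace@metadata$background_b
  jv <- flux@jv - (a + b * trace@o2)
  jv[!flux@valid] <- NA_real_
  new("FluxSeries", time = flux@time, jv = jv, valid = flux@valid,
      corrected = TRUE)
}

#' Extract one steady-state flux per protocol state
#'
#' For each event, the evaluation window opens `settle_s` after the
#' addition (excluding injection mixing and the transition ramp) and
#' closes at the earlier of the next event and `settle_s + span_frac` of
#' the inter-event gap. The state flux is the median of the valid flux
#' samples in the window (robust to single-point injection artifacts);
#' dispersion is reported as the median absolute deviation. Multi-step
#' titrations yield one row per step.
#'
#' @param flux a [FluxSeries-class] (typically background-corrected).
#' @param events event table of the source trace.
#' @param concentration cell concentration in 1e6 cells per mL, used for
#'   the per-cell flow column.
#' @param settle_s settling time after each addition, s.
#' @param span_frac fraction of the inter-event gap used after settling.
#' @return data.frame with one row per state/step: `state_label`,
#'   `step_index`, `cumulative_conc`, `units`, `substance`, `j_v`
#'   (pmol s^-1 mL^-1), `i_o2` (amol s^-1 x^-1), `t_start`, `t_end`,
#'   `n_points`, `mad`.
#' @export
extractStepFlux <- function(flux, events, concentration, settle_s = 60,
                            span_frac = 1) {
  stopifnot(is(flux, "FluxSeries"))
  if (!nrow(events)) stop("no events to extract")
  if (any(diff(events$time_s) <= 0)) stop("events must be ordered in time")
  tEnd <- flux@time[length(flux@time)]
  nextT <- c(events$time_s[-1], tEnd)
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    gap <- nextT[i] - events$time_s[i]
    w0 <- events$time_s[i] + settle_s
    w1 <- min(nextT[i], w0 + span_frac * gap)
    sel <- flux@valid & flux@time >= w0 & flux@time <= w1
    if (!any(sel))
      stop("empty evaluation window for state ", events$state_label[i],
           " (step ", events$step_index[i],
           "): events too close together for settle_s = ", settle_s)
    v <- flux@jv[sel]
    jm <- stats::median(v)
    out[[i]] <- data.frame(
      state_label = events$state_label[i],
      step_index = events$step_index[i],
      cumulative_conc = events$cumulative_conc[i],
      units = events$units[i], substance = events$substance[i],
      j_v = jm, i_o2 = perCellFlow(jm, concentration),
      t_start = w0, t_end = w1, n_points = sum(sel),
      mad = stats::mad(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-cell oxygen flow
#'
#' Converts volume-specific flux to oxygen flow per cell. The unit algebra
#' is exact: pmol s^-1 mL^-1 divided by 1e6 cells mL^-1 equals
#' amol s^-1 per cell.
#'
#' @param j_v volume-specific flux, pmol s^-1 mL^-1.
#' @param concentration cell concentration in 1e6 cells per mL (> 0).
#' @return per-cell flow in amol s^-1 x^-1.
#' @examples
#' perCellFlow(20, 200)  # 0.1
#' @export
perCellFlow <- function(j_v, concentration) {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0)
    stop("concentration must be a single number > 0")
  j_v / concentration
}
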