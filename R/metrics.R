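#' @include AllClasses.R flux.R
NULL

#' Respirometric viability index
#'
#' VI_R = 1 - (J_ce5S - J_ce4Rot) / (J_1Dig - J_2Ama): the fraction of
#' cells with an intact plasma membrane, inferred from how much of the
#' fully-permeabilized succinate capacity is already expressed before
#' digitonin. The returned value is clipped to [0, 1]; the unclipped
#' formula value is attached as attribute `"raw"`.
#'
#' The formula is invariant to the flow normalization: per-cell and
#' volume-specific inputs give the same index.
#'
#' @param jCe5S flux with succinate before permeabilization.
#' @param jCe4Rot flux after rotenone (pre-succinate baseline).
#' @param j1Dig flux after full digitonin permeabilization.
#' @param j2Ama residual flux after antimycin A.
#' @return viability index in [0, 1], with attribute `raw`.
#' @examples
#' viabilityIndex(5, 2, 22, 2)  # 0.85
#' @export
viabilityIndex <- function(jCe5S, jCe4Rot, j1Dig, j2Ama) {
  den <- j1Dig - j2Ama
  if (!is.finite(den) || den <= 0)
    stop("non-positive denominator J_1Dig - J_2Ama: permeabilization failed")
  raw <- 1 - (jCe5S - jCe4Rot) / den
  structure(min(max(raw, 0), 1), raw = raw)
}

#' Cytochrome-c control efficiency
#'
#' j_c = (J_1c - J_1Dig) / (J_1c - J_2Ama): the fractional flux
#' stimulation by external cytochrome c. Values near 0 indicate an intact
#' outer mitochondrial membrane.
#'
#' @param j1c flux after cytochrome-c addition.
#' @param j1Dig flux after digitonin permeabilization.
#' @param j2Ama residual flux after antimycin A.
#' @return the control efficiency (in [0, 1] when
#'   `j1c >= j1Dig >= j2Ama`).
#' @examples
#' cytcEfficiency(20, 18, 2)  # 0.1111
#' @export
cytcEfficiency <- function(j1c, j1Dig, j2Ama) {
  den <- j1c - j2Ama
  if (!is.finite(den) || den <= 0)
    stop("non-positive denominator J_1c - J_2Ama")
  (j1c - j1Dig) / den
}

#' Flux control ratio
#'
#' A state flow divided by the reference ET capacity of living cells
#' (E_ce3U). Because numerator and denominator share the cell-count
#' normalization, the ratio is independent of it.
#'
#' @param flowState state flow (per-cell or volume-specific).
#' @param eCe3U reference ET capacity in the same normalization (> 0).
#' @return the flux control ratio.
#' @export
fluxControlRatio <- function(flowState, eCe3U) {
  if (!is.finite(eCe3U) || eCe3U <= 0)
    stop("reference ET capacity must be > 0")
  flowState / eCe3U
}

#' Residual-flux correction of state flows
#'
#' Subtracts the residual oxygen consumption measured after antimycin A
#' (Rox, state 2Ama) from every mitochondrial state flow, flooring at 0.
#' The viability index and cytochrome-c efficiency always use raw flows:
#' their formulas carry their own baselines.
#'
#' @param flows named numeric state flows including `"2Ama"`.
#' @return named list: `corrected` (flows minus Rox, floored at 0),
#'   `floored` (names of states where flooring occurred), `rox`.
#' @export
roxCorrect <- function(flows) {
  if (!("2Ama" %in% names(flows)) || is.na(flows[["2Ama"]]))
    stop("residual flux (state 2Ama) missing")
  rox <- flows[["2Ama"]]
  states <- setdiff(names(flows), "2Ama")
  corr <- flows[states] - rox
  floored <- names(corr)[!is.na(corr) & corr < 0]
  corr[!is.na(corr) & corr < 0] <- 0
  list(corrected = corr, floored = floored, rox = rox)
}

.check_titration <- function(titration) {
  if (is.null(titration) || !nrow(titration)) stop("empty titration series")
  if (!all(c("conc", "flow") %in% names(titration)))
    stop("titration series needs 'conc' and 'flow' columns")
  titration[order(titration$conc), , drop = FALSE]
}

#' Effective oligomycin concentration and LEAK flux
#'
#' The effective (fully inhibiting) oligomycin concentration is the
#' smallest cumulative concentration after which every subsequent step
#' changes the flow by less than `rel_tol` (strictly) relative to the
#' current flow; the LEAK flux is the flow at that step. A series whose
#' flows never decrease signals a failed inhibition and is returned
#' flagged unconverged at its last step, as is a single-step series.
#'
#' @param titration data.frame with `conc` and `flow` (concentration
#'   sorted; sorted internally otherwise).
#' @param rel_tol relative stabilization tolerance (default 5%).
#' @return list with `omy_effective`, `L`, `converged`.
#' @examples
#' findOligomycinThreshold(data.frame(conc = c(0, 5, 10),
#'                                    flow = c(100, 40, 38)))
#' @export
findOligomycinThreshold <- function(titration, rel_tol = 0.05) {
  tt <- .check_titration(titration)
  n <- nrow(tt)
  f <- tt$flow
  if (n == 1L)
    return(list(omy_effective = tt$conc[1], L = f[1], converged = FALSE))
  if (all(diff(f) >= 0))
    return(list(omy_effective = tt$conc[n], L = f[n], converged = FALSE))
  relChange <- abs(diff(f)) / abs(f[-n])   # change of step j vs step j-1
  stableFrom <- n                          # last step is vacuously stable
  for (i in seq_len(n - 1L)) {
    if (all(relChange[i:(n - 1L)] < rel_tol)) { stableFrom <- i; break }
  }
  list(omy_effective = tt$conc[stableFrom], L = f[stableFrom],
       converged = TRUE)
}

.argmax_titration <- function(titration) {
  tt <- .check_titration(titration)
  if (nrow(tt) == 1L)
    return(list(conc = tt$conc[1], flow = tt$flow[1], single = TRUE))
  i <- which.max(tt$flow)   # first attainment = lowest concentration
  list(conc = tt$conc[i], flow = tt$flow[i], single = FALSE)
}

#' Optimum uncoupler (FCCP) concentration and ET capacity
#'
#' ET capacity E is the maximum flow over the titration series; the
#' effective concentration is the first (lowest) concentration attaining
#' it — the conventional uncoupler optimum.
#'
#' @inheritParams findOligomycinThreshold
#' @return list with `fccp_effective`, `E`.
#' @export
findUncouplerOptimum <- function(titration) {
  r <- .argmax_titration(titration)
  list(fccp_effective = r$conc, E = r$flow)
}

#' Optimum digitonin concentration and S-linked ET capacity
#'
#' Same argmax-with-lowest-concentration rule as the uncoupler, applied to
#' the succinate-supported flow of the permeabilization titration.
#'
#' @inheritParams findOligomycinThreshold
#' @return list with `dig_effective`, `S_E`.
#' @export
findDigitoninOptimum <- function(titration) {
  r <- .argmax_titration(titration)
  list(dig_effective = r$conc, S_E = r$flow)
}

#' Assemble a SUIT profile and its derived metrics
#'
#' Composes the per-step flux table of one run into a
#' [SuitProfile-class]: picks the reported flux of each multi-step
#' titration by the titration rules (oligomycin stabilization, FCCP and
#' digitonin argmax), computes flux control ratios against E_ce3U, the
#' viability index, the cytochrome-c control efficiency and
#' residual-corrected flows. Missing optional states yield NA metrics,
#' never silent zeros; missing mandatory states (ce1P, ce3U, 1Dig, 2Ama)
#' are an error.
#'
#' @param stepFlux per-step table from [extractStepFlux()].
#' @param rel_tol oligomycin stabilization tolerance.
#' @param flow_col which flow column to use, `"i_o2"` (per-cell, default)
#'   or `"j_v"`; every derived ratio is invariant to this choice.
#' @return a [SuitProfile-class] with its [MetricSet-class] in
#'   `profileMetrics()`.
#' @export
buildProfile <- function(stepFlux, rel_tol = 0.05, flow_col = c("i_o2", "j_v")) {
  flow_col <- match.arg(flow_col)
  stopifnot(is.data.frame(stepFlux))
  present <- unique(stepFlux$state_label)
  missing_states <- setdiff(.MANDATORY_STATES, present)
  if (length(missing_states))
    stop("mandatory states missing: ", paste(missing_states, collapse = ", "))

  getFlow <- function(label) {
    v <- stepFlux[[flow_col]][stepFlux$state_label == label]
    if (length(v)) stats::median(v) else NA_real_
  }
  titr <- function(label) {
    sub <- stepFlux[stepFlux$state_label == label, , drop = FALSE]
    data.frame(conc = sub$cumulative_conc, flow = sub[[flow_col]],
               units = sub$units, stringsAsFactors = FALSE)
  }

  flags <- character()
  titrations <- list(ce2Omy = titr("ce2Omy"), ce3U = titr("ce3U"),
                     "1Dig" = titr("1Dig"))

  if (nrow(titrations$ce2Omy)) {
    omy <- findOligomycinThreshold(titrations$ce2Omy, rel_tol = rel_tol)
    if (!omy$converged) flags <- c(flags, "oligomycin-unconverged")
  } else {
    omy <- list(omy_effective = NA_real_, L = NA_real_, converged = NA)
  }
  unc <- findUncouplerOptimum(titrations$ce3U)
  dig <- findDigitoninOptimum(titrations$"1Dig")

  flows <- c(ce1 = getFlow("ce1"), ce1P = getFlow("ce1P"),
             ce2Omy = omy$L, ce3U = unc$E, ce4Rot = getFlow("ce4Rot"),
             ce5S = getFlow("ce5S"), "1Dig" = dig$S_E,
             "1c" = getFlow("1c"), "2Ama" = getFlow("2Ama"))
  if (!is.na(flows[["2Ama"]]) && flows[["2Ama"]] < 0) {
    # residual consumption is physically non-negative; a small negative
    # estimate is sensor noise around a near-zero flux
    flows[["2Ama"]] <- 0
    flags <- c(flags, "negative-rox-clamped")
  }

  E <- unc$E
  if (!is.finite(E) || E <= 0)
    stop("reference ET capacity E_ce3U must be positive")
  fcrR <- fluxControlRatio(flows[["ce1P"]], E)
  fcrL <- if (is.na(flows[["ce2Omy"]])) NA_real_
          else fluxControlRatio(flows[["ce2Omy"]], E)
  fcrS <- fluxControlRatio(flows[["1Dig"]], E)
  if (!is.na(fcrL) && !is.na(fcrR) && !(fcrL <= fcrR && fcrR <= 1))
    flags <- c(flags, "coupling-order")

  viR <- viRaw <- NA_real_
  if (!is.na(flows[["ce5S"]]) && !is.na(flows[["ce4Rot"]])) {
    vi <- viabilityIndex(flows[["ce5S"]], flows[["ce4Rot"]],
                         flows[["1Dig"]], flows[["2Ama"]])
    viR <- as.numeric(vi); viRaw <- attr(vi, "raw")
  }
  jc <- if (is.na(flows[["1c"]])) NA_real_
        else cytcEfficiency(flows[["1c"]], flows[["1Dig"]], flows[["2Ama"]])

  rc <- roxCorrect(flows[!is.na(flows)])
  if (length(rc$floored))
    flags <- c(flags, paste0("rox-floored:", paste(rc$floored, collapse = "+")))

  metrics <- new("MetricSet", fcrR = fcrR, fcrL = fcrL, fcrS = fcrS,
                 viR = viR, viRaw = viRaw, jc = jc,
                 omyEffective = omy$omy_effective,
                 fccpEffective = unc$fccp_effective,
                 digEffective = dig$dig_effective,
                 flows = flows, roxCorrected = rc$corrected, flags = flags)
  new("SuitProfile", flows = flows[!is.na(flows)], titrations = titrations,
      steps = stepFlux, metrics = metrics, flags = flags)
}

#' Flatten a MetricSet into a one-row data.frame
#'
#' @param metrics a [MetricSet-class].
#' @return one-row data.frame with FCRs, viability index, cytochrome-c
#'   efficiency, effective concentrations, raw and residual-corrected
#'   state flows.
#' @export
metricsTable <- function(metrics) {
  stopifnot(is(metrics, "MetricSet"))
  fl <- metrics@flows
  names(fl) <- paste0("flow_", names(fl))
  rc <- metrics@roxCorrected
  names(rc) <- paste0("roxcorr_", names(rc))
  out <- data.frame(fcr_R = metrics@fcrR, fcr_L = metrics@fcrL,
                    fcr_S = metrics@fcrS, vi_r = metrics@viR,
                    vi_raw = metrics@viRaw, j_c = metrics@jc,
                    omy_effective = metrics@omyEffective,
                    fccp_effective = metrics@fccpEffective,
                    dig_effective = metrics@digEffective,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(as.list(fl)), as.data.frame(as.list(rc)),
        data.frame(flags = paste(metrics@flags, collapse = ";")))
}
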