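#' @include AllClasses.R
NULL

.TRACE_HEADER <- "#respilab-trace v1"

.NUM_META <- c("n_cells", "working_volume", "dead_volume", "sample_interval",
               "background_a", "background_b", "o2_init", "temperature")

.g17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a trace to the respilab CSV dialect
#'
#' Single-file plain-text format: a `#respilab-trace v1` header line,
#' `#meta,key,value` lines for run metadata, `#event,...` lines embedding
#' the titration event table, then a `time_s,o2_conc` CSV body. Floats are
#' written with 17 significant digits so a write/read round trip is exact.
#'
#' @param series a valid [TraceSeries-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readTrace()]
#' @export
writeTrace <- function(series, path) {
  stopifnot(is(series, "TraceSeries"))
  validObject(series)
  meta <- series@metadata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.TRACE_HEADER, con)
  for (k in names(meta))
    writeLines(paste("#meta", k,
                     if (is.numeric(meta[[k]])) .g17(meta[[k]])
                     else as.character(meta[[k]]), sep = ","), con)
  writeLines(paste("#meta", "truncated",
                   if (series@truncated) "1" else "0", sep = ","), con)
  ev <- series@events
  if (nrow(ev))
    writeLines(paste("#event", .g17(ev$time_s), ev$state_label,
                     ev$substance, .g17(ev$cumulative_conc), ev$units,
                     ev$step_index, sep = ","), con)
  writeLines("time_s,o2_conc", con)
  writeLines(paste(.g17(series@time), .g17(series@o2), sep = ","), con)
  invisible(path)
}

#' Read a trace from the respilab CSV dialect
#'
#' Parses and validates a trace file written by [writeTrace()] (or
#' exported from the instrument software through the column mapping
#' documented in the package vignette). All invariants are checked on
#' load: the declared dialect version, uniform sampling (the first
#' offending index is named), known state labels, events inside the
#' recorded time range, and complete metadata (missing keys are listed).
#'
#' @param path path to a trace file.
#' @return a validated [TraceSeries-class].
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != .TRACE_HEADER)
    stop("not a respilab trace: missing '", .TRACE_HEADER, "' header")
  metaLines <- grep("^#meta,", lines, value = TRUE)
  evLines <- grep("^#event,", lines, value = TRUE)
  bodyAt <- which(lines == "time_s,o2_conc")
  if (!length(bodyAt)) stop("trace body header 'time_s,o2_conc' not found")
  body <- lines[(bodyAt[1] + 1L):length(lines)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  time <- as.numeric(vapply(parts, `[`, "", 1L))
  o2 <- as.numeric(vapply(parts, `[`, "", 2L))

  meta <- list()
  truncated <- FALSE
  for (ln in metaLines) {
    kv <- strsplit(sub("^#meta,", "", ln), ",", fixed = TRUE)[[1]]
    key <- kv[1]; val <- paste(kv[-1], collapse = ",")
    if (key == "truncated") truncated <- val == "1"
    else meta[[key]] <- if (key %in% .NUM_META) as.numeric(val) else val
  }

  if (length(evLines)) {
    ep <- strsplit(sub("^#event,", "", evLines), ",", fixed = TRUE)
    events <- data.frame(
      time_s = as.numeric(vapply(ep, `[`, "", 1L)),
      state_label = vapply(ep, `[`, "", 2L),
      substance = vapply(ep, `[`, "", 3L),
      cumulative_conc = as.numeric(vapply(ep, function(p)
        if (nzchar(p[4])) p[4] else NA_character_, "")),
      units = vapply(ep, `[`, "", 5L),
      step_index = as.integer(vapply(ep, `[`, "", 6L)),
      stringsAsFactors = FALSE)
  } else {
    events <- data.frame(time_s = numeric(), state_label = character(),
                         substance = character(),
                         cumulative_conc = numeric(), units = character(),
                         step_index = integer(), stringsAsFactors = FALSE)
  }
  new("TraceSeries", time = time, o2 = o2, events = events,
      metadata = meta, truncated = truncated)
}

#' Read a cohort record table
#'
#' Flat CSV with one row per donor x method, carrying metric columns and
#' activation markers. Duplicate (donor_id, method) keys are rejected;
#' missing values are encoded as `NA`.
#'
#' @param path CSV path.
#' @return a data.frame of cohort records.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("donor_id", "method")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("cohort table lacks columns: ", paste(miss, collapse = ", "))
  key <- paste(rec$donor_id, rec$method)
  if (anyDuplicated(key))
    stop("duplicate (donor_id, method) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  pct <- grep("_pct$", names(rec), value = TRUE)
  for (p in pct) {
    v <- rec[[p]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop("percentages out of [0, 100] in column ", p)
  }
  rec
}

#' Write cohort metric records
#'
#' Counterpart of [readCohortTable()]: writes a flat one-row-per-run CSV
#' with 17-significant-digit floats so round trips are lossless.
#'
#' @param records data.frame with at least `donor_id` and `method`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (!all(c("donor_id", "method") %in% names(records)))
    stop("records need 'donor_id' and 'method' columns")
  key <- paste(records$donor_id, records$method)
  if (anyDuplicated(key))
    stop("duplicate (donor_id, method) keys")
  out <- records
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      col <- .g17(out[[nm]])
      col[col == ""] <- "NA"
      out[[nm]] <- col
    }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
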