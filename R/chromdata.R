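#' @include AllClasses.R
NULL

#' Construct a Trace
#'
#' @param channel one of `UV260`, `UV280`, `FLD`, `RI`, `LS00`..`LS17`.
#' @param times numeric, minutes, strictly increasing uniform grid.
#' @param values numeric signal, same length as `times`.
#' @param delayOffset detector dead-volume lag in minutes relative to the
#'   first detector of the train (default 0).
#' @return a [Trace-class] object.
#' @export
#' @examples
#' tr <- Trace("UV280", seq(0, 1, 0.01), dnorm(seq(0, 1, 0.01), 0.5, 0.1))
Trace <- function(channel, times, values, delayOffset = 0) {
  new("Trace", channel = channel, times = as.numeric(times),
      values = as.numeric(values), delayOffset = as.numeric(delayOffset))
}

#' Construct a Chromatogram
#'
#' @param traces list of [Trace-class] objects (at most one per channel).
#' @param sampleId sample identifier.
#' @param injectionVolume microlitres.
#' @param dilutionFactor dimensionless, >= 1.
#' @param temperature degrees C, `NA` outside thermal series.
#' @param angles named numeric vector of scattering angles (degrees) for the
#'   LS channels present.
#' @param lsCalibrated logical; `TRUE` when LS traces are excess Rayleigh
#'   ratios (cm^-1), `FALSE` for raw detector signals.
#' @param metadata free-form list of key-value metadata.
#' @return a [Chromatogram-class] object.
#' @export
Chromatogram <- function(traces, sampleId = "sample", injectionVolume = 100,
                         dilutionFactor = 1, temperature = NA_real_,
                         angles = numeric(0), lsCalibrated = TRUE,
                         metadata = list()) {
  names(traces) <- vapply(traces, function(tr) tr@channel, character(1))
  new("Chromatogram", sampleId = sampleId, traces = traces,
      injectionVolume = as.numeric(injectionVolume),
      dilutionFactor = as.numeric(dilutionFactor),
      temperature = as.numeric(temperature), angles = angles,
      lsCalibrated = lsCalibrated, metadata = metadata)
}

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write a chromatogram in the package CSV dialect
#'
#' The dialect is UTF-8 CSV with `.` decimal separator: `# key=value` header
#' lines (`sample_id`, `dilution_factor`, `injection_volume_uL`, optional
#' `temperature_C`, per-channel `delay_<channel>` in minutes, per-LS-channel
#' `angle_<channel>` in degrees, `ls_calibrated`, plus any free metadata
#' keys), then a header row `time_min,<channel>[,...]` and numeric rows.
#' Numbers are written with 17 significant digits so a write/read round trip
#' is lossless.
#'
#' @param x a [Chromatogram-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeChromatogram <- function(x, path) {
  stopifnot(is(x, "Chromatogram"))
  validObject(x)
  hdr <- c(sprintf("# sample_id=%s", x@sampleId),
           sprintf("# dilution_factor=%s", .fmtNum(x@dilutionFactor)),
           sprintf("# injection_volume_uL=%s", .fmtNum(x@injectionVolume)))
  if (!is.na(x@temperature))
    hdr <- c(hdr, sprintf("# temperature_C=%s", .fmtNum(x@temperature)))
  for (ch in names(x@traces))
    hdr <- c(hdr, sprintf("# delay_%s=%s", ch, .fmtNum(x@traces[[ch]]@delayOffset)))
  for (ch in names(x@angles))
    hdr <- c(hdr, sprintf("# angle_%s=%s", ch, .fmtNum(x@angles[[ch]])))
  hdr <- c(hdr, sprintf("# ls_calibrated=%s",
                        if (x@lsCalibrated) "true" else "false"))
  for (key in names(x@metadata)) {
    val <- x@metadata[[key]]
    hdr <- c(hdr, sprintf("# %s=%s", key,
                          if (is.numeric(val)) .fmtNum(val) else as.character(val)))
  }
  ## all traces must share one grid to be writable as one table
  times <- x@traces[[1L]]@times
  same <- vapply(x@traces, function(tr)
    length(tr@times) == length(times) && all(tr@times == times), logical(1))
  if (!all(same))
    stop("traces must share a common time grid to be written; align first")
  mat <- vapply(x@traces, function(tr) tr@values, numeric(length(times)))
  body <- c(paste(c("time_min", names(x@traces)), collapse = ","),
            apply(cbind(times, mat), 1L, function(row)
              paste(.fmtNum(row), collapse = ",")))
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a chromatogram from the package CSV dialect
#'
#' Parses a file written by [writeChromatogram()] (see there for the
#' dialect).  Structural problems — missing `time_min` column, non-monotone
#' times, an unknown channel name, ragged rows — raise an error naming the
#' offending line.
#'
#' @param path input file path.
#' @return a [Chromatogram-class].
#' @export
readChromatogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  isMeta <- startsWith(lines, "#")
  nMeta <- match(FALSE, isMeta) - 1L
  if (is.na(nMeta)) stop("no data section found in ", path)
  meta <- list()
  for (ln in lines[seq_len(nMeta)]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop("malformed metadata line (expected key=value): ", ln)
    key <- substr(kv, 1L, eq - 1L)
    meta[[trimws(key)]] <- trimws(substr(kv, eq + 1L, nchar(kv)))
  }
  header <- strsplit(lines[nMeta + 1L], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "time_min")
    stop(sprintf("line %d: first column must be 'time_min', got '%s'",
                 nMeta + 1L, header[1L]))
  channels <- header[-1L]
  bad <- setdiff(channels, .knownChannels)
  if (length(bad))
    stop(sprintf("line %d: unknown channel name(s): %s", nMeta + 1L,
                 paste(bad, collapse = ", ")))
  dataLines <- lines[seq(nMeta + 2L, length(lines))]
  dataLines <- dataLines[nzchar(dataLines)]
  cells <- strsplit(dataLines, ",", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != length(header))) {
    i <- which(nc != length(header))[1L]
    stop(sprintf("line %d: ragged row (%d fields, expected %d)",
                 nMeta + 1L + i, nc[i], length(header)))
  }
  mat <- matrix(as.numeric(unlist(cells)), ncol = length(header), byrow = TRUE)
  if (anyNA(mat)) {
    i <- which(apply(is.na(mat), 1L, any))[1L]
    stop(sprintf("line %d: non-numeric value", nMeta + 1L + i))
  }
  times <- mat[, 1L]
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1L]
    stop(sprintf("line %d: times not strictly increasing", nMeta + 2L + i))
  }

  num <- function(key, default) {
    if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
  }
  traces <- lapply(seq_along(channels), function(j) {
    ch <- channels[j]
    Trace(ch, times, mat[, j + 1L],
          delayOffset = num(paste0("delay_", ch), 0))
  })
  angleKeys <- grep("^angle_LS", names(meta), value = TRUE)
  angles <- vapply(angleKeys, function(k) as.numeric(meta[[k]]), numeric(1))
  names(angles) <- sub("^angle_", "", angleKeys)
  consumed <- c("sample_id", "dilution_factor", "injection_volume_uL",
                "temperature_C", "ls_calibrated", angleKeys,
                paste0("delay_", channels))
  extra <- meta[setdiff(names(meta), consumed)]
  extra <- lapply(extra, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (is.na(nv)) v else nv
  })
  Chromatogram(traces,
               sampleId = if (is.null(meta$sample_id)) "sample" else meta$sample_id,
               injectionVolume = num("injection_volume_uL", 100),
               dilutionFactor = num("dilution_factor", 1),
               temperature = num("temperature_C", NA_real_),
               angles = angles,
               lsCalibrated = !identical(meta$ls_calibrated, "false"),
               metadata = extra)
}

#' Align detector traces onto a common time grid
#'
#' Subtracts each trace's `delayOffset` (detector dead-volume lag) from its
#' time axis and resamples every trace by linear interpolation onto the first
#' trace's shifted grid, restricted to the window where all traces overlap.
#' With all offsets zero the operation is the identity on the common window,
#' and it is idempotent.
#'
#' @param x a [Chromatogram-class].
#' @return an aligned [Chromatogram-class] whose traces share one grid and
#'   have `delayOffset` 0.
#' @export
alignTraces <- function(x) {
  stopifnot(is(x, "Chromatogram"))
  if (!length(x@traces)) return(x)
  shifted <- lapply(x@traces, function(tr) tr@times - tr@delayOffset)
  lo <- max(vapply(shifted, min, numeric(1)))
  hi <- min(vapply(shifted, max, numeric(1)))
  if (hi <= lo)
    stop("traces do not overlap after delay correction (window ",
         sprintf("%.3f..%.3f min)", lo, hi))
  ref <- shifted[[1L]]
  eps <- (ref[2L] - ref[1L]) * 1e-9
  grid <- ref[ref >= lo - eps & ref <= hi + eps]
  x@traces <- lapply(x@traces, function(tr) {
    v <- stats::approx(tr@times - tr@delayOffset, tr@values, xout = grid,
                       rule = 1)$y
    Trace(tr@channel, grid, v, delayOffset = 0)
  })
  names(x@traces) <- vapply(x@traces, function(tr) tr@channel, character(1))
  validObject(x)
  x
}
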