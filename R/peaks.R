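#' @include AllClasses.R
NULL

#' Default integration quiet windows and class windows
#'
#' Quiet windows (minutes) are signal-free regions used for the linear
#' baseline fit and the robust noise estimate; the defaults bracket the
#' 30-min run.  Class windows assign labels by apex retention time: capsid
#' monomer 6.0-7.0 min, HMW aggregates 4.0-5.8 min, late low-molecular-weight
#' process impurities 8-16 min.  The thermal variant carves a nucleic-acid
#' window (5.3-5.7 min, the free-DNA peak near 5.5 min) out of the HMW
#' region.
#'
#' @return a list of `c(lo, hi)` intervals in minutes.
#' @export
defaultQuietWindows <- function() list(c(0, 2), c(25, 30))

#' @rdname defaultQuietWindows
#' @export
defaultPeakWindows <- function()
  list(monomer = c(6.0, 7.0), HMW = c(4.0, 5.8), LMW_impurity = c(8, 16))

#' @rdname defaultQuietWindows
#' @export
thermalPeakWindows <- function()
  list(monomer = c(6.0, 7.0), nucleic_acid = c(5.3, 5.7),
       HMW = c(4.0, 5.25), LMW_impurity = c(8, 16))

.windowIdx <- function(times, w) which(times >= w[1L] & times <= w[2L])

#' Robust noise estimate from quiet windows
#'
#' Median absolute deviation (scaled by 1.4826) of the signal inside the
#' quiet windows, after removing the linear baseline.
#'
#' @param trace a [Trace-class].
#' @param quietWindows list of `c(lo, hi)` intervals in minutes.
#' @return noise SD in signal units.
#' @export
quietNoiseSd <- function(trace, quietWindows = defaultQuietWindows()) {
  tr <- correctBaseline(trace, quietWindows)
  idx <- unlist(lapply(quietWindows, .windowIdx, times = tr@times))
  stats::mad(tr@values[idx], center = 0)
}

#' Subtract a linear baseline fitted to quiet windows
#'
#' Fits an ordinary least-squares line to the points inside the quiet
#' windows and subtracts it from the whole trace, so a pure linear drift is
#' removed exactly and the corrected signal averages zero over the quiet
#' regions.
#'
#' @param trace a [Trace-class].
#' @param quietWindows list of `c(lo, hi)` time intervals (minutes), each
#'   inside the trace and containing at least 3 points.
#' @return the baseline-corrected [Trace-class].
#' @export
correctBaseline <- function(trace, quietWindows = defaultQuietWindows()) {
  stopifnot(is(trace, "Trace"))
  if (!length(quietWindows)) stop("at least one quiet window is required")
  idx <- lapply(quietWindows, .windowIdx, times = trace@times)
  if (any(lengths(idx) < 3L))
    stop("each quiet window must lie inside the trace and contain >= 3 points")
  idx <- unlist(idx)
  fit <- stats::lm.fit(cbind(1, trace@times[idx]), trace@values[idx])
  base <- fit$coefficients[1L] + fit$coefficients[2L] * trace@times
  Trace(trace@channel, trace@times, trace@values - base,
        delayOffset = trace@delayOffset)
}

## peak prominence: height above the highest of the two minima separating
## the apex from higher terrain (or the trace ends)
.prominence <- function(v, apexes) {
  vapply(apexes, function(i) {
    h <- v[i]
    left <- if (i > 1L) {
      seg <- v[seq_len(i - 1L)]
      higher <- which(seg > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(v[lo:(i - 1L)])
    } else h
    right <- if (i < length(v)) {
      seg <- v[(i + 1L):length(v)]
      higher <- which(seg > h)
      hi <- if (length(higher)) i + min(higher) - 1L else length(v)
      min(v[(i + 1L):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Detect peaks on a baseline-corrected trace
#'
#' Local maxima above `minHeight` with prominence above `minProminence`.
#' Peak boundaries are the valley minima between adjacent detected peaks;
#' at the outer flanks the boundary is placed where the signal first drops
#' below `boundaryFraction` of the apex height (or at the trace end).  The
#' result is deterministic for a fixed input and ordered by apex time.
#'
#' @param trace a baseline-corrected [Trace-class].
#' @param minHeight minimum apex height, signal units.  The default is five
#'   times the robust quiet-window noise SD (floored at a tiny absolute
#'   value so that noise-free traces are handled).
#' @param minProminence minimum prominence, signal units (default
#'   `minHeight`).
#' @param quietWindows used only for the default `minHeight`.
#' @param boundaryFraction outer-boundary threshold as a fraction of the
#'   apex height (default 0.001).
#' @return data.frame with columns `start`, `apex`, `end` (minutes) and
#'   `height`; zero rows when nothing exceeds the thresholds.
#' @export
detectPeaks <- function(trace, minHeight = NULL, minProminence = NULL,
                        quietWindows = defaultQuietWindows(),
                        boundaryFraction = 0.001) {
  stopifnot(is(trace, "Trace"))
  v <- trace@values
  if (is.null(minHeight)) {
    idx <- unlist(lapply(quietWindows, .windowIdx, times = trace@times))
    noise <- if (length(idx) >= 3L) stats::mad(v[idx], center = 0) else 0
    minHeight <- max(5 * noise, 1e-9, 1e-6 * max(abs(v)))
  }
  if (is.null(minProminence)) minProminence <- minHeight
  n <- length(v)
  apexes <- which(v[-c(1L, 2L)] <= v[-c(1L, n)] & v[-c(1L, n)] > v[-c(n - 1L, n)]) + 1L
  apexes <- apexes[v[apexes] >= minHeight]
  if (length(apexes))
    apexes <- apexes[.prominence(v, apexes) >= minProminence]
  if (!length(apexes))
    return(data.frame(start = numeric(0), apex = numeric(0),
                      end = numeric(0), height = numeric(0)))
  apexes <- sort(apexes)
  k <- length(apexes)
  starts <- ends <- integer(k)
  for (j in seq_len(k)) {
    i <- apexes[j]
    thr <- boundaryFraction * v[i]
    if (j > 1L) {
      seg <- apexes[j - 1L]:i
      starts[j] <- seg[which.min(v[seg])]
    } else {
      below <- which(v[seq_len(i)] <= thr)
      starts[j] <- if (length(below)) max(below) else 1L
    }
    if (j < k) {
      seg <- i:apexes[j + 1L]
      ends[j] <- seg[which.min(v[seg])]
    } else {
      below <- which(v[i:n] <= thr)
      ends[j] <- if (length(below)) i + min(below) - 1L else n
    }
  }
  data.frame(start = trace@times[starts], apex = trace@times[apexes],
             end = trace@times[ends], height = v[apexes])
}

.trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

#' Integrate peaks over all channels of an aligned chromatogram
#'
#' Trapezoidal areas over each `[start, end]` window, per channel, using the
#' same time boundaries on every channel (so 260/280 area ratios are taken
#' over identical windows).  Percent areas are relative to the summed
#' detected-peak area per channel.
#'
#' @param chrom an aligned [Chromatogram-class] (all traces on one grid).
#' @param boundaries data.frame with columns `start`, `apex`, `end`
#'   (minutes), typically from [detectPeaks()] on the primary quantitation
#'   channel; windows must not overlap (shared endpoints are allowed).
#' @param detectionChannel name of the channel the boundaries came from.
#' @param channels channels to integrate (default: all present).
#' @return a [PeakTable-class] with label `unassigned` for every peak.
#' @export
integratePeaks <- function(chrom, boundaries, detectionChannel = channelNames(chrom)[1L],
                           channels = channelNames(chrom)) {
  stopifnot(is(chrom, "Chromatogram"))
  b <- boundaries[order(boundaries$apex), , drop = FALSE]
  if (nrow(b) > 1L && any(b$end[-nrow(b)] > b$start[-1L] + 1e-12))
    stop("peak boundaries overlap")
  times <- chrom@traces[[1L]]@times
  areas <- matrix(0, nrow(b), length(channels),
                  dimnames = list(NULL, channels))
  heights <- numeric(nrow(b))
  det <- chrom@traces[[detectionChannel]]
  for (i in seq_len(nrow(b))) {
    idx <- which(times >= b$start[i] - 1e-12 & times <= b$end[i] + 1e-12)
    if (length(idx) < 2L) stop("peak window contains fewer than 2 grid points")
    for (ch in channels) {
      tr <- chrom@traces[[ch]]
      if (!identical(length(tr@times), length(times)))
        stop("traces are not aligned on a common grid; run alignTraces()")
      areas[i, ch] <- max(.trapz(times[idx], tr@values[idx]), 0)
    }
    heights[i] <- det@values[which.min(abs(times - b$apex[i]))]
  }
  total <- colSums(areas)
  pct <- sweep(areas, 2L, ifelse(total > 0, total, 1), "/") * 100
  ## channels with zero total area get equal shares so columns still sum to 100
  zero <- total == 0
  if (any(zero) && nrow(b)) pct[, zero] <- 100 / nrow(b)
  new("PeakTable",
      peaks = data.frame(start = b$start, apex = b$apex, end = b$end,
                         height = heights,
                         label = rep("unassigned", nrow(b)),
                         stringsAsFactors = FALSE),
      areas = areas, percentArea = pct, totalArea = total,
      detectionChannel = detectionChannel)
}

#' Label peaks by retention-time window
#'
#' Each peak receives the label of the (non-overlapping) window containing
#' its apex; peaks outside every window stay `unassigned`.
#'
#' @param table a [PeakTable-class].
#' @param windows named list of `c(lo, hi)` intervals, e.g.
#'   [defaultPeakWindows()] or [thermalPeakWindows()].
#' @return the relabelled [PeakTable-class].
#' @export
classifyPeaks <- function(table, windows = defaultPeakWindows()) {
  stopifnot(is(table, "PeakTable"))
  w <- do.call(rbind, windows)
  if (nrow(w) > 1L) {
    o <- order(w[, 1L])
    if (any(w[o, 2L][-nrow(w)] > w[o, 1L][-1L]))
      stop("class windows overlap")
  }
  lab <- vapply(table@peaks$apex, function(a) {
    hit <- which(a >= w[, 1L] & a <= w[, 2L])
    if (length(hit)) rownames(w)[hit[1L]] else "unassigned"
  }, character(1))
  table@peaks$label <- lab
  table
}

#' Percent area carried by a peak class
#'
#' @param table a classified [PeakTable-class].
#' @param label peak class, e.g. `"monomer"` or `"HMW"`.
#' @param channel channel whose percent areas to sum (default: the detection
#'   channel).
#' @return summed percent area of all peaks with that label (0 when none).
#' @export
labelPercent <- function(table, label, channel = table@detectionChannel) {
  sel <- table@peaks$label == label
  if (!any(sel)) return(0)
  sum(table@percentArea[sel, channel])
}

#' Per-label A260/A280 area ratio
#'
#' @param table a classified [PeakTable-class] integrated over `UV260` and
#'   `UV280`.
#' @param label peak class.
#' @return summed area260 / summed area280 for that label, or `NA` when the
#'   label is absent or the 280 area is zero.
#' @export
labelRatio260280 <- function(table, label) {
  sel <- table@peaks$label == label
  if (!any(sel)) return(NA_real_)
  a260 <- sum(table@areas[sel, "UV260"])
  a280 <- sum(table@areas[sel, "UV280"])
  if (a280 <= 0) return(NA_real_)
  a260 / a280
}
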