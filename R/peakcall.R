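# Raw-trace processing: baseline-subtracted peak detection, size-standard
# calibration, and binding of calibrated peaks to panel targets.

.rolling_min <- function(x, window) {
  n <- length(x)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- min(x[lo:hi])
  }
  out
}

# Topographic prominence of local maxima: height above the higher of the
# two valley floors separating the peak from taller terrain.
.prominence <- function(x, apex) {
  n <- length(x)
  vapply(apex, function(i) {
    h <- x[i]
    left_min <- h; j <- i
    while (j > 1L) {
      j <- j - 1L
      if (x[j] > h) break
      if (x[j] < left_min) left_min <- x[j]
    }
    if (j == 1L && x[j] <= h && x[j] < left_min) left_min <- x[j]
    right_min <- h; j <- i
    while (j < n) {
      j <- j + 1L
      if (x[j] > h) break
      if (x[j] < right_min) right_min <- x[j]
    }
    if (j == n && x[j] <= h && x[j] < right_min) right_min <- x[j]
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect peaks in a raw trace
#'
#' Each dye channel is baseline-corrected by subtracting a rolling minimum
#' and clamping at zero, then local maxima with sufficient height and
#' topographic prominence are kept. Sizes are `NA` until calibration.
#'
#' @param trace A `thal_trace`.
#' @param min_height Minimum baseline-corrected apex height (RFU).
#' @param min_prominence Minimum topographic prominence (RFU).
#' @param window Rolling-minimum baseline window (scans, odd).
#' @param dyes Channels to scan (default all four).
#' @return `data.frame` of peaks: `dye`, `size` (`NA`), `height`, `area`,
#'   `scan_position`.
#' @export
detect_peaks <- function(trace, min_height = 50, min_prominence = 25,
                         window = 51L, dyes = DYE_LEVELS) {
  stopifnot(inherits(trace, "thal_trace"))
  if (window > trace$scan_count)
    stop("baseline window (", window, ") exceeds trace length (",
         trace$scan_count, ")", call. = FALSE)
  out <- list()
  for (dye in dyes) {
    x <- trace$channels[[dye]]
    y <- pmax(x - .rolling_min(x, window), 0)
    n <- length(y)
    if (n < 3L) next
    apex <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                    y[2:(n - 1L)] >= y[3:n]) + 1L
    apex <- apex[y[apex] >= min_height]
    if (length(apex)) {
      prom <- .prominence(y, apex)
      apex <- apex[prom >= min_prominence]
    }
    if (length(apex))
      out[[dye]] <- data.frame(dye = dye, size = NA_real_,
                               height = y[apex], area = NA_real_,
                               scan_position = apex,
                               stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(dye = character(), size = numeric(),
                      height = numeric(), area = numeric(),
                      scan_position = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit a scan-to-size calibration from ladder peaks
#'
#' Matches detected LIZ peaks to the known ladder fragment sizes and builds
#' a strictly monotone piecewise-linear scan-to-bp mapping with linear
#' extrapolation at both ends. When more peaks than ladder fragments are
#' detected, the tallest `length(ladder_sizes)` peaks are used, in scan
#' order. Residuals are leave-one-out interpolation errors.
#'
#' @param liz_peaks Peak `data.frame` (LIZ rows are selected).
#' @param ladder_sizes Known fragment sizes (bp), ascending.
#' @param min_ladder_points Minimum matched points (default 8).
#' @param residual_tolerance Maximum absolute leave-one-out residual (bp).
#' @return A `thal_calibration`, or an object of class `thal_ladder_failure`
#'   describing why calibration failed.
#' @export
fit_size_ladder <- function(liz_peaks, ladder_sizes = default_ladder_sizes(),
                            min_ladder_points = 8L,
                            residual_tolerance = 1.0) {
  pk <- liz_peaks[liz_peaks$dye == "LIZ", , drop = FALSE]
  fail <- function(reason)
    structure(list(reason = reason, n_peaks = nrow(pk)),
              class = "thal_ladder_failure")
  ladder_sizes <- sort(as.numeric(ladder_sizes))
  if (nrow(pk) < max(4L, min_ladder_points)) return(fail("too few ladder peaks"))
  if (nrow(pk) > length(ladder_sizes)) {
    keep <- order(pk$height, decreasing = TRUE)[seq_along(ladder_sizes)]
    pk <- pk[sort(keep), , drop = FALSE]
  }
  pk <- pk[order(pk$scan_position), , drop = FALSE]
  if (nrow(pk) < length(ladder_sizes)) {
    # keep the trailing ladder sizes: late dropouts are rarer than missed
    # small fragments at the injection front
    sizes <- utils::tail(ladder_sizes, nrow(pk))
  } else sizes <- ladder_sizes
  scans <- pk$scan_position
  if (any(diff(scans) <= 0)) return(fail("ladder peaks not monotone"))
  # leave-one-out residuals of interior points
  resid <- rep(0, length(scans))
  if (length(scans) >= 3L)
    for (i in 2:(length(scans) - 1L)) {
      pred <- sizes[i - 1L] + (sizes[i + 1L] - sizes[i - 1L]) *
        (scans[i] - scans[i - 1L]) / (scans[i + 1L] - scans[i - 1L])
      resid[i] <- sizes[i] - pred
    }
  if (max(abs(resid)) > residual_tolerance)
    return(fail(sprintf("ladder residual %.2f bp exceeds tolerance",
                        max(abs(resid)))))
  structure(list(scans = scans, sizes = sizes, residuals = resid),
            class = "thal_calibration")
}

#' Map scan positions to fragment sizes
#'
#' Piecewise-linear interpolation within the calibrated range; linear
#' extrapolation using the terminal segments outside it. Monotone by
#' construction.
#'
#' @param calibration A `thal_calibration`.
#' @param scan Numeric scan positions.
#' @return Sizes in bp.
#' @export
calibrated_size <- function(calibration, scan) {
  stopifnot(inherits(calibration, "thal_calibration"))
  s <- calibration$scans; z <- calibration$sizes
  n <- length(s)
  out <- stats::approx(s, z, xout = scan, rule = 1)$y
  lo <- scan < s[1]
  hi <- scan > s[n]
  slope1 <- (z[2] - z[1]) / (s[2] - s[1])
  slopeN <- (z[n] - z[n - 1]) / (s[n] - s[n - 1])
  out[lo] <- z[1] + (scan[lo] - s[1]) * slope1
  out[hi] <- z[n] + (scan[hi] - s[n]) * slopeN
  out
}

#' Assign calibrated sizes to detected peaks
#'
#' @param peaks Peak `data.frame` with `scan_position`.
#' @param calibration A `thal_calibration`.
#' @param max_extrapolation Scans beyond the calibrated range after which a
#'   peak is flagged `out_of_range` instead of sized.
#' @return `peaks` with `size` filled in and a logical `out_of_range`
#'   column.
#' @export
assign_sizes <- function(peaks, calibration, max_extrapolation = 200) {
  stopifnot(inherits(calibration, "thal_calibration"))
  if (nrow(peaks) == 0L) {
    peaks$out_of_range <- logical(0)
    return(peaks)
  }
  rng <- range(calibration$scans)
  oor <- peaks$scan_position < rng[1] - max_extrapolation |
    peaks$scan_position > rng[2] + max_extrapolation
  peaks$size <- calibrated_size(calibration, peaks$scan_position)
  peaks$size[oor] <- NA_real_
  peaks$out_of_range <- oor
  peaks
}

#' Bind calibrated peaks to panel targets
#'
#' For each target (processed in ascending expected size) the unassigned
#' peak in the target's dye within `size_tolerance` bp and with maximal
#' height is bound; height ties break toward the smaller size error, then
#' the smaller size. Unmatched targets are absent; unmatched peaks are
#' orphans. The result does not depend on the input row order.
#'
#' @param peaks Calibrated peak `data.frame` (`dye`, `size`, `height`).
#' @param panel A `thal_panel`.
#' @param size_tolerance Binding tolerance (bp); default the panel's.
#' @return A `thal_binding`: list with `assignments` (named list of one-row
#'   peak data.frames or `NULL` for absent targets) and `orphans`.
#' @export
bind_peaks <- function(peaks, panel, size_tolerance = panel$size_tolerance) {
  stopifnot(inherits(panel, "thal_panel"))
  pk <- peaks[!is.na(peaks$size) & peaks$dye != "LIZ", , drop = FALSE]
  pk <- pk[order(pk$dye, pk$size, pk$height), , drop = FALSE]  # canonical order
  rownames(pk) <- NULL
  used <- rep(FALSE, nrow(pk))
  tg <- panel$targets[order(panel$targets$expected_size), , drop = FALSE]
  assignments <- stats::setNames(vector("list", nrow(tg)), tg$name)
  for (i in seq_len(nrow(tg))) {
    err <- abs(pk$size - tg$expected_size[i])
    cand <- which(!used & pk$dye == tg$dye[i] & err <= size_tolerance)
    if (!length(cand)) next
    o <- cand[order(-pk$height[cand], err[cand], pk$size[cand])][1]
    used[o] <- TRUE
    assignments[[tg$name[i]]] <- pk[o, , drop = FALSE]
  }
  structure(list(assignments = assignments,
                 orphans = pk[!used, , drop = FALSE]),
            class = "thal_binding")
}

#' Height of a bound target (0 when absent)
#' @param binding A `thal_binding`.
#' @param target Target name.
#' @return Height in RFU.
#' @export
bound_height <- function(binding, target) {
  p <- binding$assignments[[target]]
  if (is.null(p)) 0 else p$height
}

#' Names of targets bound to a peak
#' @param binding A `thal_binding`.
#' @return Character vector of present target names.
#' @export
bound_targets <- function(binding) {
  names(binding$assignments)[!vapply(binding$assignments, is.null,
                                     logical(1))]
}
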