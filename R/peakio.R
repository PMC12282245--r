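# Peak-table (CSV) and raw-trace (JSON) I/O. These stand in for
# GeneMapper-style peak exports and .fsa raw data; the native formats are
# plain text so fixtures can be built and diffed anywhere.

#' Construct a peak table
#'
#' @param sample_id Sample identifier.
#' @param peaks `data.frame` with columns `dye`, `size` (bp, `NA` before
#'   calibration), `height` (RFU), and optionally `area` and
#'   `scan_position`.
#' @param metadata Free-form named list (instrument, run date, ...).
#' @return A `thal_peak_table`.
#' @export
peak_table <- function(sample_id, peaks, metadata = list()) {
  if (nrow(peaks) == 0L && !all(c("dye", "size", "height") %in% names(peaks)))
    peaks <- data.frame(dye = character(), size = numeric(),
                        height = numeric(), area = numeric(),
                        scan_position = integer(),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("dye", "size", "height") %in% names(peaks)))
  if (!all(peaks$dye %in% DYE_LEVELS))
    stop("unknown dye(s): ", paste(setdiff(peaks$dye, DYE_LEVELS),
                                   collapse = ", "), call. = FALSE)
  if (any(peaks$height < 0, na.rm = TRUE))
    stop("peak heights must be >= 0", call. = FALSE)
  if (is.null(peaks$area)) peaks$area <- NA_real_
  if (is.null(peaks$scan_position)) peaks$scan_position <- NA_integer_
  rownames(peaks) <- NULL
  structure(list(sample_id = as.character(sample_id), peaks = peaks,
                 metadata = metadata), class = "thal_peak_table")
}

#' @export
print.thal_peak_table <- function(x, ...) {
  cat("<thal_peak_table>", x$sample_id, "-", nrow(x$peaks), "peaks\n")
  invisible(x)
}

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)  # round-trips doubles exactly
  out[is.na(x)] <- ""
  out
}

#' Write a peak table to CSV
#'
#' Columns `sample_id,dye,size_bp,height,area` in fixed order; floats are
#' written with full precision so read/write round-trips exactly.
#'
#' @param table A `thal_peak_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "thal_peak_table"))
  p <- table$peaks
  df <- data.frame(sample_id = rep(table$sample_id, nrow(p)),
                   dye = p$dye, size_bp = .fmt_num(p$size),
                   height = .fmt_num(p$height), area = .fmt_num(p$area),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a peak table from CSV
#'
#' Rows with unknown dyes or non-numeric heights are rejected, not silently
#' dropped: the returned table carries a `rejections` attribute naming each
#' bad row, and every input row is either kept or reported there.
#'
#' @param path CSV with header `sample_id,dye,size_bp,height[,area]`.
#' @return A `thal_peak_table` (with attribute `rejections`).
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("sample_id", "dye", "size_bp", "height")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("peak table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(df$area)) df$area <- ""
  num <- function(x) suppressWarnings(as.numeric(x))
  height <- num(df$height)
  rej <- list()
  bad_height <- which(is.na(height) & nzchar(df$height) |
                        !nzchar(df$height))
  for (i in bad_height)
    rej[[length(rej) + 1L]] <- sprintf(
      "row %d: non-numeric height '%s'", i, df$height[i])
  bad_dye <- which(!(df$dye %in% DYE_LEVELS))
  for (i in bad_dye)
    rej[[length(rej) + 1L]] <- sprintf("row %d: unknown dye '%s'", i,
                                       df$dye[i])
  keep <- setdiff(seq_len(nrow(df)), union(bad_height, bad_dye))
  peaks <- data.frame(dye = df$dye[keep], size = num(df$size_bp)[keep],
                      height = height[keep], area = num(df$area)[keep],
                      scan_position = rep(NA_integer_, length(keep)),
                      stringsAsFactors = FALSE)
  sid <- if (nrow(df)) df$sample_id[[1]] else "unknown"
  out <- peak_table(sid, peaks)
  attr(out, "rejections") <- unlist(rej) %||% character()
  out
}

# ---------------------------------------------------------------------------

#' Construct a raw sample trace
#'
#' @param sample_id Sample identifier.
#' @param channels Named list of numeric signal vectors (RFU per scan) for
#'   `FAM`, `VIC`, `NED` and `LIZ`; all the same length.
#' @return A `thal_trace`.
#' @export
sample_trace <- function(sample_id, channels) {
  need <- c("FAM", "VIC", "NED", "LIZ")
  if (!all(need %in% names(channels)))
    stop("trace needs channels ", paste(need, collapse = ", "),
         call. = FALSE)
  channels <- lapply(channels[need], as.numeric)
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("ragged trace: channel lengths differ (",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  if (!all(vapply(channels, function(x) all(is.finite(x)), logical(1))))
    stop("trace signal must be finite", call. = FALSE)
  structure(list(sample_id = as.character(sample_id), channels = channels,
                 scan_count = unname(lens[[1]])), class = "thal_trace")
}

#' @export
print.thal_trace <- function(x, ...) {
  cat("<thal_trace>", x$sample_id, "-", x$scan_count, "scans\n")
  invisible(x)
}

#' Write a trace to JSON
#' @param trace A `thal_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "thal_trace"))
  doc <- c(list(sample_id = trace$sample_id, scans = trace$scan_count),
           trace$channels)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace from JSON
#' @param path Trace JSON file.
#' @return A `thal_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sample_id", "FAM", "VIC", "NED", "LIZ")
  missing_f <- setdiff(need, names(doc))
  if (length(missing_f))
    stop("trace file is missing field(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  sample_trace(doc$sample_id, doc[c("FAM", "VIC", "NED", "LIZ")])
}
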