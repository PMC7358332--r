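#' Construct a regional-scan object
#'
#' A `regional_scan` bundles one scan's numeric time-by-regions matrix with
#' its sampling interval, identifying labels, and a list of contiguous
#' segments.  Segments mark rows that are temporally contiguous in the
#' original recording: model fitting never forms a lagged (predictor,
#' response) pair that straddles a segment boundary, which is what makes
#' scrubbing, block concatenation and interleaved subsampling safe for
#' lag-based connectivity estimation.
#'
#' @param data numeric matrix, rows = timepoints, columns = regions.
#' @param tr sampling interval in seconds.
#' @param subject_id,condition,run character labels attached to the scan.
#' @param segments integer matrix with columns `start`, `end` (1-based,
#'   inclusive) partitioning `1:nrow(data)` into ordered contiguous blocks.
#'   Default: one segment covering all rows.
#' @param region_names optional character vector of column names.
#' @return An object of class `regional_scan`.
#' @seealso [read_scan()], [fit_var()], [scrub()]
#' @export
regional_scan <- function(data, tr, subject_id = "s1", condition = "cond",
                          run = "r1", segments = NULL, region_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("scan data must be numeric")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) stop("scan data must be finite")
  if (!is.null(region_names)) colnames(data) <- region_names
  if (is.null(colnames(data))) {
    colnames(data) <- paste0("R", seq_len(ncol(data)))
  }
  if (is.null(segments)) segments <- cbind(start = 1L, end = nrow(data))
  segments <- validate_segments(segments, nrow(data))
  if (nrow(data) <= ncol(data)) {
    stop("dimensionality error: need more timepoints than regions (T = ",
         nrow(data), ", R = ", ncol(data), ")")
  }
  structure(
    list(data = data, tr = as.numeric(tr), subject_id = as.character(subject_id),
         condition = as.character(condition), run = as.character(run),
         segments = segments),
    class = "regional_scan")
}

validate_segments <- function(segments, T) {
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) == 0) stop("empty segment list")
  if (any(segments[, 1] > segments[, 2])) stop("segment start after end")
  rows <- unlist(lapply(seq_len(nrow(segments)),
                        function(i) segments[i, 1]:segments[i, 2]))
  if (length(rows) != T || any(sort(rows) != seq_len(T))) {
    stop("segments must partition all ", T, " retained rows")
  }
  if (is.unsorted(segments[, 1])) stop("segments must be sorted")
  segments
}

#' @export
print.regional_scan <- function(x, ...) {
  cat("Regional scan: ", nrow(x$data), " timepoints x ", ncol(x$data),
      " regions (TR = ", x$tr, " s)\n", sep = "")
  cat("  subject ", x$subject_id, ", condition ", x$condition,
      ", run ", x$run, ", ", nrow(x$segments), " segment(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.regional_scan <- function(x) dim(x$data)

#' Number of regions in a scan
#' @param scan a `regional_scan`.
#' @return integer count of regions (columns).
#' @export
n_regions <- function(scan) ncol(scan$data)

#' Read a regional time-series scan from delimited text
#'
#' Rows are timepoints and columns are regions; an optional header row gives
#' region names.  Field separator is auto-detected (tab, comma, or
#' whitespace).
#'
#' @param path file path.
#' @param tr sampling interval in seconds.
#' @param subject_id,condition,run metadata labels.
#' @param header logical; `NA` (default) auto-detects a non-numeric first row.
#' @return A [regional_scan()] with a single segment covering all rows.
#' @export
read_scan <- function(path, tr, subject_id = "s1", condition = "cond",
                      run = "r1", header = NA) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  if (is.na(header)) {
    fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
    header <- anyNA(suppressWarnings(as.numeric(fields)))
  }
  df <- read.table(path, header = header, sep = sep)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("parse error: non-numeric cell in ", path)
  regional_scan(m, tr = tr, subject_id = subject_id, condition = condition,
                run = run,
                region_names = if (header) colnames(df) else NULL)
}

#' Write a scan to tab-separated text with a JSON metadata side-car
#'
#' @param scan a `regional_scan`.
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  write.table(scan$data, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(tr = scan$tr, subject_id = scan$subject_id,
               condition = scan$condition, run = scan$run,
               segments = unname(scan$segments))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# Replace a scan's data/segments, keeping metadata.
scan_update <- function(scan, data, segments, tr = scan$tr) {
  regional_scan(data, tr = tr, subject_id = scan$subject_id,
                condition = scan$condition, run = scan$run,
                segments = segments)
}

# Row indices of each segment as a list.
segment_rows <- function(scan) {
  lapply(seq_len(nrow(scan$segments)),
         function(i) scan$segments[i, 1]:scan$segments[i, 2])
}

#' Read a motion-parameter trace
#'
#' Whitespace-delimited text, one row per frame, six columns: translations
#' x, y, z in mm then rotations x, y, z in radians (or the reverse order).
#'
#' @param path file path.
#' @param rotations_first logical; TRUE if rotations occupy the first three
#'   columns.
#' @return numeric matrix with columns `tx, ty, tz, rx, ry, rz`.
#' @export
read_motion <- function(path, rotations_first = FALSE) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) < 6) stop("motion trace must have 6 columns")
  m <- m[, 1:6, drop = FALSE]
  if (rotations_first) m <- m[, c(4:6, 1:3), drop = FALSE]
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}
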