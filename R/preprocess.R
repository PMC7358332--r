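#' Truncate scans to a common minimum length
#'
#' Connectivity magnitudes depend on the number of samples used in
#' estimation, so scans entering the same comparison are first cut to the
#' shortest length among them.  Truncation keeps the initial rows;
#' segment lists are re-clipped accordingly.
#'
#' @param scans list of [regional_scan()] objects (at least two).
#' @return list of scans, all with the same (minimum) number of rows.
#' @export
truncate_to_common_length <- function(scans) {
  if (!is.list(scans) || length(scans) < 2) {
    stop("need at least two scans to truncate to a common length")
  }
  Tmin <- min(vapply(scans, function(s) nrow(s$data), integer(1)))
  lapply(scans, truncate_scan, Tmin = Tmin)
}

truncate_scan <- function(scan, Tmin) {
  if (nrow(scan$data) == Tmin) return(scan)
  seg <- scan$segments
  seg <- seg[seg[, 1] <= Tmin, , drop = FALSE]
  seg[, 2] <- pmin(seg[, 2], Tmin)
  scan_update(scan, scan$data[seq_len(Tmin), , drop = FALSE], seg)
}

#' Interleaved subsampling with concatenation
#'
#' Emulates estimation at a coarser sampling rate without discarding data:
#' the series is split into `factor` interleaved subsampled series (every
#' `factor`-th row, at each of the `factor` phases), which are concatenated
#' in order.  The sampling interval is multiplied by `factor` and a segment
#' boundary is inserted at every concatenation junction, so no lagged pair
#' spans the junction between two subsampled series.
#'
#' @param scan a [regional_scan()].
#' @param factor integer subsampling factor (2 or 3 in typical use).
#' @param offset integer in `0:(factor-1)`; rotates which phase leads the
#'   concatenation (0 = the series starting at the first row).
#' @return A [regional_scan()] with the same total number of rows, `tr`
#'   multiplied by `factor`, and one segment per (phase, original-segment)
#'   chunk.
#' @export
decimate_concat <- function(scan, factor, offset = 0L) {
  factor <- as.integer(factor)
  if (factor < 2) stop("usage error: subsampling factor must be >= 2")
  offset <- as.integer(offset) %% factor
  phases <- ((offset + seq_len(factor) - 1L) %% factor) + 1L
  pieces <- list()
  for (ph in phases) {
    for (rows in segment_rows(scan)) {
      keep <- rows[seq_along(rows) %% factor == ph %% factor]
      if (length(keep) > 0) pieces[[length(pieces) + 1L]] <- keep
    }
  }
  lens <- lengths(pieces)
  ends <- cumsum(lens)
  seg <- cbind(start = ends - lens + 1L, end = ends)
  scan_update(scan, scan$data[unlist(pieces), , drop = FALSE], seg,
              tr = scan$tr * factor)
}

#' Extract and concatenate blocks of a scan
#'
#' Used to assemble per-subtask series from a block-design scan: the rows of
#' each requested block are kept in temporal order, and each block becomes
#' its own segment so that the junction between two non-contiguous blocks is
#' never used for lagged estimation.
#'
#' @param scan a [regional_scan()].
#' @param blocks two-column matrix (or list of length-2 vectors) of 1-based
#'   inclusive `[start, end]` row intervals; must be disjoint and in order.
#' @return A [regional_scan()] containing only the block rows.
#' @export
concat_blocks <- function(scan, blocks) {
  if (is.list(blocks)) blocks <- do.call(rbind, blocks)
  blocks <- matrix(as.integer(blocks), ncol = 2)
  T <- nrow(scan$data)
  if (any(blocks < 1L) || any(blocks > T)) stop("block outside scan rows")
  if (any(blocks[, 1] > blocks[, 2])) stop("block start after end")
  rows <- unlist(lapply(seq_len(nrow(blocks)),
                        function(i) blocks[i, 1]:blocks[i, 2]))
  if (anyDuplicated(rows)) stop("usage error: overlapping blocks")
  lens <- blocks[, 2] - blocks[, 1] + 1L
  ends <- cumsum(lens)
  seg <- cbind(start = ends - lens + 1L, end = ends)
  scan_update(scan, scan$data[rows, , drop = FALSE], seg)
}

#' Framewise displacement from motion parameters
#'
#' Summarises per-frame head motion as the sum of absolute temporal
#' derivatives of the three translations (mm) plus the three rotations
#' (radians) converted to arc length on a sphere of radius
#' `rotation_radius_mm`.
#'
#' @param motion numeric matrix with 6 columns: translations x, y, z in mm
#'   then rotations x, y, z in radians (set `rotations_first = TRUE` if the
#'   file stores rotations in the first three columns).
#' @param rotation_radius_mm sphere radius for the rotation-to-displacement
#'   conversion; 50 mm is the common convention.
#' @param rotations_first logical; column-order switch.
#' @return nonnegative numeric vector of length `nrow(motion)`; the first
#'   frame has FD 0.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50,
                                   rotations_first = FALSE) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  if (nrow(motion) < 2) stop("need at least two frames")
  if (any(!is.finite(motion))) stop("motion parameters must be finite")
  if (rotations_first) motion <- motion[, c(4:6, 1:3), drop = FALSE]
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion scrubbing
#'
#' Frames whose framewise displacement exceeds `threshold` are discarded,
#' together with `n_neighbors` frames on each side (lag-based estimation at
#' model order p needs p clean preceding frames, so `n_neighbors` should be
#' the intended VAR order; the default 1 matches an order-1 model).
#' Remaining runs of contiguous frames become the new segments; runs crossing
#' an existing segment boundary stay split.
#'
#' @param scan a [regional_scan()].
#' @param fd framewise-displacement vector of length `nrow(scan$data)`.
#' @param threshold displacement threshold in mm (default 0.5).
#' @param n_neighbors frames to drop on each side of a flagged frame.
#' @return A scrubbed [regional_scan()].
#' @export
scrub <- function(scan, fd, threshold = 0.5, n_neighbors = 1L) {
  T <- nrow(scan$data)
  if (length(fd) != T) stop("fd length must equal scan length")
  bad <- which(fd > threshold)
  if (length(bad) > 0 && n_neighbors > 0) {
    bad <- unique(unlist(lapply(bad, function(t) {
      max(1L, t - n_neighbors):min(T, t + n_neighbors)
    })))
  }
  keep <- setdiff(seq_len(T), bad)
  if (length(keep) == 0) stop("empty scan: all frames scrubbed")
  seg_id <- integer(T)
  for (i in seq_len(nrow(scan$segments))) {
    seg_id[scan$segments[i, 1]:scan$segments[i, 2]] <- i
  }
  # new segment whenever retained rows are non-adjacent or cross old segments
  brk <- c(TRUE, diff(keep) != 1L | diff(seg_id[keep]) != 0L)
  grp <- cumsum(brk)
  lens <- tabulate(grp)
  ends <- cumsum(lens)
  seg <- cbind(start = ends - lens + 1L, end = ends)
  scan_update(scan, scan$data[keep, , drop = FALSE], seg)
}
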