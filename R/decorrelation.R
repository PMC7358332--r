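#' ZCA (Mahalanobis) whitening of a scan
#'
#' Purges instantaneous correlations: with covariance `C = E D E'`, the
#' transform `W = E D^{-1/2} E' = C^{-1/2}` yields whitened data with
#' identity covariance that are, among all whitening transforms, closest to
#' the original data in least squares.  Because the transform is anchored
#' to the original region axes, whitened dimensions correspond one-to-one
#' across subjects.
#'
#' @param scan a [regional_scan()].
#' @param shrinkage scalar in `[0, 1)`; shrink the covariance toward
#'   `mean(diag(C)) I` before whitening (required if `C` is rank
#'   deficient).
#' @return list with `scan` (whitened [regional_scan()]) and `transform`
#'   (class `whitening_transform` holding the matrix, method, covariance
#'   and eigen diagnostics).
#' @export
zca_whiten <- function(scan, shrinkage = 0) {
  C <- lagged_covariance(scan, 0L)$matrix
  if (shrinkage > 0) {
    C <- (1 - shrinkage) * C + shrinkage * mean(diag(C)) * diag(nrow(C))
  }
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values)) {
    stop("rank-deficient covariance: rerun with shrinkage > 0")
  }
  Wz <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  Wz <- (Wz + t(Wz)) / 2
  out <- project_scan(scan, Wz)
  tr <- structure(list(matrix = Wz, method = "zca", C = C,
                       D = eg$values, E = eg$vectors),
                  class = "whitening_transform")
  list(scan = out, transform = tr)
}

#' Joint decorrelation of two scans via generalized eigenvectors
#'
#' Finds a single projection `G` that diagonalizes the covariances of both
#' datasets (`G' C_T G` and `G' C_R G` diagonal), so both scans are purged
#' of instantaneous correlations in one shared basis.  The default
#' construction whitens by the first covariance and eigendecomposes the
#' whitened second covariance, which jointly diagonalizes exactly;
#' `method = "literal"` instead uses the product `E_T D_T^{-1/2} E_R` of
#' the two separate eigendecompositions, provided for comparison (it does
#' not jointly diagonalize in general).
#'
#' @param task_scan,rest_scan [regional_scan()] objects with the same
#'   regions.
#' @param method `"whiten"` (default) or `"literal"`.
#' @param shrinkage covariance shrinkage as in [zca_whiten()].
#' @return list with `task`, `rest` (projected scans) and `transform`.
#' @export
gev_decorrelate <- function(task_scan, rest_scan,
                            method = c("whiten", "literal"),
                            shrinkage = 0) {
  method <- match.arg(method)
  shrink <- function(C) {
    if (shrinkage > 0) {
      (1 - shrinkage) * C + shrinkage * mean(diag(C)) * diag(nrow(C))
    } else C
  }
  CT <- shrink(lagged_covariance(task_scan, 0L)$matrix)
  CR <- shrink(lagged_covariance(rest_scan, 0L)$matrix)
  egT <- eigen(CT, symmetric = TRUE)
  if (min(egT$values) < 1e-10 * max(egT$values)) {
    stop("rank-deficient covariance: rerun with shrinkage > 0")
  }
  egR <- eigen(CR, symmetric = TRUE)
  if (method == "whiten") {
    W1 <- egT$vectors %*% (t(egT$vectors) / sqrt(egT$values))
    M <- W1 %*% CR %*% W1
    egM <- eigen((M + t(M)) / 2, symmetric = TRUE)
    G <- W1 %*% egM$vectors
  } else {
    G <- egT$vectors %*% (diag(1 / sqrt(egT$values)) %*% egR$vectors)
  }
  tr <- structure(list(matrix = G, method = paste0("gev-", method),
                       C_T = CT, C_R = CR,
                       D_T = egT$values, E_T = egT$vectors,
                       E_R = egR$vectors),
                  class = "whitening_transform")
  list(task = project_scan(task_scan, t(G)),
       rest = project_scan(rest_scan, t(G)),
       transform = tr)
}

# apply a linear map M to each (demeaned-per-segment) row vector: y = M x
project_scan <- function(scan, M) {
  out <- scan$data
  for (rows in segment_rows(scan)) {
    seg <- scan$data[rows, , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    out[rows, ] <- seg %*% t(M)
  }
  colnames(out) <- colnames(scan$data)
  scan_update(scan, out, scan$segments)
}

#' @export
print.whitening_transform <- function(x, ...) {
  cat("Whitening transform (", x$method, "), ", nrow(x$matrix),
      " dimensions\n", sep = "")
  invisible(x)
}
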