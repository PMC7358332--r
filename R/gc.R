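#' Conditional Granger-Geweke measures for one region pair
#'
#' Decomposes the conditional linear dependence between regions `i` and `j`
#' (conditioning set z = all remaining regions) into directed feedback
#' `F_{i->j|z}`, `F_{j->i|z}` and the instantaneous term `F_{i.j|z}`.
#' The two-stage estimator compares the residual variance of the target
#' region between a reduced VAR fitted without the source region and the
#' full VAR on all regions; the instantaneous term is
#' `log(S_ii * S_jj / det(S_[ij]))` on the full-model residual covariance S.
#' The full measure is the log ratio comparing the joint model to the two
#' separate reduced models, and equals the sum of the three components.
#'
#' @param scan a [regional_scan()].
#' @param i,j distinct region indices (or names).
#' @param order VAR order.
#' @return named numeric vector with elements `f_ij` (i to j), `f_ji`,
#'   `f_inst`, `f_full`.
#' @export
conditional_gc_pair <- function(scan, i, j, order = 1L) {
  R <- ncol(scan$data)
  if (is.character(i)) i <- match(i, colnames(scan$data))
  if (is.character(j)) j <- match(j, colnames(scan$data))
  if (i == j) stop("regions must be distinct")
  full <- fit_var(scan, order)
  S <- full$resid_cov
  red_i <- fit_var(scan_subset(scan, setdiff(seq_len(R), i)), order)$resid_cov
  red_j <- fit_var(scan_subset(scan, setdiff(seq_len(R), j)), order)$resid_cov
  v_j_wo_i <- red_i[region_pos(j, i), region_pos(j, i)]
  v_i_wo_j <- red_j[region_pos(i, j), region_pos(i, j)]
  gc_terms(v_i_wo_j, v_j_wo_i, S[i, i], S[j, j], S[i, j])
}

region_pos <- function(target, removed) target - (target > removed)

gc_terms <- function(v_i_red, v_j_red, s_ii, s_jj, s_ij) {
  det2 <- s_ii * s_jj - s_ij^2
  if (any(c(v_i_red, v_j_red, s_ii, s_jj, det2) <= 0)) {
    stop("numerical degeneracy: nonpositive variance ratio")
  }
  f_ij <- log(v_j_red / s_jj)
  f_ji <- log(v_i_red / s_ii)
  f_inst <- log(s_ii * s_jj / det2)
  c(f_ij = f_ij, f_ji = f_ji, f_inst = f_inst, f_full = f_ij + f_ji + f_inst)
}

scan_subset <- function(scan, cols) {
  scan_update(scan, scan$data[, cols, drop = FALSE], scan$segments)
}

#' Full connectivity matrices for a scan
#'
#' Computes, for every region pair with the remaining regions as
#' conditioning set: the symmetric instantaneous GC matrix (`igc`), the
#' directed GC matrix (`dgc`, destination in rows and source in columns),
#' the full linear-dependence matrix (`full`), and partial correlations
#' (`pc`).  The two-stage estimator fits one full VAR plus one reduced VAR
#' per region and reuses each reduced fit for all of its target regions.
#'
#' @param scan a [regional_scan()].
#' @param order VAR order, or `"auto"` for AIC selection.
#' @param p_max maximum order considered when `order = "auto"`.
#' @return An object of class `gc_matrices` with fields `igc`, `dgc`,
#'   `full`, `pc`, `order`, `estimator`, `region_names`.  Diagonals of the
#'   GC matrices are zero; `pc` has unit diagonal.
#' @examples
#' m <- var_model(rbind(c(0.5, 0), c(0.5, 0.5)))
#' sc <- regional_scan(simulate(m, nsim = 2000, seed = 1), tr = 1)
#' gc_matrices(sc, order = 1)
#' @export
gc_matrices <- function(scan, order = "auto", p_max = 8L) {
  if (identical(order, "auto")) order <- select_order_aic(scan, p_max)
  R <- ncol(scan$data)
  full <- fit_var(scan, order)
  S <- full$resid_cov
  red_var <- matrix(NA_real_, R, R)  # [target, removed]
  for (i in seq_len(R)) {
    red <- fit_var(scan_subset(scan, setdiff(seq_len(R), i)), order)
    v <- diag(red$resid_cov)
    red_var[-i, i] <- v
  }
  build_gc_matrices(S, red_var, order, "two-stage", full$region_names,
                    pc = partial_correlation(scan))
}

build_gc_matrices <- function(S, red_var, order, tag, nm, pc) {
  R <- nrow(S)
  igc <- dgc <- fullm <- matrix(0, R, R, dimnames = list(nm, nm))
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      tm <- gc_terms(red_var[i, j], red_var[j, i], S[i, i], S[j, j], S[i, j])
      dgc[j, i] <- tm["f_ij"]      # source i (column), destination j (row)
      dgc[i, j] <- tm["f_ji"]
      igc[i, j] <- igc[j, i] <- tm["f_inst"]
      fullm[i, j] <- fullm[j, i] <- tm["f_full"]
    }
  }
  structure(list(igc = igc, dgc = dgc, full = fullm, pc = pc,
                 order = order, estimator = tag, region_names = nm),
            class = "gc_matrices")
}

#' One-stage directed GC from a single full regression
#'
#' Fits the full VAR once and obtains each reduced model's innovation
#' variance analytically from the fitted parameters: the autocovariance
#' sequence implied by the full model is truncated at convergence, and the
#' innovation covariance of each leave-one-region-out subprocess is solved
#' from its block-Toeplitz prediction problem.  No second regression is run
#' on the data.
#'
#' @inheritParams gc_matrices
#' @param q_max largest predictor depth used when solving the reduced
#'   models' prediction problems.
#' @return A `gc_matrices` object with `estimator = "one-stage"`.
#' @export
one_stage_gc <- function(scan, order = "auto", p_max = 8L, q_max = 64L) {
  if (identical(order, "auto")) order <- select_order_aic(scan, p_max)
  full <- fit_var(scan, order)
  if (!is_stable(full)) stop("unstable full model; one-stage GC undefined")
  gm <- analytic_gc(full, q_max = q_max, tag = "one-stage")
  gm$pc <- partial_correlation(scan)
  gm
}

#' Population-level GC of a known VAR model
#'
#' Treats the model's parameters as the truth and returns exact
#' population values of all GC measures: the full-model innovation
#' covariance is the model's own, and reduced-model innovation variances
#' are solved from the model-implied autocovariances.  Population GC values
#' are nonnegative and free of estimation bias, which makes this the
#' oracle against which sample estimators are checked.
#'
#' @param model a stable `slowgc_var` (e.g. from [var_model()] or
#'   [discretize_ou()]).
#' @param q_max predictor depth cap for the reduced prediction problems.
#' @return A `gc_matrices` object with `estimator = "population"`.
#' @export
population_gc <- function(model, q_max = 64L) {
  if (!is_stable(model)) stop("model is not stable")
  analytic_gc(model, q_max = q_max, tag = "population")
}

analytic_gc <- function(model, q_max, tag) {
  R <- nrow(model$resid_cov)
  S <- model$resid_cov
  G <- acov_var(model$coeffs, S, q_max)
  red_var <- matrix(NA_real_, R, R)
  for (i in seq_len(R)) {
    keep <- setdiff(seq_len(R), i)
    Gsub <- lapply(G, function(M) M[keep, keep, drop = FALSE])
    W <- innovation_cov_grow(Gsub)
    red_var[keep, i] <- diag(W)
  }
  pc <- pc_from_cov(G[[1]])
  build_gc_matrices(S, red_var, model$order, tag, model$region_names, pc)
}

# grow predictor depth q until the innovation log-determinant stabilises
innovation_cov_grow <- function(G, tol = 1e-10) {
  q_max <- length(G) - 1L
  q <- 2L
  prev <- innovation_cov(G, min(q, q_max))
  while (q < q_max) {
    q2 <- min(2L * q, q_max)
    cur <- innovation_cov(G, q2)
    if (abs(determinant(cur)$modulus - determinant(prev)$modulus) < tol) {
      return(cur)
    }
    prev <- cur
    q <- q2
  }
  prev
}

#' Partial correlations of a scan
#'
#' `PC_ij = -P_ij / sqrt(P_ii P_jj)` with P the inverse of the pooled
#' (per-segment demeaned) sample covariance.
#'
#' @param scan a [regional_scan()] or a covariance matrix.
#' @param shrinkage scalar in `[0, 1)`; if positive, the covariance is
#'   shrunk toward `mean(diag(C)) * I` before inversion.
#' @return symmetric matrix with unit diagonal.
#' @export
partial_correlation <- function(scan, shrinkage = 0) {
  C <- if (inherits(scan, "regional_scan")) {
    lagged_covariance(scan, 0L)$matrix
  } else {
    as.matrix(scan)
  }
  if (shrinkage > 0) {
    C <- (1 - shrinkage) * C + shrinkage * mean(diag(C)) * diag(nrow(C))
  }
  pc_from_cov(C)
}

pc_from_cov <- function(C) {
  P <- tryCatch(solve(C), error = function(e) {
    stop("singular covariance; rerun with shrinkage > 0")
  })
  if (rcond(C) < 1e-12) stop("singular covariance; rerun with shrinkage > 0")
  d <- 1 / sqrt(diag(P))
  pc <- -P * outer(d, d)
  # partial correlations at double-precision round-off are numerically zero
  pc[abs(pc) < 1e-10] <- 0
  diag(pc) <- 1
  dimnames(pc) <- dimnames(C)
  (pc + t(pc)) / 2
}

#' @export
print.gc_matrices <- function(x, ...) {
  R <- nrow(x$igc)
  cat("Granger-Geweke connectivity (", x$estimator, " estimator, order ",
      x$order, "), ", R, " regions\n", sep = "")
  cat("  iGC range: [", format(min(x$igc), digits = 3), ", ",
      format(max(x$igc), digits = 3), "]  dGC range: [",
      format(min(x$dgc), digits = 3), ", ",
      format(max(x$dgc), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Heatmap display of connectivity matrices
#'
#' @param x a `gc_matrices` object.
#' @param which one of `"igc"`, `"dgc"`, `"full"`, `"pc"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.gc_matrices <- function(x, which = c("igc", "dgc", "full", "pc"), ...) {
  which <- match.arg(which)
  M <- x[[which]]
  R <- nrow(M)
  image(seq_len(R), seq_len(R), t(M[R:1, , drop = FALSE]),
        xlab = "source", ylab = "destination", axes = FALSE,
        main = toupper(which), ...)
  axis(1, at = seq_len(R), labels = colnames(M), las = 2, cex.axis = 0.7)
  axis(2, at = seq_len(R), labels = rev(rownames(M)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Entrywise average of connectivity estimates across runs
#'
#' @param ... two or more `gc_matrices` objects (or a single list of them)
#'   with matching shape and estimator.
#' @return A `gc_matrices` object of entrywise means.
#' @export
average_runs <- function(...) {
  gcs <- list(...)
  if (length(gcs) == 1 && !inherits(gcs[[1]], "gc_matrices")) gcs <- gcs[[1]]
  tags <- vapply(gcs, function(g) g$estimator, character(1))
  if (length(unique(tags)) != 1) stop("estimator mismatch across runs")
  Rs <- vapply(gcs, function(g) nrow(g$igc), integer(1))
  if (length(unique(Rs)) != 1) stop("shape mismatch across runs")
  out <- gcs[[1]]
  for (f in c("igc", "dgc", "full", "pc")) {
    out[[f]] <- Reduce(`+`, lapply(gcs, `[[`, f)) / length(gcs)
  }
  out
}

#' Flat edge list of connectivity values
#'
#' @param gc a `gc_matrices` object.
#' @return data frame with columns `source`, `destination`, `measure`,
#'   `value`; symmetric measures appear once per unordered pair.
#' @export
gc_edge_list <- function(gc) {
  nm <- gc$region_names
  R <- length(nm)
  rows <- list()
  for (ms in c("igc", "pc", "full")) {
    idx <- which(upper.tri(gc[[ms]]), arr.ind = TRUE)
    rows[[ms]] <- data.frame(source = nm[idx[, 1]],
                             destination = nm[idx[, 2]], measure = ms,
                             value = gc[[ms]][idx])
  }
  idx <- which(row(gc$dgc) != col(gc$dgc), arr.ind = TRUE)
  rows$dgc <- data.frame(source = nm[idx[, 2]],
                         destination = nm[idx[, 1]], measure = "dgc",
                         value = gc$dgc[idx])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read connectivity matrices
#'
#' JSON serialization carries the four matrices as nested arrays plus the
#' estimator metadata; `format = "tsv"` writes the [gc_edge_list()].
#'
#' @param gc a `gc_matrices` object.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gc <- function(gc, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(gc_edge_list(gc), path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  } else {
    jsonlite::write_json(
      list(igc = gc$igc, dgc = gc$dgc, full = gc$full, pc = gc$pc,
           order = gc$order, estimator = gc$estimator,
           region_names = gc$region_names),
      path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(path)
}

#' @rdname write_gc
#' @export
read_gc <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- j$region_names
  shape <- function(M) {
    M <- as.matrix(M); dimnames(M) <- list(nm, nm); M
  }
  structure(list(igc = shape(j$igc), dgc = shape(j$dgc),
                 full = shape(j$full), pc = shape(j$pc),
                 order = j$order, estimator = j$estimator,
                 region_names = nm),
            class = "gc_matrices")
}
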