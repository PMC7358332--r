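#' Canonical double-gamma hemodynamic response kernel
#'
#' The kernel is the difference of two gamma densities (response peak near
#' 5-6 s, later undershoot), shifted right by `onset_latency` and truncated
#' at `length` seconds.  Defaults match the canonical parameterisation
#' (peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' peak:undershoot ratio 6, 32 s support); the kernel is normalised to unit
#' sum so convolution preserves the scale of a constant input.
#'
#' @param dt sampling step of the kernel in seconds (0.1 s or finer
#'   recommended).
#' @param onset_latency delay before the response begins, seconds.
#' @param peak_delay,undershoot_delay gamma means in seconds.
#' @param peak_disp,undershoot_disp gamma dispersions.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length kernel support in seconds.
#' @param normalize divide by the kernel sum (default TRUE).
#' @return numeric vector of kernel samples at `0, dt, 2 dt, ...`.
#' @export
hrf_kernel <- function(dt, onset_latency = 0, peak_delay = 6,
                       undershoot_delay = 16, peak_disp = 1,
                       undershoot_disp = 1, ratio = 6, length = 32,
                       normalize = TRUE) {
  if (onset_latency < 0) stop("onset latency must be nonnegative")
  t <- seq(0, length, by = dt) - onset_latency
  h <- dgamma(t, shape = peak_delay / peak_disp, rate = 1 / peak_disp) -
    dgamma(t, shape = undershoot_delay / undershoot_disp,
           rate = 1 / undershoot_disp) / ratio
  h[t < 0] <- 0
  if (normalize) {
    s <- sum(h)
    if (s <= 0) stop("kernel does not integrate to a positive value")
    h <- h / s
  }
  h
}

# causal FFT convolution: y[t] = sum_{k>=0} h[k+1] x[t-k]
fft_convolve_causal <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                     stats::fft(c(h, rep(0, nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_along(x)]
}

#' Convolve latent neural series with HRFs and sample at the scan rate
#'
#' Each column (node) is convolved causally with its own hemodynamic
#' kernel, the initial kernel-length transient is discarded, and the result
#' is decimated from the simulation step `sim_dt` to the output sampling
#' interval `tr_out`.
#'
#' @param series numeric matrix of latent activity, rows = time at `sim_dt`.
#' @param sim_dt simulation step, seconds; must divide `tr_out`.
#' @param tr_out output sampling interval, seconds.
#' @param onset_latency scalar or per-node vector of HRF onset latencies.
#' @param noise_frac additive Gaussian measurement noise, expressed as a
#'   fraction of each output channel's temporal SD (0 = noiseless
#'   convolution; scanner thermal noise makes a nonzero value realistic).
#' @param ... further kernel parameters passed to [hrf_kernel()].
#' @param tr,subject_id,condition,run metadata for the returned scan.
#' @return A [regional_scan()] sampled at `tr_out`.
#' @export
neural_to_bold <- function(series, sim_dt, tr_out, onset_latency = 0,
                           noise_frac = 0, ...,
                           subject_id = "s1", condition = "cond",
                           run = "r1") {
  series <- as.matrix(series)
  N <- ncol(series)
  ratio <- tr_out / sim_dt
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("sim_dt must divide tr_out")
  }
  ratio <- round(ratio)
  if (length(onset_latency) == 1) onset_latency <- rep(onset_latency, N)
  if (length(onset_latency) != N) {
    stop("need one onset latency per node (", N, "), got ",
         length(onset_latency))
  }
  kernels <- lapply(onset_latency, function(mu) {
    hrf_kernel(dt = sim_dt, onset_latency = mu, ...)
  })
  klen <- max(lengths(kernels))
  bold <- vapply(seq_len(N), function(j) {
    fft_convolve_causal(series[, j], kernels[[j]])
  }, numeric(nrow(series)))
  bold <- bold[-seq_len(min(klen, nrow(bold) - 1L)), , drop = FALSE]
  keep <- seq(1L, nrow(bold), by = ratio)
  bold <- bold[keep, , drop = FALSE]
  if (noise_frac > 0) {
    sds <- apply(bold, 2, sd)
    bold <- bold + matrix(rnorm(length(bold)), nrow(bold)) %*%
      diag(noise_frac * sds, length(sds))
  }
  regional_scan(bold, tr = tr_out,
                subject_id = subject_id, condition = condition, run = run,
                region_names = colnames(series))
}
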