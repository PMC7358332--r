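#' Simulate a stationary VAR process
#'
#' Draws Gaussian innovations with the model's residual covariance and
#' iterates the autoregression; an initial burn-in of
#' `10 / (1 - spectral radius)` steps is discarded so the returned rows are
#' (approximately) stationary.
#'
#' @param object a stable `slowgc_var`.
#' @param nsim number of timepoints to return.
#' @param seed optional RNG seed for exact reproducibility.
#' @param burn burn-in length; default derived from the spectral radius.
#' @param ... unused.
#' @return numeric matrix `nsim` x R.
#' @export
simulate.slowgc_var <- function(object, nsim = 200, seed = NULL,
                                burn = NULL, ...) {
  if (!is_stable(object)) stop("cannot simulate an unstable model")
  if (!is.null(seed)) set.seed(seed)
  R <- nrow(object$resid_cov)
  p <- object$order
  if (is.null(burn)) {
    burn <- ceiling(10 / (1 - spectral_radius(object))) + p
  }
  n <- nsim + burn
  eg <- eigen(object$resid_cov, symmetric = TRUE)
  L <- eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0)))
  X <- matrix(rnorm(n * R), n, R) %*% L
  A <- lapply(object$coeffs, t)   # transposed once: x_t' += x_{t-k}' A_k'
  for (t in (p + 1):n) {
    for (k in seq_len(p)) {
      X[t, ] <- X[t, ] + X[t - k, ] %*% A[[k]]
    }
  }
  out <- X[(burn + 1):n, , drop = FALSE]
  colnames(out) <- object$region_names
  out
}

#' Two-node feedforward network
#'
#' One directed connection from node 1 to node 2, with identical node time
#' constants; the canonical probe for whether lag-based connectivity
#' survives slow sampling.
#'
#' @param timescale node time constant in seconds (e.g. 0.05 for a fast,
#'   1 for a slow network).
#' @param weight feedforward weight.
#' @return A [continuous_network()].
#' @export
two_node_network <- function(timescale, weight = 0.9) {
  W <- matrix(0, 2, 2)
  W[2, 1] <- weight
  continuous_network(W, tau = timescale)
}

#' Paired six-node networks with fast and slow subnetworks
#'
#' Two conditions ("A", "B"), each a six-node network whose nodes 1-3 form
#' a fast subnetwork (time constant `tau_fast`) and nodes 4-6 a slow one
#' (`tau_slow`).  The conditions differ in which directed connections are
#' present within each subnetwork, giving planted fast- and slow-timescale
#' connectivity differences for feature-selection experiments.
#'
#' @param weight feedforward connection weight.
#' @param tau_fast,tau_slow subnetwork time constants in seconds.
#' @return named list of two [continuous_network()] objects.
#' @export
dual_timescale_networks <- function(weight = 0.9, tau_fast = 0.05,
                                    tau_slow = 1) {
  tau <- c(rep(tau_fast, 3), rep(tau_slow, 3))
  mk <- function(edges) {
    W <- matrix(0, 6, 6)
    for (e in edges) W[e[1], e[2]] <- weight   # [dst, src]
    continuous_network(W, tau = tau)
  }
  list(A = mk(list(c(2, 1), c(3, 2), c(5, 4), c(6, 5))),
       B = mk(list(c(3, 1), c(2, 3), c(6, 4), c(5, 6))))
}

#' Two-node sweep of GC recoverability across sampling intervals
#'
#' Simulates the two-node feedforward network at a fine step, convolves
#' with the hemodynamic kernel, samples the result at each requested
#' interval, and estimates iGC, dGC (both directions) and PC on `n_time`
#' samples, repeated `reps` times.  Estimates are averaged across
#' repetitions and the averaged value of each measure is tested against a
#' null of equally rep-averaged phase-scrambling surrogates, with
#' Benjamini-Hochberg correction across the tested measures; per-repetition
#' surrogate significance fractions are reported alongside.
#'
#' @param timescale node time constant in seconds.
#' @param sampling_intervals vector of sampling intervals in seconds; each
#'   must be a multiple of `sim_dt`.
#' @param n_time timepoints per estimated series.
#' @param reps repetitions.
#' @param seed RNG seed.
#' @param weight feedforward weight.
#' @param n_surr phase-scrambling surrogates per repetition.
#' @param alpha significance level after BH correction.
#' @param sim_dt simulation step in seconds.
#' @param use_hrf convolve with the hemodynamic kernel before sampling.
#' @param noise_frac additive Gaussian measurement noise on the sampled
#'   series, as a fraction of each channel's SD (emulates scanner thermal
#'   noise).
#' @return data frame with one row per interval and measure (`dgc_true`,
#'   `dgc_rev`, `igc`, `pc`; PC reported as absolute value): the
#'   rep-averaged estimate, the per-rep significance fraction, the
#'   group-level surrogate `p_mean`, and the BH-corrected `significant`
#'   flag.
#' @export
two_node_experiment <- function(timescale, sampling_intervals = 0.75,
                                n_time = 200, reps = 25, seed = 1,
                                weight = 0.9, n_surr = 200, alpha = 0.05,
                                sim_dt = 0.005, use_hrf = TRUE,
                                noise_frac = 0.2) {
  set.seed(seed)
  net <- two_node_network(timescale, weight)
  dm <- discretize_ou(net, sim_dt)
  ratios <- sampling_intervals / sim_dt
  if (any(abs(ratios - round(ratios)) > 1e-9)) {
    stop("each sampling interval must be a multiple of sim_dt")
  }
  ratios <- as.integer(round(ratios))
  need <- n_time * max(ratios) + if (use_hrf) ceiling(36 / sim_dt) else 0L
  measures <- c("dgc_true", "dgc_rev", "igc", "pc")
  obs_all <- array(NA_real_, c(reps, length(ratios), 4))
  null_sum <- array(0, c(n_surr, length(ratios), 4))
  rep_sig <- array(NA, c(reps, length(ratios), 4))
  for (rep in seq_len(reps)) {
    x <- simulate(dm, nsim = need)
    series <- if (use_hrf) {
      neural_to_bold(x, sim_dt = sim_dt, tr_out = sim_dt)$data
    } else {
      x
    }
    for (iv in seq_along(ratios)) {
      sub <- series[seq(1L, nrow(series), by = ratios[iv]), , drop = FALSE]
      sub <- sub[seq_len(n_time), , drop = FALSE]
      if (noise_frac > 0) {
        sub <- sub + matrix(rnorm(length(sub)), nrow(sub)) %*%
          diag(noise_frac * apply(sub, 2, sd), ncol(sub))
      }
      obs <- two_node_measures(sub, sampling_intervals[iv])
      null <- matrix(NA_real_, n_surr, 4)
      for (s in seq_len(n_surr)) {
        sur <- apply(sub, 2, phase_scramble)
        null[s, ] <- two_node_measures(sur, sampling_intervals[iv])
      }
      null[, 4] <- abs(null[, 4])
      stat <- c(obs[1:3], abs(obs[4]))
      p <- vapply(1:4, function(k) {
        (1 + sum(null[, k] >= stat[k])) / (n_surr + 1)
      }, numeric(1))
      obs_all[rep, iv, ] <- stat
      null_sum[, iv, ] <- null_sum[, iv, ] + null
      rep_sig[rep, iv, ] <- p.adjust(p, "BH") < alpha
    }
  }
  out <- list()
  for (iv in seq_along(ratios)) {
    mean_obs <- colMeans(matrix(obs_all[, iv, ], ncol = 4))
    null_mean <- null_sum[, iv, ] / reps
    p_mean <- vapply(1:4, function(k) {
      (1 + sum(null_mean[, k] >= mean_obs[k])) / (n_surr + 1)
    }, numeric(1))
    out[[iv]] <- data.frame(
      interval = sampling_intervals[iv], measure = measures,
      mean_value = mean_obs,
      sig_fraction = colMeans(matrix(rep_sig[, iv, ], ncol = 4)),
      p_mean = p_mean,
      significant = p.adjust(p_mean, "BH") < alpha)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# iGC, dGC both directions and PC for a two-column matrix (order-1 VAR)
two_node_measures <- function(m, tr) {
  sc <- regional_scan(m, tr = tr)
  g <- gc_matrices(sc, order = 1)
  c(dgc_true = g$dgc[2, 1], dgc_rev = g$dgc[1, 2],
    igc = g$igc[1, 2], pc = g$pc[1, 2])
}

#' Specify a synthetic multi-subject, multi-condition cohort
#'
#' The generator emulates a panel of BOLD-like scans: per subject,
#' condition-specific latent networks perturbed by a subject-level weight
#' offset, hemodynamic convolution with subject-specific onset latencies
#' (relative latencies between nodes preserved within subject), sampling at
#' the scan interval, and behavioral scores loading linearly on the
#' subject's connectivity perturbation.
#'
#' @param conditions named list of [continuous_network()] objects, one per
#'   condition label.
#' @param n_subjects cohort size.
#' @param n_runs scan runs per subject and condition (runs share the
#'   subject's networks and latencies; connectivity is typically averaged
#'   across runs downstream).
#' @param between_subject_sd SD of the Gaussian weight perturbation shared
#'   by all of a subject's conditions.
#' @param perturb `"edges"` (default) perturbs only the union of nonzero
#'   connections across the condition networks, emulating individual
#'   variability in existing anatomical connections; `"all"` perturbs every
#'   weight entry.
#' @param latency_mean mean HRF onset latency in seconds (scalar or one per
#'   node).
#' @param sigma_latency SD of the subject-level onset-latency shift,
#'   seconds; shifts are resampled until all latencies are positive.
#' @param behavior_loadings optional matrix (n_scores x N^2) mapping the
#'   vectorized weight perturbation to score means.
#' @param score_noise_sd SD of additive score noise.
#' @param tr output sampling interval in seconds.
#' @param noise_frac additive measurement noise on each scan, as a
#'   fraction of channel SD.
#' @param sim_dt simulation step in seconds (must divide `tr`).
#' @param n_timepoints timepoints per scan.
#' @param seed RNG seed.
#' @return A `cohort_spec` list, validated.
#' @export
cohort_spec <- function(conditions, n_subjects = 20, n_runs = 1,
                        between_subject_sd = 0.05,
                        perturb = c("edges", "all"), latency_mean = 3,
                        sigma_latency = 0.2, behavior_loadings = NULL,
                        score_noise_sd = 1, tr = 0.75, noise_frac = 0.2,
                        sim_dt = 0.05, n_timepoints = 200, seed = 1) {
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("conditions must be a named list of networks")
  }
  Ns <- vapply(conditions, function(nt) nrow(nt$W), integer(1))
  if (length(unique(Ns)) != 1) stop("all condition networks must share N")
  if (!is.null(behavior_loadings) &&
      ncol(behavior_loadings) != Ns[1]^2) {
    stop("behavior_loadings must have N^2 = ", Ns[1]^2, " columns")
  }
  if (abs(tr / sim_dt - round(tr / sim_dt)) > 1e-9) {
    stop("sim_dt must divide tr")
  }
  perturb <- match.arg(perturb)
  structure(list(conditions = conditions, n_subjects = n_subjects,
                 n_runs = n_runs,
                 between_subject_sd = between_subject_sd, perturb = perturb,
                 latency_mean = latency_mean,
                 sigma_latency = sigma_latency,
                 behavior_loadings = behavior_loadings,
                 score_noise_sd = score_noise_sd, tr = tr,
                 noise_frac = noise_frac, sim_dt = sim_dt,
                 n_timepoints = n_timepoints, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of scans, scores and ground truth
#'
#' @param spec a [cohort_spec()].
#' @return list with `scans` (list of [regional_scan()], one per subject
#'   and condition), `scores` (matrix subjects x scores, or NULL), and
#'   `truth` (per-subject weight perturbations and latencies, plus the
#'   spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  N <- nrow(spec$conditions[[1]]$W)
  lat_mean <- rep(spec$latency_mean, length.out = N)
  scans <- list()
  mask <- if (spec$perturb == "edges") {
    Reduce(`|`, lapply(spec$conditions, function(nt) nt$W != 0)) * 1
  } else {
    matrix(1, N, N)
  }
  perturb <- vector("list", spec$n_subjects)
  latencies <- matrix(NA_real_, spec$n_subjects, N)
  steps <- ceiling((spec$n_timepoints * spec$tr + 40) / spec$sim_dt)
  for (s in seq_len(spec$n_subjects)) {
    nets <- NULL
    for (try in 1:100) {
      dW <- matrix(rnorm(N * N, sd = spec$between_subject_sd), N, N) * mask
      nets <- tryCatch(
        lapply(spec$conditions, function(nt) {
          continuous_network(nt$W + dW, nt$tau, nt$Sigma)
        }), error = function(e) NULL)
      if (!is.null(nets)) break
    }
    if (is.null(nets)) stop("could not perturb networks to stability")
    perturb[[s]] <- dW
    repeat {   # common shift preserves relative latencies within subject
      shift <- rnorm(1, 0, spec$sigma_latency)
      if (all(lat_mean + shift > 0)) break
    }
    latencies[s, ] <- lat_mean + shift
    for (cond in names(nets)) {
      dm <- discretize_ou(nets[[cond]], spec$sim_dt)
      for (run in seq_len(spec$n_runs)) {
        x <- simulate(dm, nsim = steps)
        sc <- neural_to_bold(x, sim_dt = spec$sim_dt, tr_out = spec$tr,
                             onset_latency = latencies[s, ],
                             noise_frac = spec$noise_frac,
                             subject_id = paste0("s", s), condition = cond,
                             run = paste0("r", run))
        scans[[length(scans) + 1]] <- truncate_scan(sc, spec$n_timepoints)
      }
    }
  }
  scores <- NULL
  if (!is.null(spec$behavior_loadings)) {
    L <- spec$behavior_loadings
    scores <- do.call(rbind, lapply(perturb, function(dW) {
      as.numeric(L %*% as.vector(dW))
    }))
    scores <- scores + matrix(rnorm(length(scores),
                                    sd = spec$score_noise_sd),
                              nrow(scores), ncol(scores))
    rownames(scores) <- paste0("s", seq_len(spec$n_subjects))
    colnames(scores) <- paste0("score", seq_len(ncol(scores)))
  }
  list(scans = scans,
       scores = scores,
       truth = list(perturbations = perturb, latencies = latencies,
                    spec = spec))
}

#' Cluster-pair connectivity experiment
#'
#' Builds two 100-neuron clusters connected through their port neurons with
#' a chosen sign pattern, simulates the neuron-level dynamics at a fine
#' step, averages to node level, convolves with the hemodynamic kernel,
#' samples at `tr_out`, and estimates node-level iGC, dGC (both directions)
#' and PC.  Estimates are averaged across repetitions and tested against
#' rep-averaged phase-scrambling surrogate nulls with Benjamini-Hochberg
#' correction.
#'
#' @param pattern `"feedforward"` (1 to 2 excitatory), `"ee"` (balanced
#'   excitatory feedback both ways) or `"ei"` (excitatory forward,
#'   inhibitory feedback, balanced in strength).
#' @param reps repetitions.
#' @param n_time timepoints per estimated series.
#' @param tr_out sampling interval in seconds.
#' @param n_surr surrogates per repetition.
#' @param alpha BH-corrected significance level.
#' @param sim_dt simulation step in seconds.
#' @param noise_frac measurement noise fraction.
#' @param seed RNG seed (also used for network construction).
#' @param ... further arguments to [build_cluster_network()].
#' @return data frame with one row per measure (`dgc_12`, `dgc_21`, `igc`,
#'   `pc`): rep-averaged value (absolute value for PC), per-rep significance
#'   fraction, group-level surrogate p and significance flag.
#' @export
cluster_pair_experiment <- function(pattern = c("feedforward", "ee", "ei"),
                                    reps = 10, n_time = 200, tr_out = 0.75,
                                    n_surr = 100, alpha = 0.05,
                                    sim_dt = 0.005, noise_frac = 0.2,
                                    seed = 1, ...) {
  pattern <- match.arg(pattern)
  edges <- switch(pattern,
    feedforward = data.frame(src = 1, dst = 2, sign = 1),
    ee = data.frame(src = c(1, 2), dst = c(2, 1), sign = c(1, 1)),
    ei = data.frame(src = c(1, 2), dst = c(2, 1), sign = c(1, -1)))
  args <- list(n_nodes = 2, inter_edges = edges,
               clone_clusters = pattern != "feedforward", seed = seed, ...)
  if (pattern == "ee" && is.null(args$target_radius)) {
    # mutual excitation adds to the leading mode; leave stability headroom
    args$target_radius <- 0.95
  }
  net <- do.call(build_cluster_network, args)
  dm <- discretize_ou(net, sim_dt)
  set.seed(seed + 1)
  need <- n_time * round(tr_out / sim_dt) + ceiling(36 / sim_dt)
  measures <- c("dgc_12", "dgc_21", "igc", "pc")
  obs <- matrix(NA_real_, reps, 4)
  null_sum <- matrix(0, n_surr, 4)
  rep_sig <- matrix(NA, reps, 4)
  stat_of <- function(b) {
    g <- gc_matrices(regional_scan(b, tr = tr_out), order = 1)
    c(g$dgc[2, 1], g$dgc[1, 2], g$igc[1, 2], abs(g$pc[1, 2]))
  }
  for (r in seq_len(reps)) {
    x <- simulate(dm, nsim = need)
    nd <- node_average(x, net)
    sc <- neural_to_bold(nd, sim_dt = sim_dt, tr_out = tr_out,
                         noise_frac = noise_frac)
    b <- sc$data[seq_len(n_time), , drop = FALSE]
    obs[r, ] <- stat_of(b)
    null <- matrix(NA_real_, n_surr, 4)
    for (s in seq_len(n_surr)) {
      null[s, ] <- stat_of(apply(b, 2, phase_scramble))
    }
    p <- vapply(1:4, function(k) {
      (1 + sum(null[, k] >= obs[r, k])) / (n_surr + 1)
    }, numeric(1))
    rep_sig[r, ] <- p.adjust(p, "BH") < alpha
    null_sum <- null_sum + null
  }
  mo <- colMeans(obs)
  nm <- null_sum / reps
  p_mean <- vapply(1:4, function(k) {
    (1 + sum(nm[, k] >= mo[k])) / (n_surr + 1)
  }, numeric(1))
  out <- data.frame(measure = measures, mean_value = mo,
                    null_mean = colMeans(nm),
                    sig_fraction = colMeans(rep_sig), p_mean = p_mean,
                    significant = p.adjust(p_mean, "BH") < alpha)
  colnames(obs) <- measures
  attr(out, "reps") <- obs
  out
}
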