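#' Continuous-time linear network (vector Ornstein-Uhlenbeck model)
#'
#' Latent dynamics follow `tau dr/dt = -r + W r + eps`, with `eps` white
#' Gaussian noise of covariance `Sigma`.  The drift matrix is
#' `A = (1/tau)(W - I)`; the network is stable iff every eigenvalue of `A`
#' has negative real part, which is asserted at construction.
#'
#' @param W ground-truth weight matrix (N x N).
#' @param tau node time constant in seconds (scalar, or one value per node
#'   for networks mixing fast and slow units).
#' @param Sigma noise covariance (default identity).
#' @param node_of_neuron optional integer vector mapping each unit to a
#'   node, for cluster networks whose units are neurons.
#' @return An object of class `continuous_network` with fields `W`, `tau`,
#'   `Sigma`, `A`, `node_of_neuron`.
#' @export
continuous_network <- function(W, tau, Sigma = NULL,
                               node_of_neuron = NULL) {
  W <- as.matrix(W)
  N <- nrow(W)
  if (is.null(Sigma)) Sigma <- diag(N)
  if (!length(tau) %in% c(1L, N)) stop("tau must be scalar or one per node")
  A <- (W - diag(N)) / tau      # vector tau recycles down rows: row i / tau_i
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    stop("unstable network: max Re(eigenvalue of A) = ",
         format(max(Re(ev)), digits = 4))
  }
  structure(list(W = W, tau = tau, Sigma = Sigma, A = A,
                 node_of_neuron = node_of_neuron),
            class = "continuous_network")
}

#' @export
print.continuous_network <- function(x, ...) {
  N <- nrow(x$W)
  tau_lab <- if (length(unique(x$tau)) == 1) {
    paste0(x$tau[1], " s")
  } else {
    paste0(min(x$tau), "-", max(x$tau), " s")
  }
  cat("Continuous linear network: ", N, " units, tau = ", tau_lab, "\n",
      sep = "")
  ts <- eigen_timescales(x)
  cat("  slowest emergent timescale: ", format(ts[1], digits = 4), " s\n",
      sep = "")
  if (!is.null(x$node_of_neuron)) {
    cat("  ", length(unique(x$node_of_neuron)), " nodes\n", sep = "")
  }
  invisible(x)
}

#' Stationary covariance of a continuous network
#'
#' Solves the continuous-time Lyapunov equation
#' `A G(0) + G(0) A' + Sigma = 0` for the zero-lag autocovariance of the
#' stationary Ornstein-Uhlenbeck process.
#'
#' @param net a [continuous_network()].
#' @return symmetric positive-semidefinite matrix `G(0)`.
#' @export
solve_lyapunov_continuous <- function(net) {
  lyap_continuous(net$A, net$Sigma)
}

#' Exact discretization of a continuous network
#'
#' At sampling interval `delta` the sampled process is an exact VAR(1) with
#' coefficient `exp(delta A)` and innovation covariance
#' `G(0) - exp(delta A) G(0) exp(delta A)'`.  This unscaled innovation
#' covariance keeps the stationary covariance of the discrete model equal
#' to `G(0)` at every `delta`; the rate-scaled form (the same matrix
#' divided by `delta`) is reported in the `sigma_rate` attribute.
#'
#' @param net a [continuous_network()].
#' @param delta sampling interval in seconds.
#' @return A `slowgc_var` of order 1 with `tr = delta`; attribute
#'   `sigma_rate` carries the `1/delta`-scaled innovation covariance.
#' @export
discretize_ou <- function(net, delta) {
  if (delta <= 0) stop("delta must be positive")
  Ad <- pracma::expm(delta * net$A)
  if (any(!is.finite(Ad))) stop("non-finite matrix exponential")
  G0 <- solve_lyapunov_continuous(net)
  Sd <- G0 - Ad %*% G0 %*% t(Ad)
  Sd <- (Sd + t(Sd)) / 2
  m <- var_model(Ad, Sd, tr = delta)
  attr(m, "sigma_rate") <- Sd / delta
  m
}

#' Emergent timescales of a network or sub-network
#'
#' Each eigenvalue `lambda` of the drift matrix contributes an eigenmode
#' decaying with timescale `-1/Re(lambda)`.  Recurrent net excitation pushes
#' eigenvalues toward zero, creating emergent timescales far slower than the
#' single-unit time constant; a purely feedforward weight matrix (nilpotent
#' `W`) leaves every timescale equal to `tau`.
#'
#' @param net a [continuous_network()].
#' @param subset optional unit indices; the sub-drift-matrix
#'   `A[subset, subset]` is analysed.
#' @return numeric vector of timescales in seconds, sorted decreasing.
#' @export
eigen_timescales <- function(net, subset = NULL) {
  A <- net$A
  if (!is.null(subset)) A <- A[subset, subset, drop = FALSE]
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) stop("unstable (sub-)network: Re(eigenvalue) >= 0")
  sort(-1 / Re(ev), decreasing = TRUE)
}

#' Build a clustered excitatory/inhibitory neuron network
#'
#' Each node is a cluster of neurons with sparse random E/I connectivity,
#' net excitatory, scaled so the cluster's slowest emergent timescale is
#' `tau / (1 - target_radius)` (default 50x the single-neuron constant).
#' Only a small designated fraction of each node's neurons takes part in
#' internode connections; requested internode edges connect the source
#' node's port neurons to the destination node's port neurons with the
#' requested sign.
#'
#' @param n_nodes number of clusters.
#' @param neurons_per_node neurons in each cluster.
#' @param conn_prob within-cluster connection probability.
#' @param e_weight,i_weight weights of excitatory / inhibitory synapses.
#' @param e_fraction fraction of excitatory neurons per cluster.
#' @param inter_node_fraction fraction of neurons per node acting as ports
#'   for internode connections.
#' @param inter_edges data frame with columns `src`, `dst`, `sign`
#'   (+1 excitatory, -1 inhibitory), one row per internode edge.
#' @param inter_weight absolute synaptic weight of internode connections.
#' @param tau single-neuron time constant in seconds.
#' @param target_radius within-cluster weight matrices are rescaled so their
#'   leading eigenvalue's real part equals this value (< 1); the cluster's
#'   slowest timescale is then `tau / (1 - target_radius)` (default 0.98,
#'   i.e. a slowest emergent mode 50x slower than a single neuron).
#' @param clone_clusters if TRUE every node reuses the first node's
#'   within-cluster weight block, so internode couplings with mirrored
#'   signs are exactly balanced at the population level.
#' @param seed RNG seed.
#' @param max_retries resampling attempts if the assembled network is
#'   unstable.
#' @return A [continuous_network()] with `node_of_neuron` set and attribute
#'   `retries` recording how many resamples were needed.
#' @export
build_cluster_network <- function(n_nodes, neurons_per_node = 100,
                                  conn_prob = 0.1, e_weight = 0.08,
                                  i_weight = -0.06, e_fraction = 0.8,
                                  inter_node_fraction = 0.05,
                                  inter_edges = NULL, inter_weight = 0.1,
                                  tau = 0.05, target_radius = 0.98,
                                  clone_clusters = FALSE,
                                  seed = 1L, max_retries = 100L) {
  set.seed(seed)
  N <- n_nodes * neurons_per_node
  node_of <- rep(seq_len(n_nodes), each = neurons_per_node)
  n_ports <- max(1L, ceiling(inter_node_fraction * neurons_per_node))
  for (attempt in 0:max_retries) {
    W <- matrix(0, N, N)
    bad <- FALSE
    first_blk <- NULL
    for (nd in seq_len(n_nodes)) {
      idx <- which(node_of == nd)
      if (clone_clusters && !is.null(first_blk)) {
        W[idx, idx] <- first_blk
        next
      }
      n <- length(idx)
      n_e <- round(e_fraction * n)
      wcol <- c(rep(e_weight, n_e), rep(i_weight, n - n_e))
      blk <- matrix(stats::rbinom(n * n, 1, conn_prob), n, n)
      diag(blk) <- 0
      blk <- sweep(blk, 2, wcol, `*`)
      lead <- max(Re(eigen(blk, only.values = TRUE)$values))
      if (lead <= 0) { bad <- TRUE; break }   # not net excitatory; resample
      blk <- blk * (target_radius / lead)
      W[idx, idx] <- blk
      if (is.null(first_blk)) first_blk <- blk
    }
    if (bad) next
    if (!is.null(inter_edges)) {
      for (r in seq_len(nrow(inter_edges))) {
        src <- which(node_of == inter_edges$src[r])[seq_len(n_ports)]
        dst <- which(node_of == inter_edges$dst[r])[seq_len(n_ports)]
        W[dst, src] <- inter_edges$sign[r] * inter_weight
      }
    }
    A <- (W - diag(N)) / tau
    if (max(Re(eigen(A, only.values = TRUE)$values)) < 0) {
      net <- continuous_network(W, tau, node_of_neuron = node_of)
      attr(net, "retries") <- attempt
      return(net)
    }
  }
  stop("could not assemble a stable cluster network in ", max_retries,
       " retries")
}

#' Average neuron-level series to node level
#'
#' @param series numeric matrix, rows = time, columns = neurons.
#' @param net the [continuous_network()] whose `node_of_neuron` defines the
#'   grouping (or an integer mapping vector).
#' @return matrix with one column per node (mean across member neurons).
#' @export
node_average <- function(series, net) {
  node_of <- if (inherits(net, "continuous_network")) net$node_of_neuron
             else as.integer(net)
  if (is.null(node_of)) stop("network has no neuron-to-node mapping")
  if (length(node_of) != ncol(series)) {
    stop("mapping length does not match number of columns")
  }
  nodes <- sort(unique(node_of))
  out <- vapply(nodes, function(nd) {
    rowMeans(series[, node_of == nd, drop = FALSE])
  }, numeric(nrow(series)))
  colnames(out) <- paste0("node", nodes)
  out
}
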