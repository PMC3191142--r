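# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: population moments come from the companion-form
# Lyapunov equation, counts from exhaustive enumeration, ROC sweeps from a
# dense brute-force grid.

# Population covariance of the companion state of a coupling_spec,
# Var(z) = C Var(z) C' + Q, solved by fixed-point iteration (the couplings
# used in tests have spectral radius well below 1).
oracle_companion_cov <- function(coupling, iterations = 300) {
  C <- dmngc:::companion_matrix(coupling)
  R <- length(coupling$node_labels)
  Q <- matrix(0, nrow(C), ncol(C))
  diag(Q)[1:R] <- coupling$noise_sd^2
  S <- Q
  for (i in seq_len(iterations)) S <- C %*% S %*% t(C) + Q
  S
}

# population Cov(x_t, x_{t-k}) blocks from the companion covariance
oracle_lag_cov <- function(coupling, k) {
  S <- oracle_companion_cov(coupling)
  R <- length(coupling$node_labels)
  S[1:R, (k * R + 1):((k + 1) * R), drop = FALSE]
}

# exhaustive hub-index counts from an edge data frame
oracle_hub_counts <- function(edges, hub_labels) {
  d_all <- nrow(edges)
  d_outer <- 0L
  hh <- 0L
  nn <- 0L
  for (e in seq_len(nrow(edges))) {
    hs <- edges$source[e] %in% hub_labels
    ht <- edges$target[e] %in% hub_labels
    if (hs && ht) hh <- hh + 1L
    else if (!hs && !ht) nn <- nn + 1L
    else d_outer <- d_outer + 1L
  }
  list(d_all = d_all, d_outer = d_outer, within_hub = hh,
       within_nonhub = nn)
}

# brute-force best Youden threshold over a dense grid of candidate cuts
oracle_best_youden <- function(neg, pos) {
  cand <- c(-Inf, Inf, sort(unique(c(neg, pos))),
            sort(unique(c(neg, pos))) - 1e-9,
            sort(unique(c(neg, pos))) + 1e-9)
  best <- -Inf
  for (thr in cand) {
    j <- mean(pos < thr) + mean(!(neg < thr)) - 1
    if (j > best) best <- j
  }
  best
}

# random causal graph over n nodes with each directed edge present with
# probability p
random_graph <- function(n_nodes = 8, n_hubs = 3, p = 0.3) {
  nodes <- paste0("N", seq_len(n_nodes))
  hubs <- nodes[seq_len(min(n_hubs, n_nodes))]
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p
  causal_graph(nodes, pairs[keep, , drop = FALSE], hubs)
}

periodogram <- function(x) abs(stats::fft(x))^2 / length(x)

# Hub-index score sets consistent with the reference confusion counts for
# the old-control vs patient cohorts: 16 controls of which 13 score above
# the optimal cutoff, 15 patients of which 13 score below it, with the
# adjacent scores placed so the midpoint cutoff lands at 0.647.
confusion_fixture <- function() {
  list(
    old = c(0.50, 0.53, 0.55,
            0.664, 0.67, 0.68, 0.70, 0.71, 0.72, 0.73, 0.74, 0.75, 0.76,
            0.77, 0.78, 0.80),
    ad = c(0.45, 0.47, 0.49, 0.50, 0.52, 0.54, 0.56, 0.57, 0.58, 0.59,
           0.60, 0.62, 0.63,
           0.70, 0.72))
}

# small white-noise ts_matrix fixture
white_ts <- function(T = 120, R = 3, seed = 1, tr = 2) {
  set.seed(seed)
  ts_matrix(matrix(rnorm(T * R), T, R),
            node_labels = paste0("V", seq_len(R)), tr_seconds = tr)
}
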