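#' Directed VAR coupling specification for a synthetic DMN cohort
#'
#' A `coupling_spec` is the ground-truth generative model behind a synthetic
#' subject: a stable VAR(p) over labelled nodes with a designated hub subset.
#' Cross-node influences are listed as directed edges (source, target, lag,
#' coefficient); each node additionally carries its own autoregressive
#' coefficients and innovation standard deviation.
#'
#' @param node_labels Ordered character vector of node names.
#' @param hub_labels Subset of `node_labels` designated as hubs.
#' @param edges Data frame with columns `source`, `target`, `lag`,
#'   `coefficient`; every endpoint must be a listed node, lags in `1..order`,
#'   no self-loops (own dynamics live in `self_coefficients`).
#' @param self_coefficients Numeric matrix, nodes x order; row i holds node
#'   i's own-lag AR coefficients.
#' @param noise_sd Innovation standard deviation per node (recycled).
#' @param order VAR order p (default 5).
#' @return An object of class `coupling_spec`.
#' @seealso [make_default_coupling()] for the hub-centric defaults,
#'   [simulate_subject()] to draw data from the model.
#' @export
coupling_spec <- function(node_labels, hub_labels, edges, self_coefficients,
                          noise_sd = 1, order = 5) {
  node_labels <- as.character(node_labels)
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  if (!all(hub_labels %in% node_labels))
    stop("hub_labels must be a subset of node_labels")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("source", "target", "lag", "coefficient")
  if (!all(need %in% names(edges)))
    stop("edges needs columns: ", paste(need, collapse = ", "))
  edges <- edges[, need]
  if (nrow(edges) > 0) {
    if (!all(edges$source %in% node_labels) ||
        !all(edges$target %in% node_labels))
      stop("edge endpoints must appear in node_labels")
    if (any(edges$source == edges$target))
      stop("self-loops are expressed through 'self_coefficients'")
    if (any(edges$lag < 1 | edges$lag > order))
      stop("edge lags must lie in 1..order")
  }
  R <- length(node_labels)
  self_coefficients <- matrix(as.numeric(self_coefficients), nrow = R,
                              ncol = order,
                              dimnames = list(node_labels, NULL))
  noise_sd <- rep_len(as.numeric(noise_sd), R)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  spec <- structure(list(node_labels = node_labels,
                         hub_labels = as.character(hub_labels),
                         edges = edges,
                         self_coefficients = self_coefficients,
                         noise_sd = noise_sd, order = as.integer(order)),
                    class = "coupling_spec")
  rho <- companion_spectral_radius(spec)
  if (rho >= 1)
    stop(sprintf(
      "coupling is non-stationary: companion spectral radius %.4f >= 1", rho))
  spec
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("coupling_spec: VAR(%d), %d nodes (%d hubs), %d cross edges\n",
              x$order, length(x$node_labels), length(x$hub_labels),
              nrow(x$edges)))
  cat(sprintf("companion spectral radius: %.4f\n",
              companion_spectral_radius(x)))
  invisible(x)
}

# Stack the per-lag coefficient matrices A_l (target row, source column).
coupling_matrices <- function(spec) {
  R <- length(spec$node_labels)
  A <- array(0, dim = c(R, R, spec$order),
             dimnames = list(spec$node_labels, spec$node_labels, NULL))
  for (l in seq_len(spec$order))
    diag(A[, , l]) <- spec$self_coefficients[, l]
  if (nrow(spec$edges) > 0) {
    for (e in seq_len(nrow(spec$edges))) {
      A[spec$edges$target[e], spec$edges$source[e], spec$edges$lag[e]] <-
        A[spec$edges$target[e], spec$edges$source[e], spec$edges$lag[e]] +
        spec$edges$coefficient[e]
    }
  }
  A
}

#' Spectral radius of the companion-form transition matrix
#'
#' The VAR(p) is stationary iff this is strictly below 1; the generator
#' refuses non-stationary specifications.
#'
#' @param spec A [coupling_spec()].
#' @return The largest eigenvalue modulus of the (R p) x (R p) companion
#'   matrix.
#' @export
companion_spectral_radius <- function(spec) {
  C <- companion_matrix(spec)
  max(Mod(eigen(C, only.values = TRUE)$values))
}

companion_matrix <- function(spec) {
  A <- coupling_matrices(spec)
  R <- dim(A)[1]
  p <- dim(A)[3]
  C <- matrix(0, R * p, R * p)
  for (l in seq_len(p)) C[1:R, ((l - 1) * R + 1):(l * R)] <- A[, , l]
  if (p > 1) {
    lower <- cbind(diag(R * (p - 1)), matrix(0, R * (p - 1), R))
    C[(R + 1):(R * p), ] <- lower
  }
  C
}

#' Hub-centric default coupling for the control and attenuated cohorts
#'
#' Builds the ground-truth causal structure the synthetic cohorts emulate.
#' In the control specification every hub is coupled to every non-hub and
#' to every other hub, non-hub pairs carry no direct coupling, and PCC is a
#' pure sink: it receives a directed influence from each of the other seven
#' nodes and sends none.  Concretely, MPFC (a pure source) drives lIPC and
#' all four non-hubs at lag 1 and rIPC at lag 2, lIPC drives rIPC at lag 1,
#' each non-hub sends to lIPC at lag 1 and to rIPC at lag 2, and every node
#' feeds PCC at lag 5 — so the fitted VAR(5) has genuinely multi-lag
#' structure.
#'
#' The topology is deliberately chosen so that pairwise *bivariate* Granger
#' analysis is faithful to it: the cross-edge graph is a DAG (stationary at
#' any coupling strength — the companion spectral radius equals the own-lag
#' AR radius), every two-step causal path is shadowed by a direct true
#' edge, co-driven nodes share their driver at equal lags, and PCC receives
#' at the longest lag so its past is always staler than any target's own
#' history.  Without these properties, indirect influences would surface as
#' systematic "false" edges — a genuine limitation of bivariate causality,
#' not of the detector.
#'
#' The `attenuated` variant emulates a degenerated network: every coupling
#' incident to MPFC, lIPC or rIPC is multiplied by `attenuation_factor`,
#' except edges that touch PCC, which are left intact (the posterior
#' cingulate keeps its afferent influences in the degraded network).
#'
#' @param group `"control"` or `"attenuated"`.
#' @param attenuation_factor Multiplier in \[0, 1\] applied to the attenuated
#'   couplings (ignored for `"control"`).
#' @param coupling_strength Cross-edge coefficient of the control network
#'   (default 0.4).
#' @param self_coefficient Own lag-1 AR coefficient of every node
#'   (default 0.3).
#' @param noise_sd Innovation standard deviation (default 1).
#' @return A [coupling_spec()] over [dmn_node_labels()] with hubs
#'   [dmn_hub_labels()].
#' @examples
#' ctrl <- make_default_coupling("control")
#' sum(ctrl$edges$target == "PCC")  # PCC receives from all 7 other nodes
#' @export
make_default_coupling <- function(group = c("control", "attenuated"),
                                  attenuation_factor = 0.4,
                                  coupling_strength = 0.4,
                                  self_coefficient = 0.3,
                                  noise_sd = 1) {
  group <- match.arg(group)
  if (!is.numeric(attenuation_factor) || length(attenuation_factor) != 1L ||
      attenuation_factor < 0 || attenuation_factor > 1)
    stop("'attenuation_factor' must be a single number in [0, 1]")
  nodes <- .dmn_nodes
  hubs <- .dmn_hubs
  nonhubs <- setdiff(nodes, hubs)                 # lITC, rITC, lHC, rHC
  senders <- setdiff(hubs, "PCC")                 # MPFC, lIPC, rIPC

  edges <- rbind(
    # MPFC is the network's source: it drives the other sending hubs and
    # every non-hub
    data.frame(source = "MPFC", target = c("lIPC", nonhubs),
               lag = 1L, coefficient = coupling_strength),
    data.frame(source = c("MPFC", "lIPC"), target = "rIPC",
               lag = 2:1, coefficient = coupling_strength),
    # every non-hub sends to both IPC nodes (hub/non-hub pairs coupled,
    # direction into the hub); rIPC listens one lag later than lIPC so the
    # two aggregators never carry the same source information at the same
    # age (that alignment would register as a spurious rIPC -> lIPC link)
    expand.grid(source = nonhubs, target = c("lIPC", "rIPC"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
      transform(lag = rep(1:2, each = length(nonhubs)),
                coefficient = coupling_strength),
    # every other node drives PCC (PCC is a pure receiver), long lag
    data.frame(source = setdiff(nodes, "PCC"), target = "PCC",
               lag = 5L, coefficient = coupling_strength)
  )
  rownames(edges) <- NULL

  if (group == "attenuated") {
    touched <- (edges$source %in% senders | edges$target %in% senders) &
      edges$source != "PCC" & edges$target != "PCC"
    edges$coefficient[touched] <- edges$coefficient[touched] *
      attenuation_factor
    edges <- edges[edges$coefficient != 0, , drop = FALSE]
  }

  self <- matrix(0, length(nodes), 5)
  self[, 1] <- self_coefficient
  coupling_spec(nodes, hubs, edges, self, noise_sd = noise_sd, order = 5)
}

#' Simulate one subject from a coupling specification
#'
#' Iterates the VAR recursion with Gaussian innovations, discarding an
#' initial burn-in so the recorded segment is drawn from the stationary
#' distribution.  Identical `(coupling, n_timepoints, seed)` give
#' bit-identical output.
#'
#' @param coupling A stationary [coupling_spec()].
#' @param n_timepoints Number of recorded time points T (must exceed
#'   10 x order).
#' @param seed Integer seed for the innovation stream.
#' @param burn_in Transient steps discarded before recording (default 200).
#' @param tr_seconds Sampling interval attached to the output (default 2).
#' @param hrf Convolve each node's series with a canonical double-gamma
#'   haemodynamic response sampled at `tr_seconds` (default FALSE: the
#'   causal ground truth is defined at the VAR level, and convolution
#'   blurs it).
#' @return A [ts_matrix()] of dimension T x R.
#' @export
simulate_subject <- function(coupling, n_timepoints, seed,
                             burn_in = 200, tr_seconds = 2, hrf = FALSE) {
  stopifnot(inherits(coupling, "coupling_spec"))
  p <- coupling$order
  if (n_timepoints <= 10 * p)
    stop("n_timepoints must exceed 10 x order")
  rho <- companion_spectral_radius(coupling)
  if (rho >= 1)
    stop(sprintf(
      "coupling is non-stationary: companion spectral radius %.4f >= 1", rho))
  if (burn_in < p) stop("burn_in must be at least the VAR order")
  A <- coupling_matrices(coupling)
  R <- length(coupling$node_labels)
  total <- burn_in + n_timepoints
  X <- matrix(0, total, R)
  innov <- with_seed(seed,
    matrix(rnorm(total * R), total, R) *
      rep(coupling$noise_sd, each = total))
  for (t in (p + 1):total) {
    acc <- innov[t, ]
    for (l in seq_len(p)) acc <- acc + A[, , l] %*% X[t - l, ]
    X[t, ] <- acc
  }
  out <- X[(burn_in + 1):total, , drop = FALSE]
  if (hrf) {
    h <- .double_gamma_hrf(tr_seconds)
    out <- apply(out, 2, function(col)
      stats::convolve(col, rev(h), type = "open")[seq_along(col)])
  }
  ts_matrix(out, node_labels = coupling$node_labels,
            tr_seconds = tr_seconds)
}

# canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6),
# sampled at the TR over a 32 s support and normalised to unit sum
.double_gamma_hrf <- function(tr_seconds, duration = 32) {
  t <- seq(0, duration, by = tr_seconds)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / sum(h)
}

#' Cohort specification
#'
#' Bundles a coupling model with cohort size, series length, sampling
#' interval, between-subject coefficient jitter and a master seed.  The
#' default length, 295 time points, corresponds to a 300-volume acquisition
#' with the first 5 volumes discarded (245 for a 250-volume protocol).
#'
#' @param coupling A [coupling_spec()].
#' @param n_subjects Number of subjects (>= 1).
#' @param n_timepoints Recorded time points per subject (default 295).
#' @param tr_seconds Sampling interval in seconds (default 2).
#' @param between_subject_jitter Relative standard deviation of the
#'   multiplicative Gaussian jitter applied to every cross-edge coefficient
#'   per subject; the multiplier is truncated below at 0 so couplings never
#'   flip sign (default 0.1).
#' @param seed Master integer seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(coupling, n_subjects, n_timepoints = 295,
                        tr_seconds = 2, between_subject_jitter = 0.1,
                        seed = 1) {
  stopifnot(inherits(coupling, "coupling_spec"))
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (n_timepoints <= 10 * coupling$order)
    stop("n_timepoints must exceed 10 x order")
  if (between_subject_jitter < 0) stop("jitter must be >= 0")
  structure(list(coupling = coupling, n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = as.numeric(tr_seconds),
                 between_subject_jitter = as.numeric(between_subject_jitter),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Jitter the cross-edge coefficients of a coupling spec (multiplicative
# Gaussian, truncated at zero to preserve sign).
jitter_coupling <- function(coupling, jitter) {
  if (jitter == 0 || nrow(coupling$edges) == 0) return(coupling)
  mult <- pmax(0, rnorm(nrow(coupling$edges), mean = 1, sd = jitter))
  out <- coupling
  out$edges$coefficient <- out$edges$coefficient * mult
  out
}

#' Simulate a whole cohort with known causal ground truth
#'
#' Draws `n_subjects` independent subjects from the cohort specification.
#' Each subject gets its own jittered copy of the coupling coefficients and
#' its own seed derived from the master seed, and is paired with the binary
#' directed graph of its nonzero couplings — the ground truth that downstream
#' edge detection is scored against.  Jitter draws that would break
#' stationarity are resampled up to `max_retries` times.
#'
#' @param spec A [cohort_spec()].
#' @param max_retries Resampling cap per subject for non-stationary jitter
#'   draws (default 20).
#' @return A list of class `cohort` with elements `subjects` (list of
#'   [ts_matrix()]), `graphs` (list of [causal_graph()] ground truths),
#'   `couplings` (per-subject jittered [coupling_spec()]s) and `spec`.
#' @export
simulate_cohort <- function(spec, max_retries = 20) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- vector("list", spec$n_subjects)
  graphs <- vector("list", spec$n_subjects)
  couplings <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    cp <- NULL
    for (try in 0:max_retries) {
      cp <- with_seed(derive_seed(spec$seed, i, try),
                      try(jitter_coupling(spec$coupling,
                                          spec$between_subject_jitter),
                          silent = TRUE))
      if (!inherits(cp, "try-error") &&
          companion_spectral_radius(cp) < 1) break
      cp <- NULL
    }
    if (is.null(cp))
      stop("subject ", i, ": jitter produced a non-stationary coupling ",
           max_retries + 1, " times")
    couplings[[i]] <- cp
    subjects[[i]] <- simulate_subject(cp, spec$n_timepoints,
                                      seed = derive_seed(spec$seed, i),
                                      tr_seconds = spec$tr_seconds)
    gt <- unique(cp$edges[cp$edges$coefficient != 0, c("source", "target")])
    graphs[[i]] <- causal_graph(cp$node_labels, gt, cp$hub_labels)
  }
  structure(list(subjects = subjects, graphs = graphs,
                 couplings = couplings, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects x %d time points x %d nodes (TR = %g s)\n",
              length(x$subjects), x$spec$n_timepoints,
              length(x$spec$coupling$node_labels), x$spec$tr_seconds))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One TSV per subject (header = node labels, one row per time point) plus a
#' JSON sidecar holding the cohort parameters and each subject's ground-truth
#' edge list.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort$subjects)
  files <- sprintf("subject%02d.tsv", seq_len(n))
  for (i in seq_len(n))
    write_timeseries(cohort$subjects[[i]], file.path(dir, files[i]))
  sidecar <- list(
    n_subjects = n,
    n_timepoints = cohort$spec$n_timepoints,
    tr_seconds = cohort$spec$tr_seconds,
    between_subject_jitter = cohort$spec$between_subject_jitter,
    seed = cohort$spec$seed,
    node_labels = cohort$spec$coupling$node_labels,
    hub_labels = cohort$spec$coupling$hub_labels,
    files = files,
    ground_truth_edges = lapply(cohort$graphs, function(g)
      as.data.frame(g$edges)))
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
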