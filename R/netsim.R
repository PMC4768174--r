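#' Sample a directed scale-free adjacency matrix
#'
#' Draws a directed graph with a fixed edge budget and power-law in/out degree
#' tails (no self-loops, no multi-edges) using a static fitness model with
#' power-law fitness sequences, the standard way to hit a target degree
#' exponent at a fixed edge count.
#'
#' @param n node count (>= 3).
#' @param degree_exponent target tail exponent of the degree distribution
#'   (> 1); gene-regulatory benchmarks typically use 2.2.
#' @param edge_budget exact number of directed edges (<= n*(n-1)).
#' @param seed integer seed.
#' @return binary n x n adjacency with `A[i, j] = 1` when node `j` directly
#'   influences node `i`.
#' @export
sample_scale_free <- function(n, degree_exponent, edge_budget, seed) {
  stopifnot(n >= 3, degree_exponent > 1, edge_budget >= 1)
  if (edge_budget > n * (n - 1))
    stop("edge_budget exceeds n*(n-1) possible directed edges", call. = FALSE)
  g <- with_seed(seed,
    igraph::sample_fitness_pl(no.of.nodes = n, no.of.edges = edge_budget,
                              exponent.out = degree_exponent,
                              exponent.in = degree_exponent,
                              loops = FALSE, multiple = FALSE))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  # igraph convention: A[u, v] = 1 for edge u -> v (u influences v);
  # package convention: S[i, j] = influence of j on i, so transpose.
  t(A)
}

#' Assign weights to an adjacency pattern
#'
#' Weights are drawn uniformly in magnitude on `magnitude_range` with random
#' sign (or all positive), placed exactly on the adjacency support. With
#' `symmetric = TRUE` the support is symmetrized and the upper-triangle
#' weights are mirrored, giving an undirected coupling matrix. Stabilization
#' keeps the total-influence closure convergent (spectral radius strictly
#' below 1): a symmetric matrix is rescaled so its spectral radius equals
#' `beta` exactly (the usual deconvolution scaling convention), a directed
#' one is rescaled only when its spectral radius exceeds `beta` (near-acyclic
#' directed draws have spectral radius close to zero, where an exact rescale
#' would blow the weights up).
#'
#' @param adjacency binary square matrix.
#' @param magnitude_range `c(lo, hi)` with `0 < lo <= hi`.
#' @param sign_mode `"mixed"` (random sign) or `"positive"`.
#' @param stabilize apply the spectral rescaling described above.
#' @param seed integer seed.
#' @param symmetric mirror support and weights across the diagonal.
#' @param beta target spectral radius for stabilization.
#' @return weighted direct-influence matrix on the (possibly symmetrized)
#'   support.
#' @export
assign_weights <- function(adjacency, magnitude_range = c(0.1, 1),
                           sign_mode = c("mixed", "positive"),
                           stabilize = TRUE, seed = 1, symmetric = FALSE,
                           beta = 0.9) {
  sign_mode <- match.arg(sign_mode)
  check_square(adjacency, "adjacency")
  lo <- magnitude_range[1]; hi <- magnitude_range[2]
  stopifnot(lo > 0, hi >= lo, beta > 0, beta < 1)
  if (symmetric) adjacency <- (adjacency + t(adjacency) != 0) * 1
  idx <- which(adjacency != 0)
  S <- matrix(0, nrow(adjacency), ncol(adjacency))
  if (length(idx)) {
    S[idx] <- with_seed(seed, {
      mag <- runif(length(idx), lo, hi)
      if (sign_mode == "mixed") mag <- mag * sample(c(-1, 1), length(idx), TRUE)
      mag
    })
    if (symmetric) S[lower.tri(S)] <- t(S)[lower.tri(S)]
    if (stabilize) {
      sr <- spectral_radius(S)
      if (symmetric && sr > 0) S <- S * (beta / sr)
      else if (sr > beta) S <- S * (beta / sr)
    }
  }
  S
}

#' Total-influence closure of a direct-influence matrix
#'
#' Accumulates direct influences over all directed paths:
#' `G = S + S %*% G`, i.e. `G = solve(I - S) %*% S`, convergent exactly when
#' the spectral radius of `S` is below 1.
#'
#' @param S direct-influence matrix with spectral radius < 1.
#' @return the total-influence matrix `G`.
#' @export
total_influence_closure <- function(S) {
  check_square(S, "S")
  if (spectral_radius(S) >= 1)
    stop("spectral radius of S must be < 1 for the closure to converge",
         call. = FALSE)
  solve(diag(nrow(S)) - S, S)
}

#' Contaminate a total-influence matrix with measurement noise
#'
#' Two noise models: proportional, `dG[i,j] = sigma * |G0[i,j]| * z[i,j]`, and
#' independent, `dG[i,j] = sigma * z[i,j]`, with `z` i.i.d. standard normal.
#' The realized noise matrix is returned alongside the contaminated matrix so
#' bound estimators can use it.
#'
#' @param G0 clean total-influence matrix.
#' @param sigma nonnegative noise magnitude.
#' @param mode `"proportional"` or `"independent"`.
#' @param seed integer seed.
#' @return list with `G` (noisy matrix) and `dG` (realized noise).
#' @export
add_noise <- function(G0, sigma, mode = c("proportional", "independent"),
                      seed = 1) {
  mode <- match.arg(mode)
  check_square(G0, "G0")
  stopifnot(sigma >= 0)
  n <- nrow(G0)
  z <- with_seed(seed, matrix(rnorm(n * n), n, n))
  dG <- if (mode == "proportional") sigma * abs(G0) * z else sigma * z
  list(G = G0 + dG, dG = dG)
}

#' Michaelis-Menten network dynamics
#'
#' Constructs the benchmark regulatory dynamics
#' \deqn{dx_i/dt = -p_i x_i + \sum_j A_{ij} \, x_j^h / (1 + x_j^h),}
#' a Hill-type (Michaelis-Menten for `h = 1`) activation model with linear
#' self-degradation — exactly the case where the degradation parameter enters
#' its own equation linearly, which the robust perturbation procedure
#' exploits.
#'
#' @param S0 interaction weight matrix `A` (support = network structure).
#' @param degradation per-node positive degradation rates `p` (recycled).
#' @param hill_exponent Hill coefficient `h` (default 1).
#' @param x0 initial state (nonnegative, recycled).
#' @return list of class `mm_system`.
#' @export
mm_system <- function(S0, degradation = 1, hill_exponent = 1, x0 = 1) {
  check_square(S0, "S0")
  n <- nrow(S0)
  p <- rep_len(degradation, n)
  x0 <- rep_len(x0, n)
  stopifnot(all(p > 0), all(x0 >= 0), hill_exponent > 0)
  structure(list(S0 = S0, p = p, h = hill_exponent, x0 = x0, n = n),
            class = "mm_system")
}

mm_rhs <- function(t, x, parms) {
  sat <- x^parms$h / (1 + x^parms$h)
  list(-parms$p * x + drop(parms$S0 %*% sat))
}

#' Simulate one (optionally noisy) trajectory of a Michaelis-Menten system
#'
#' Integrates the system with an adaptive stiff-capable solver
#' (`deSolve::lsoda`, rtol 1e-8, atol 1e-10) and adds i.i.d. Gaussian
#' observation noise of magnitude `sigma_obs` to every sample.
#'
#' @param system an [mm_system()].
#' @param times strictly increasing time grid.
#' @param sigma_obs observation-noise standard deviation.
#' @param seed integer seed for the observation noise.
#' @param p_override optional replacement parameter vector (used internally by
#'   [perturb_and_simulate()]).
#' @param rtol,atol integrator tolerances.
#' @return list with `times`, `noiseless` and `observed` (time x node
#'   matrices).
#' @export
simulate_mm <- function(system, times, sigma_obs = 0, seed = 1,
                        p_override = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "mm_system"), all(diff(times) > 0))
  parms <- list(S0 = system$S0, h = system$h,
                p = if (is.null(p_override)) system$p else p_override)
  out <- deSolve::ode(y = system$x0, times = times, func = mm_rhs,
                      parms = parms, method = "lsoda",
                      rtol = rtol, atol = atol)
  X <- unname(out[, -1, drop = FALSE])
  if (nrow(X) < length(times) || !all(is.finite(X)))
    stop("Michaelis-Menten integration failed (non-finite state)",
         call. = FALSE)
  obs <- if (sigma_obs > 0) {
    X + with_seed(seed, matrix(rnorm(length(X), sd = sigma_obs),
                               nrow(X), ncol(X)))
  } else X
  list(times = times, noiseless = X, observed = obs)
}

#' Parameter-perturbation trajectory ensemble
#'
#' Generates the MRA measurement design: one baseline trajectory plus one
#' trajectory per node `k` in which only the degradation rate `p_k` is changed
#' by `delta_frac * p_k`, all started from the same initial condition and
#' observed with independent noise. The degradation rate enters exactly one
#' node's equation, so each perturbation directly drives a single node — the
#' condition the response-matrix construction relies on. An additional inert
#' member (no parameter changed, fresh observation noise) is simulated to
#' emulate the non-robust historical design, in which the experiment for the
#' row being inferred may not touch any parameter of that row's equation and
#' therefore contributes only the noise floor.
#'
#' @param system an [mm_system()].
#' @param delta_frac relative perturbation size (default 0.1 = 10%).
#' @param times time grid.
#' @param sigma_obs observation-noise standard deviation.
#' @param seed integer seed; observation noise of every member derives from it.
#' @return list of class `trajectory_ensemble`: `times`, `baseline`,
#'   `baseline_noiseless`, `perturbed` (list of n observed matrices),
#'   `perturbed_noiseless`, `inert`, `design` (data frame of perturbed
#'   parameter index and absolute delta), `delta_frac`, `sigma_obs`, `system`.
#' @export
perturb_and_simulate <- function(system, delta_frac = 0.1, times,
                                 sigma_obs = 0, seed = 1) {
  stopifnot(inherits(system, "mm_system"), delta_frac >= 0)
  n <- system$n
  base <- simulate_mm(system, times, sigma_obs, seed = derive_seed(seed, 0))
  perturbed <- vector("list", n)
  perturbed_true <- vector("list", n)
  deltas <- delta_frac * system$p
  for (k in seq_len(n)) {
    p_k <- system$p
    p_k[k] <- p_k[k] + deltas[k]
    run <- simulate_mm(system, times, sigma_obs, seed = derive_seed(seed, k),
                       p_override = p_k)
    perturbed[[k]] <- run$observed
    perturbed_true[[k]] <- run$noiseless
  }
  inert <- simulate_mm(system, times, sigma_obs,
                       seed = derive_seed(seed, n + 1))
  structure(list(times = times,
                 baseline = base$observed,
                 baseline_noiseless = base$noiseless,
                 perturbed = perturbed,
                 perturbed_noiseless = perturbed_true,
                 inert = inert$observed,
                 design = data.frame(param = seq_len(n), delta = deltas),
                 delta_frac = delta_frac, sigma_obs = sigma_obs,
                 system = system),
            class = "trajectory_ensemble")
}
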