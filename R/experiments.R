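#' Configuration objects for the benchmark experiments
#'
#' `case1_config()` parameterizes the total-influence benchmark: an ensemble
#' of random scale-free direct-influence networks, their closures, and noisy
#' measurements thereof. `mm_config()` parameterizes the Michaelis-Menten
#' transient-trajectory benchmark. Defaults are the package's desk-scale
#' study conditions (see the methods vignette for how each was fixed);
#' every run is fully determined by `seed`.
#'
#' @param n_nodes nodes per network.
#' @param n_networks number of network realizations.
#' @param degree_exponent scale-free degree exponent.
#' @param edge_budget directed edges per network.
#' @param noise_mode `"proportional"` or `"independent"`.
#' @param sigma measurement-noise magnitude on the total-influence matrix.
#' @param weight_range magnitude range of the nonzero direct influences.
#' @param sign_mode `"mixed"` or `"positive"` weights.
#' @param coupling `"symmetric"` (undirected coupling, spectral radius
#'   rescaled to exactly `beta`) or `"directed"`.
#' @param beta target spectral radius of the direct-influence matrix.
#' @param seed root seed.
#' @return a named list of class `case1_config` / `mm_config`.
#' @export
case1_config <- function(n_nodes = 50, n_networks = 50, degree_exponent = 2.2,
                         edge_budget = 70,
                         noise_mode = "proportional", sigma = 0.1,
                         weight_range = c(0.1, 1), sign_mode = "mixed",
                         coupling = c("symmetric", "directed"), beta = 0.9,
                         seed = 1) {
  coupling <- match.arg(coupling)
  structure(as.list(environment()), class = "case1_config")
}

#' @rdname case1_config
#' @param n_trials number of network/trajectory realizations.
#' @param times integration grid.
#' @param sigma_obs observation-noise standard deviation on trajectories.
#' @param delta_frac relative parameter-perturbation size.
#' @param n_times number of randomly chosen interior time points averaged
#'   over.
#' @param tau absence-detection threshold (a tenth of the smallest true
#'   interaction weight by default).
#' @export
mm_config <- function(n_nodes = 50, n_trials = 10, degree_exponent = 2.2,
                      edge_budget = 70, weight_range = c(0.1, 1),
                      times = seq(0, 3.5, by = 0.1), sigma_obs = 1e-4,
                      delta_frac = 0.1, n_times = 30, tau = 0.01, seed = 1) {
  structure(as.list(environment()), class = "mm_config")
}

# one Case-I instance: network, closure, noisy measurement
case1_instance <- function(config, k) {
  sd_net <- derive_seed(config$seed, 2 * k)
  sd_noise <- derive_seed(config$seed, 2 * k + 1)
  A <- sample_scale_free(config$n_nodes, config$degree_exponent,
                         config$edge_budget, seed = sd_net)
  S0 <- assign_weights(A, config$weight_range, config$sign_mode,
                       stabilize = TRUE, seed = sd_net,
                       symmetric = config$coupling == "symmetric",
                       beta = config$beta)
  G0 <- total_influence_closure(S0)
  nz <- add_noise(G0, config$sigma, config$noise_mode, seed = sd_noise)
  list(S0 = S0, G0 = G0, G = nz$G, dG = nz$dG)
}

#' Benchmark: deconvolution versus l1 recovery from noisy total influence
#'
#' For each network realization: build the noisy measurement, recover the
#' direct-influence matrix by closed-form deconvolution and by row-wise
#' l1-minimization under the true and the approximated residual bounds, and
#' score inference error and Hoyer sparsity. Also tabulates the mean of the
#' three bound estimators (true / approx / upper).
#'
#' @param config a [case1_config()].
#' @return list with `per_network` (long data frame: network, method, rho,
#'   hoyer) , `bounds` (data frame of per-network mean eps by kind) and
#'   `summary` (named list of ensemble means, variances and the comparative
#'   percentage deltas).
#' @export
run_case1 <- function(config) {
  rows <- list(); brows <- list()
  for (k in seq_len(config$n_networks)) {
    inst <- case1_instance(config, k)
    form <- build_linear_system(inst$G)
    S_nd <- nd_closed_form(inst$G)
    b_true <- true_bound(inst$S0, form)
    b_appr <- approx_bound(inst$G, inst$dG)
    b_upp <- upper_bound(inst$G, inst$dG)
    S_l1t <- solve_matrix(form, b_true)$S_hat
    S_l1a <- solve_matrix(form, b_appr)$S_hat
    rows[[k]] <- data.frame(
      network = k,
      method = c("nd", "l1_true", "l1_approx"),
      rho = c(inference_error(S_nd, inst$S0),
              inference_error(S_l1t, inst$S0),
              inference_error(S_l1a, inst$S0)),
      hoyer = c(hoyer(S_nd), hoyer(S_l1t), hoyer(S_l1a)))
    brows[[k]] <- data.frame(network = k, eps_true = mean(b_true$eps),
                             eps_approx = mean(b_appr$eps),
                             eps_upper = mean(b_upp$eps))
  }
  per_network <- do.call(rbind, rows)
  bounds <- do.call(rbind, brows)
  m <- function(meth, col) per_network[per_network$method == meth, col]
  summary <- list(
    mean_rho_nd = mean(m("nd", "rho")),
    mean_rho_l1_true = mean(m("l1_true", "rho")),
    mean_rho_l1_approx = mean(m("l1_approx", "rho")),
    var_rho_nd = var(m("nd", "rho")),
    var_rho_l1_true = var(m("l1_true", "rho")),
    var_rho_l1_approx = var(m("l1_approx", "rho")),
    mean_hoyer_nd = mean(m("nd", "hoyer")),
    mean_hoyer_l1_true = mean(m("l1_true", "hoyer")),
    mean_hoyer_l1_approx = mean(m("l1_approx", "hoyer")),
    mean_eps_true = mean(bounds$eps_true),
    mean_eps_approx = mean(bounds$eps_approx),
    mean_eps_upper = mean(bounds$eps_upper))
  summary$pct_rho_reduction_true <-
    100 * (1 - summary$mean_rho_l1_true / summary$mean_rho_nd)
  summary$pct_rho_reduction_approx <-
    100 * (1 - summary$mean_rho_l1_approx / summary$mean_rho_nd)
  summary$pct_hoyer_increase_true <-
    100 * (summary$mean_hoyer_l1_true / summary$mean_hoyer_nd - 1)
  summary$pct_hoyer_increase_approx <-
    100 * (summary$mean_hoyer_l1_approx / summary$mean_hoyer_nd - 1)
  list(per_network = per_network, bounds = bounds, summary = summary)
}

#' Inference error as a function of the residual bound
#'
#' On a single noisy Case-I instance, sweeps the per-row bound as a multiple
#' of the true bound and records the inference error: the curve bottoms out
#' near the true bound, rises roughly linearly beyond it, and blows up as the
#' bound shrinks toward zero (overfitting the noise).
#'
#' The curve is averaged over `n_instances` network/noise realizations: a
#' single realization's curve is dominated by whether that draw happens to
#' sit in the deconvolution baseline's heavy error tail, while the ensemble
#' mean exposes the generic overfit/underfit shape.
#'
#' @param config a [case1_config()].
#' @param factors multiplicative grid applied to the true per-row bounds.
#' @param n_instances realizations averaged over.
#' @return data frame with `factor`, `eps_mean` (mean true-bound scale times
#'   factor), `rho` (ensemble mean inference error).
#' @export
run_eps_sweep <- function(config,
                          factors = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5,
                                      1, 1.5, 2, 3, 4, 6, 8, 10),
                          n_instances = 10) {
  acc <- matrix(0, length(factors), n_instances)
  eps_scale <- 0
  for (k in seq_len(n_instances)) {
    inst <- case1_instance(config, k)
    form <- build_linear_system(inst$G)
    eps0 <- true_bound(inst$S0, form)$eps
    eps_scale <- eps_scale + mean(eps0) / n_instances
    acc[, k] <- vapply(factors, function(f)
      inference_error(solve_matrix(form, f * eps0)$S_hat, inst$S0),
      numeric(1))
  }
  data.frame(factor = factors, eps_mean = factors * eps_scale,
             rho = rowMeans(acc))
}

#' Averaging over noise realizations
#'
#' Fixes one Case-I network, draws `N` independent noisy measurements of its
#' total-influence matrix, estimates the network from each (deconvolution and
#' l1 with the true bound), and compares the mean single-realization error to
#' the error of the averaged estimate. Repeated over `n_reps` seeds.
#'
#' @param config a [case1_config()].
#' @param N realizations averaged per repetition.
#' @param n_reps independent repetitions.
#' @return list with `per_rep` (data frame: rep, method, rho_single_mean,
#'   rho_avg, ratio) and `summary` (mean ratios).
#' @export
run_averaging <- function(config, N = 40, n_reps = 10) {
  inst0 <- case1_instance(config, 0)
  S0 <- inst0$S0
  G0 <- inst0$G0
  rows <- list()
  for (r in seq_len(n_reps)) {
    est_nd <- vector("list", N); est_l1 <- vector("list", N)
    rho_nd <- rho_l1 <- numeric(N)
    for (k in seq_len(N)) {
      nz <- add_noise(G0, config$sigma, config$noise_mode,
                      seed = derive_seed(config$seed, 1000 * r + k))
      form <- build_linear_system(nz$G)
      est_nd[[k]] <- nd_closed_form(nz$G)
      est_l1[[k]] <- solve_matrix(form, true_bound(S0, form))$S_hat
      rho_nd[k] <- inference_error(est_nd[[k]], S0)
      rho_l1[k] <- inference_error(est_l1[[k]], S0)
    }
    rows[[r]] <- data.frame(
      rep = r, method = c("nd", "l1_true"),
      rho_single_mean = c(mean(rho_nd), mean(rho_l1)),
      rho_avg = c(inference_error(average_estimates(est_nd), S0),
                  inference_error(average_estimates(est_l1), S0)))
  }
  per_rep <- do.call(rbind, rows)
  per_rep$ratio <- per_rep$rho_single_mean / per_rep$rho_avg
  summary <- list(
    ratio_nd = mean(per_rep$ratio[per_rep$method == "nd"]),
    ratio_l1 = mean(per_rep$ratio[per_rep$method == "l1_true"]))
  summary$ratio_mean <- mean(c(summary$ratio_nd, summary$ratio_l1))
  list(per_rep = per_rep, summary = summary)
}

# floor an absence-error mean by the resolution of the underlying counts
pseudocount_floor <- function(e, n_cells) pmax(e, 1 / (2 * n_cells))

#' Michaelis-Menten transient-inference benchmark
#'
#' Runs the four arms of the trajectory study on `n_trials` random networks.
#' All arms consume the same robustly-perturbed trajectory ensemble; they
#' differ in the solver: plain least-squares inversion (`sontag`) versus
#' l1-minimization with the observation-noise level known (`l1_known`),
#' underestimated ten-fold (`l1_under`) or overestimated ten-fold
#' (`l1_over`). Each trial integrates the perturbation ensemble once,
#' estimates the network at `n_times` random interior time points inside the
#' transient window, and scores the absence-detection error of
#' single-time-point estimates (`e_single`, mean over time points) against
#' the time-averaged estimate (`e_avg`). The ill-conditioning of the
#' historical non-robust design itself is exposed separately through
#' [build_response_system()]'s `robust = FALSE` mode.
#'
#' @param config an [mm_config()].
#' @param arms subset of the four arm names to run.
#' @return list with `per_trial` (data frame: trial, arm, e_single, e_avg)
#'   and `summary` (per-arm means, floored by the count resolution
#'   `1 / (2 * total absent-arc decisions)`, plus the Sontag / l1 error
#'   ratio when both arms are present).
#' @export
run_mm <- function(config,
                   arms = c("sontag", "l1_known", "l1_under", "l1_over")) {
  arms <- match.arg(arms, several.ok = TRUE)
  sig_factor <- c(l1_known = 1, l1_under = 0.1, l1_over = 10)
  n <- config$n_nodes
  rows <- list()
  for (tr in seq_len(config$n_trials)) {
    sd_tr <- derive_seed(config$seed, tr)
    A <- sample_scale_free(n, config$degree_exponent, config$edge_budget,
                           seed = sd_tr)
    S0 <- assign_weights(A, config$weight_range, sign_mode = "positive",
                         stabilize = FALSE, seed = sd_tr)
    sys <- mm_system(S0)
    ens <- perturb_and_simulate(sys, config$delta_frac, config$times,
                                config$sigma_obs, seed = sd_tr)
    nt <- length(config$times)
    t_idx <- with_seed(derive_seed(sd_tr, 777),
                       sample(2:(nt - 1), config$n_times))
    ts <- config$times[t_idx]
    est <- lapply(arms, function(a) vector("list", length(ts)))
    names(est) <- arms
    for (j in seq_along(ts)) {
      t <- ts[j]
      for (a in arms) est[[a]][[j]] <- matrix(0, n, n)
      for (i in seq_len(n)) {
        rs <- build_response_system(ens, i, t, robust = TRUE)
        pilot <- sontag_solve(rs)$s
        if ("sontag" %in% arms) est[["sontag"]][[j]][i, ] <- pilot
        for (a in intersect(arms, names(sig_factor))) {
          eps <- mra_bound(ens, i, t, sig_factor[[a]] * config$sigma_obs,
                           pilot = pilot)
          est[[a]][[j]][i, ] <- l1_solve_row_mra(rs, eps)$s
        }
      }
    }
    for (a in arms) {
      e_t <- vapply(est[[a]], absence_error, numeric(1),
                    S0 = S0, tau = config$tau)
      rows[[length(rows) + 1]] <- data.frame(
        trial = tr, arm = a, e_single = mean(e_t),
        e_avg = absence_error(average_estimates(est[[a]]), S0, config$tau))
    }
  }
  per_trial <- do.call(rbind, rows)
  n_zero_cells <- config$n_trials * (n * (n - 1) - config$edge_budget)
  summary <- list()
  for (a in arms) {
    sub <- per_trial[per_trial$arm == a, ]
    summary[[paste0("e_single_", a)]] <-
      pseudocount_floor(mean(sub$e_single), n_zero_cells)
    summary[[paste0("e_avg_", a)]] <-
      pseudocount_floor(mean(sub$e_avg), n_zero_cells)
    summary[[paste0("pct_avg_reduction_", a)]] <-
      100 * (1 - summary[[paste0("e_avg_", a)]] /
               summary[[paste0("e_single_", a)]])
  }
  if (all(c("sontag", "l1_known") %in% arms))
    summary$sontag_over_l1_ratio <-
      summary$e_single_sontag / summary$e_single_l1_known
  list(per_trial = per_trial, summary = summary)
}
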