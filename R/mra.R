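#' Central-difference time derivative of a trajectory matrix
#'
#' O(dt^2)-accurate central difference at an interior grid time; falls back to
#' a one-sided difference with a warning at the boundary.
#'
#' @param traj time x node matrix sampled on `times`.
#' @param times time grid.
#' @param t evaluation time (must lie on the grid).
#' @return vector of per-node derivatives at `t`.
#' @export
derivative <- function(traj, times, t) {
  it <- which.min(abs(times - t))
  if (abs(times[it] - t) > 1e-9 * max(1, abs(t)))
    stop("t is not on the time grid", call. = FALSE)
  nt <- length(times)
  if (it > 1 && it < nt) {
    (traj[it + 1, ] - traj[it - 1, ]) / (times[it + 1] - times[it - 1])
  } else {
    warning("boundary time point: using one-sided difference")
    if (it == 1) (traj[2, ] - traj[1, ]) / (times[2] - times[1])
    else (traj[nt, ] - traj[nt - 1, ]) / (times[nt] - times[nt - 1])
  }
}

#' Build the response linear system of modular response analysis
#'
#' At a chosen interior time `t`, forms the response matrix
#' `R[j, k] = x_j^(k)(t) - x_j^(0)(t)` (state response of node `j` to
#' perturbation `k`) and, for a target row `i`, the right-hand side
#' `d[k] = d/dt (x_i^(k) - x_i^(0))(t)` from central differences. The row of
#' direct influences then satisfies `s_i %*% R = d` to first order in the
#' perturbation size.
#'
#' With `robust = TRUE` (the package's design), perturbation `i` is the
#' perturbation of node i's own degradation rate; since that parameter enters
#' `f_i` linearly through `-p_i x_i`, its known direct contribution
#' `-delta_i * x_i^(i)(t)` is moved to the right-hand side
#' (`d[i] + delta_i * x_i^(i)(t)`), keeping column `i` of `R` on the same
#' scale as the others. With `robust = FALSE` the historical design is
#' emulated: no admissible parameter drives node `i` directly, so column `i`
#' is replaced by the inert member's response (pure noise floor), which is the
#' documented source of severe ill-conditioning.
#'
#' @param ens a `trajectory_ensemble` from [perturb_and_simulate()].
#' @param i target row index.
#' @param t interior grid time.
#' @param robust use the robust design and right-hand-side correction.
#' @return list of class `response_system`: `R`, `d`, `row_index`, `t`,
#'   `corrected`, `col_norm_ratio` (max/min column norm of `R`).
#' @export
build_response_system <- function(ens, i, t, robust = TRUE) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  times <- ens$times
  it <- which.min(abs(times - t))
  if (abs(times[it] - t) > 1e-9 * max(1, abs(t)))
    stop("t is not on the time grid", call. = FALSE)
  if (it == 1 || it == length(times))
    stop("t must be an interior grid time (central differences need ",
         "both neighbours)", call. = FALSE)
  n <- ens$system$n
  stopifnot(i >= 1, i <= n)
  R <- matrix(0, n, n)
  d <- numeric(n)
  dbase <- derivative(ens$baseline, times, t)
  for (k in seq_len(n)) {
    traj_k <- if (!robust && k == i) ens$inert else ens$perturbed[[k]]
    R[, k] <- traj_k[it, ] - ens$baseline[it, ]
    d[k] <- derivative(traj_k, times, t)[i] - dbase[i]
  }
  if (robust) {
    # known self-term of the perturbed parameter moved to the RHS
    d[i] <- d[i] + ens$design$delta[i] * ens$perturbed[[i]][it, i]
  }
  cn <- sqrt(colSums(R^2))
  structure(list(R = R, d = d, row_index = i, t = t, corrected = robust,
                 col_norm_ratio = if (min(cn) > 0) max(cn) / min(cn) else Inf),
            class = "response_system")
}

#' Direct (least-squares) solution of the response system
#'
#' The classical MRA estimate: solves `s_i %*% R = d` by SVD pseudo-inverse
#' (singular values below `1e-12 * sigma_max` truncated), returning the
#' minimum-norm least-squares row together with the condition number of `R`.
#' Highly sensitive to noise when the response matrix is badly column-scaled.
#'
#' @param rs a `response_system`.
#' @return list with `s` (the row estimate) and `condition` (kappa of `R`).
#' @export
sontag_solve <- function(rs) {
  stopifnot(inherits(rs, "response_system"))
  sv <- svd(t(rs$R))
  pos <- sv$d > 1e-12 * max(sv$d)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  s <- drop(sv$v %*% (dinv * crossprod(sv$u, rs$d)))
  list(s = s,
       condition = if (any(!pos)) Inf else max(sv$d) / min(sv$d))
}

#' l1-minimization solution of the response system
#'
#' Delegates to [solve_row()] with `A = t(R)` and `b = d`: the sparse,
#' noise-robust alternative to [sontag_solve()].
#'
#' @param rs a `response_system`.
#' @param eps_i allowable residual for this row (e.g. from [mra_bound()]).
#' @param tol solver tolerance.
#' @return the [solve_row()] result list.
#' @export
l1_solve_row_mra <- function(rs, eps_i, tol = 1e-10) {
  stopifnot(inherits(rs, "response_system"))
  solve_row(t(rs$R), rs$d, eps_i, tol = tol)
}

#' Residual bound for the MRA l1 program from the observation-noise level
#'
#' Propagates the measurement noise into the response system, using the
#' exact noise expectations of the measurement design. Every entry of `R` is
#' a difference of two independently observed samples (variance
#' `2 * sigma_obs^2`), so the row perturbation `s_hat %*% dR` concentrates at
#' `||s_hat|| * sqrt(2) * sigma_obs * sqrt(n)`; every entry of `d` carries
#' central-difference-amplified noise of standard deviation `sigma_obs / dt`,
#' so `||dd||` concentrates at `sigma_obs * sqrt(n) / dt`. The bound is their
#' sum,
#' `eps_i = ||s_hat_i|| * sqrt(2) * sigma_obs * sqrt(n) + sigma_obs * sqrt(n)
#' / dt`, with `s_hat_i` a pilot direct solve; it scales linearly in
#' `sigma_obs`, so an assumed noise level can be swept.
#'
#' @param ens a `trajectory_ensemble`.
#' @param i target row index.
#' @param t interior grid time.
#' @param sigma_obs assumed observation-noise standard deviation.
#' @param pilot optional precomputed pilot row estimate (vector); when `NULL`
#'   a [sontag_solve()] on the robust design at `t` is used.
#' @return scalar `eps_i`.
#' @export
mra_bound <- function(ens, i, t, sigma_obs, pilot = NULL) {
  stopifnot(sigma_obs >= 0)
  n <- ens$system$n
  dt <- mean(diff(ens$times))
  if (is.null(pilot)) pilot <- sontag_solve(build_response_system(ens, i, t))$s
  dR <- sqrt(2) * sigma_obs * sqrt(n)
  dd <- sigma_obs * sqrt(n) / dt
  sqrt(sum(pilot^2)) * dR + dd
}
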