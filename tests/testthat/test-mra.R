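test_that("central-difference derivative is exact for quadratics", {
  times <- seq(0, 2, 0.1)
  tr <- cbind(times^2, rep(1, length(times)))
  d <- derivative(tr, times, 1.0)
  expect_equal(d[1], 2, tolerance = 1e-12)
  expect_equal(d[2], 0)
  # e^t at t with a fine grid: Taylor-bounded error
  times2 <- seq(-0.1, 0.1, 0.01)
  expect_equal(derivative(cbind(exp(times2)), times2, 0)[1], 1,
               tolerance = 1e-4)
  expect_warning(derivative(tr, times, 0), "one-sided")
  expect_error(derivative(tr, times, 0.123), "grid")
})

mm_demo <- function(n = 7, seed = 5, sigma_obs = 1e-4, delta = 0.1,
                    times = seq(0, 3, 0.1)) {
  A <- sample_scale_free(n, 2.2, max(n + 3, 10), seed = seed)
  S0 <- assign_weights(A, sign_mode = "positive", stabilize = FALSE,
                       seed = seed)
  sys <- mm_system(S0)
  list(sys = sys, S0 = S0,
       ens = perturb_and_simulate(sys, delta, times, sigma_obs, seed = seed))
}

test_that("non-robust design reproduces the two-orders column imbalance; robust design cures it", {
  d <- mm_demo()
  rs_ns <- build_response_system(d$ens, 1, 2.0, robust = FALSE)
  rs_r <- build_response_system(d$ens, 1, 2.0, robust = TRUE)
  expect_gt(rs_ns$col_norm_ratio, 100)
  expect_lt(rs_r$col_norm_ratio, 10)
  expect_error(build_response_system(d$ens, 1, 0), "interior")
})

test_that("both solvers recover the Jacobian row of linear dynamics from noiseless ensembles", {
  # dx/dt = (A - diag(p)) x is exactly its own linearization, so the only
  # error sources are the finite-difference stencil and the integrator
  n <- 6
  A <- with_seed(8, matrix(rnorm(n * n, sd = 0.3) * (runif(n * n) < 0.3), n, n))
  diag(A) <- 0
  p <- rep(1, n)
  J <- A - diag(p)
  times <- seq(0, 2, 0.01)
  x0 <- rep(1, n)
  delta <- 1e-3
  base <- linear_traj(J, x0, times)
  perturbed <- lapply(seq_len(n), function(k) {
    Jk <- A - diag(p + delta * (seq_len(n) == k))
    linear_traj(Jk, x0, times)
  })
  ens <- structure(list(times = times, baseline = base,
                        baseline_noiseless = base, perturbed = perturbed,
                        perturbed_noiseless = perturbed, inert = base,
                        design = data.frame(param = 1:n, delta = delta),
                        delta_frac = delta, sigma_obs = 0,
                        system = list(n = n)),
                   class = "trajectory_ensemble")
  for (i in c(1, 3, 6)) {
    rs <- build_response_system(ens, i, 1.0, robust = TRUE)
    s_direct <- sontag_solve(rs)$s
    expect_equal(s_direct, J[i, ], tolerance = 1e-4)
    s_l1 <- l1_solve_row_mra(rs, 0)$s
    expect_equal(s_l1, J[i, ], tolerance = 1e-4)
  }
})

test_that("direct solve degrades under noise where the l1 solve holds up", {
  d0 <- mm_demo(sigma_obs = 0)
  dn <- mm_demo(sigma_obs = 1e-4)
  t <- 1.5
  err <- function(s, i) max(abs(s - (d0$S0 %*% diag(1 / (1 + x_t)^2) -
                                       diag(d0$sys$p))[i, ]))
  x_t <- d0$ens$baseline[which.min(abs(d0$ens$times - t)), ]
  i <- 2
  s_clean <- sontag_solve(build_response_system(d0$ens, i, t))$s
  s_noisy <- sontag_solve(build_response_system(dn$ens, i, t))$s
  expect_gt(err(s_noisy, i), 10 * err(s_clean, i))
})

test_that("the MRA residual bound matches its formula and the realized noise", {
  d <- mm_demo()
  expect_equal(mra_bound(d$ens, 1, 1.5, 0, pilot = rep(1, 7)), 0)
  e1 <- mra_bound(d$ens, 1, 1.5, 1e-4, pilot = rep(1, 7))
  expect_equal(mra_bound(d$ens, 1, 1.5, 2e-4, pilot = rep(1, 7)), 2 * e1)
  # plug-in value: ||pilot|| * sqrt(2) * sigma * sqrt(n) + sigma * sqrt(n)/dt
  sig <- 1e-4; n <- 7; dt <- 0.1
  expect_equal(e1, sqrt(7) * sqrt(2) * sig * sqrt(n) + sig * sqrt(n) / dt)
  # the dd term matches the empirical norm of derivative-difference noise
  sys0 <- mm_system(matrix(0, 10, 10), x0 = 0)   # flat dynamics: pure noise
  times <- seq(0, 3, 0.1)
  norms <- vapply(1:40, function(k) {
    a <- simulate_mm(sys0, times, 1e-4, seed = k)$observed
    b <- simulate_mm(sys0, times, 1e-4, seed = k + 1000)$observed
    da <- derivative(a, times, 1.5); db <- derivative(b, times, 1.5)
    sqrt(sum((da - db)^2))
  }, numeric(1))
  predicted <- 1e-4 * sqrt(10) / 0.1
  expect_gt(mean(norms), 0.7 * predicted)
  expect_lt(mean(norms), 1.3 * predicted)
})
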