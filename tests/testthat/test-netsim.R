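test_that("scale-free sampler conserves the edge budget and forbids self-loops", {
  A <- sample_scale_free(3, 2.2, 2, seed = 1)
  expect_equal(sum(A), 2)
  expect_equal(sum(diag(A)), 0)
  B <- sample_scale_free(50, 2.2, 70, seed = 42)
  expect_equal(sum(B), 70)
  expect_equal(sum(diag(B)), 0)
  expect_identical(B, sample_scale_free(50, 2.2, 70, seed = 42))
  expect_error(sample_scale_free(5, 2.2, 21), "edge_budget")
})

test_that("pooled degree tail is consistent with the requested exponent", {
  degs <- unlist(lapply(1:20, function(s) {
    A <- sample_scale_free(500, 2.2, 1000, seed = s)
    c(rowSums(A != 0), colSums(A != 0))
  }))
  alpha <- powerlaw_mle(degs)
  expect_gt(alpha, 1.7)
  expect_lt(alpha, 2.7)
})

test_that("weight assignment respects support, range, sign mode and stabilization", {
  expect_equal(assign_weights(matrix(0, 4, 4), seed = 1), matrix(0, 4, 4))
  A1 <- matrix(0, 3, 3); A1[2, 1] <- 1
  W <- assign_weights(A1, c(0.5, 0.5), sign_mode = "positive", seed = 1)
  expect_equal(W[2, 1], 0.5)
  expect_equal(sum(W != 0), 1)
  # dense matrix gets pulled to spectral radius <= 0.9
  Ad <- matrix(1, 10, 10); diag(Ad) <- 0
  Sd <- assign_weights(Ad, seed = 3)
  expect_lte(max(Mod(eigen(Sd, only.values = TRUE)$values)), 0.9 + 1e-10)
  # symmetric mode: mirrored weights, spectral radius exactly beta
  As <- sample_scale_free(20, 2.2, 30, seed = 5)
  Ss <- assign_weights(As, seed = 5, symmetric = TRUE, beta = 0.9)
  expect_equal(Ss, t(Ss))
  expect_equal(max(abs(eigen(Ss, symmetric = TRUE, only.values = TRUE)$values)),
               0.9, tolerance = 1e-10)
})

test_that("total-influence closure accumulates path influences", {
  expect_equal(total_influence_closure(matrix(0, 3, 3)), matrix(0, 3, 3))
  # nilpotent chain: geometric series truncates at the path products
  S <- matrix(0, 3, 3); S[1, 2] <- 0.5; S[2, 3] <- 0.4
  G <- total_influence_closure(S)
  expect_equal(G[1, 2], 0.5)
  expect_equal(G[2, 3], 0.4)
  expect_equal(G[1, 3], 0.2)
  # scalar geometric series
  expect_equal(total_influence_closure(matrix(0.5, 1, 1))[1, 1], 1)
  # fixed point G = S + S G for random stable S
  for (seed in 1:3) {
    S <- random_stable_S(20, seed = seed)
    G <- total_influence_closure(S)
    expect_lt(frob(G - (S + S %*% G)) / max(frob(G), 1), 1e-10)
  }
  expect_error(total_influence_closure(diag(2) * 1.5), "spectral radius")
})

test_that("noise contamination follows the declared models and seeds", {
  G0 <- total_influence_closure(random_stable_S(12, seed = 2))
  expect_equal(add_noise(G0, 0, "proportional", seed = 1)$G, G0)
  # proportional noise leaves exact zeros untouched
  G0z <- G0; G0z[1, ] <- 0
  nz <- add_noise(G0z, 0.3, "proportional", seed = 4)
  expect_equal(nz$G[1, ], rep(0, 12))
  # independent mode: empirical entry sd over replicates
  sds <- unlist(lapply(1:50, function(k)
    add_noise(matrix(0, 10, 10), 0.1, "independent", seed = k)$dG))
  expect_gt(sd(sds), 0.09)
  expect_lt(sd(sds), 0.11)
  # bitwise reproducibility
  expect_identical(add_noise(G0, 0.2, "independent", seed = 9),
                   add_noise(G0, 0.2, "independent", seed = 9))
})

test_that("Michaelis-Menten simulator matches analytic limits", {
  n <- 4
  sys <- mm_system(matrix(0, n, n), degradation = 1, x0 = 2)
  times <- seq(0, 2, 0.1)
  tr <- simulate_mm(sys, times)
  expect_equal(tr$noiseless, outer(exp(-times), rep(2, n)), tolerance = 1e-7)
  # started at an equilibrium, the trajectory stays there
  S2 <- matrix(c(0, 0.4, 0.3, 0), 2, 2)
  xeq <- with_seed(1, {
    f <- function(x) -x + drop(S2 %*% (x / (1 + x)))
    x <- c(0.2, 0.2)
    for (i in 1:200) x <- x + 0.1 * f(x)   # damped fixed-point iteration
    x
  })
  sys2 <- mm_system(S2, x0 = xeq)
  tr2 <- simulate_mm(sys2, times)
  expect_lt(max(abs(sweep(tr2$noiseless, 2, xeq))), 1e-4)
  # observation noise magnitude
  tr3 <- simulate_mm(sys, times, sigma_obs = 1e-4, seed = 7)
  expect_lt(max(abs(tr3$observed - tr3$noiseless)), 5e-4)
  expect_gt(max(abs(tr3$observed - tr3$noiseless)), 1e-5)
})

test_that("MM integration is converged with respect to solver tolerance", {
  S <- assign_weights(sample_scale_free(6, 2.2, 9, seed = 3),
                      sign_mode = "positive", stabilize = FALSE, seed = 3)
  sys <- mm_system(S)
  times <- seq(0, 3, 0.1)
  a <- simulate_mm(sys, times)$noiseless
  b <- simulate_mm(sys, times, rtol = 5e-9, atol = 5e-11)$noiseless
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
})

test_that("perturbation ensembles have one member per parameter plus baseline", {
  S <- assign_weights(sample_scale_free(7, 2.2, 10, seed = 1),
                      sign_mode = "positive", stabilize = FALSE, seed = 1)
  sys <- mm_system(S)
  times <- seq(0, 2, 0.1)
  ens <- perturb_and_simulate(sys, 0.1, times, sigma_obs = 0, seed = 2)
  expect_length(ens$perturbed, 7)
  expect_equal(nrow(ens$design), 7)
  expect_equal(ens$design$delta, rep(0.1, 7))
  # zero perturbation size: members coincide with the baseline
  ens0 <- perturb_and_simulate(sys, 0, times, sigma_obs = 0, seed = 2)
  for (k in 1:7)
    expect_equal(ens0$perturbed[[k]], ens0$baseline)
})
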