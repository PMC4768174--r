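test_that("row solver reproduces closed-form special cases", {
  # shrink toward zero along c (1-D soft threshold geometry)
  r <- solve_row(diag(2), c(1, 0), 0.5)
  expect_equal(r$s, c(0.5, 0), tolerance = 1e-9)
  expect_equal(r$status, "optimal")
  # zero is feasible and l1-minimal once eps covers ||c||
  expect_equal(solve_row(diag(2), c(1, 0), 1.5)$s, c(0, 0))
  # eps = 0 with invertible matrix: the unique feasible point
  A <- matrix(c(2, 1, 0, 1), 2, 2)
  expect_equal(solve_row(A, c(1, 1), 0)$s, solve(A, c(1, 1)))
  # eps = 0 with an inconsistent system errors
  expect_error(solve_row(matrix(c(1, 1, 1, 1), 2, 2), c(1, 0), 0),
               "inconsistent")
  expect_error(solve_row(diag(2), c(1, 0), -0.1), "nonnegative")
})

test_that("row solutions are feasible, certified, and monotone in eps", {
  for (seed in 1:10) {
    S0 <- random_stable_S(15, density = 0.12, seed = seed)
    G0 <- total_influence_closure(S0)
    nz <- add_noise(G0, 0.1, "independent", seed = seed + 100)
    form <- build_linear_system(nz$G)
    A <- t(form$B)
    b <- form$C[1 + seed %% 15, ]
    last_l1 <- Inf
    for (f in c(0.25, 0.5, 1, 2, 4)) {
      eps <- f * 0.1 * sqrt(15)
      r <- solve_row(A, b, eps)
      expect_lte(r$residual_norm, eps + 1e-7)
      expect_lt(abs(r$gap), 1e-7 * max(1, r$l1))
      expect_lte(r$l1, last_l1 + 1e-9)   # larger eps never increases ||s||_1
      last_l1 <- r$l1
    }
  }
})

test_that("row solver agrees with an independent lasso implementation", {
  skip_if_not_installed("glmnet")
  for (seed in 1:5) {
    S0 <- random_stable_S(15, density = 0.12, seed = seed)
    nz <- add_noise(total_influence_closure(S0), 0.08, "independent",
                    seed = seed + 7)
    form <- build_linear_system(nz$G)
    A <- t(form$B); b <- form$C[seed, ]
    r <- solve_row(A, b, 0.3)
    if (r$lambda > 1e-10) {
      g <- glmnet::glmnet(A, b, lambda = r$lambda / nrow(A),
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14, maxit = 1e7)
      expect_equal(as.numeric(coef(g))[-1], r$s, tolerance = 1e-5)
    }
  }
})

test_that("row solver matches support-enumeration brute force on small instances", {
  # a quick version of the exhaustive acceptance check
  for (seed in 1:10) {
    inst <- with_seed(seed, {
      A <- diag(8) + matrix(rnorm(64, sd = 0.25 / sqrt(8)), 8, 8)
      s_true <- numeric(8)
      supp <- sample(8, 3)
      s_true[supp] <- sample(c(-1, 1), 3, TRUE) * runif(3, 0.5, 1.5)
      noise <- rnorm(8, sd = 0.02)
      list(A = A, b = drop(A %*% s_true) + noise,
           eps = sqrt(sum(noise^2)) * 1.2)
    })
    mine <- solve_row(inst$A, inst$b, inst$eps)
    oracle <- brute_force_l1(inst$A, inst$b, inst$eps, kmax = 4)
    expect_equal(mine$l1, oracle, tolerance = 1e-4)
  }
})

test_that("matrix recovery at eps = 0 equals closed-form deconvolution", {
  S0 <- random_stable_S(15, density = 0.15, seed = 11)
  nz <- add_noise(total_influence_closure(S0), 0.05, "independent", seed = 4)
  form <- build_linear_system(nz$G)
  res <- solve_matrix(form, rep(0, 15))
  expect_lt(frob(res$S_hat - nd_closed_form(nz$G)), 1e-6)
  expect_true(all(res$status == "optimal"))
  # zero-diagonal flag wipes the diagonal and keeps rows feasible
  bt <- true_bound(S0, form)
  rz <- solve_matrix(form, bt, zero_diag = TRUE)
  expect_equal(diag(rz$S_hat), rep(0, 15))
  expect_true(all(rz$residual_norms <= bt$eps + 1e-7))
})

test_that("bound estimators verify their algebraic definitions", {
  # scalar true bound: s0 = 0.5, noisy g = 1.1 -> |0.5*2.1 - 1.1| = 0.05
  f <- build_linear_system(matrix(1.1, 1, 1))
  expect_equal(true_bound(matrix(0.5, 1, 1), f)$eps, 0.05)
  # noiseless: all bounds vanish
  S0 <- random_stable_S(12, seed = 3)
  G0 <- total_influence_closure(S0)
  f0 <- build_linear_system(G0)
  expect_equal(true_bound(S0, f0)$eps, rep(0, 12), tolerance = 1e-10)
  expect_equal(approx_bound(G0, dG = matrix(0, 12, 12))$eps, rep(0, 12))
  expect_equal(upper_bound(G0, matrix(0, 12, 12))$eps, rep(0, 12))
  # noisy: upper dominates approx elementwise; approx tracks true within 10x
  nz <- add_noise(G0, 0.1, "proportional", seed = 5)
  et <- true_bound(S0, build_linear_system(nz$G))$eps
  ea <- approx_bound(nz$G, nz$dG)$eps
  eu <- upper_bound(nz$G, nz$dG)$eps
  expect_true(all(eu >= ea))
  expect_lt(mean(ea) / mean(et), 10)
  expect_gt(mean(ea) / mean(et), 0.1)
})

test_that("restricted-isometry error bound matches its formula", {
  expect_equal(ric_error_bound(0.2, 0), 0)
  expect_equal(ric_error_bound(0, 1), 4)
  grid <- seq(0, sqrt(2) - 1 - 1e-6, length.out = 30)
  vals <- vapply(grid, ric_error_bound, numeric(1), eps_i = 1)
  expect_true(all(diff(vals) > 0))
  expect_error(ric_error_bound(sqrt(2) - 1, 1), "delta_2K")
  expect_error(ric_error_bound(-0.1, 1), "delta_2K")
})

test_that("Hoyer measure spans its range with the documented conventions", {
  one <- matrix(0, 5, 5); one[2, 3] <- 7
  expect_equal(hoyer(one), 1)
  expect_equal(hoyer(matrix(2, 4, 4)), 0)
  expect_equal(hoyer(matrix(c(3, 4), 1, 2)),
               (sqrt(2) - 7 / 5) / (sqrt(2) - 1))
  expect_equal(hoyer(matrix(0, 3, 3)), 1)   # all-zero convention
})
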