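sphere <- function(x) sum(x^2)

cfg2 <- function(seed = 1, D = 2, T = 100, map = NULL) {
  sparrow_config(D = D, lb = -10, ub = 10, N = 30, T = T, map = map,
                 seed = seed)
}

test_that("discoverer kernel matches scalar arithmetic", {
  X <- matrix(1, 1, 3)
  cfg <- sparrow_config(D = 3, lb = -10, ub = 10, T = 500)
  # safe branch, rank 1, forced alpha = 1
  out <- sparrowforge:::.discoverer_step(X, T = 500, R2 = 0.1, ST = 0.8,
                                         alpha = 1, Q = 0)
  expect_equal(out[1, ], rep(exp(-1 / 500), 3))
  expect_equal(out[1, 1], 0.9980020, tolerance = 1e-6)
  # danger branch with forced Q = 0 leaves the position unchanged
  out2 <- sparrowforge:::.discoverer_step(X, T = 500, R2 = 0.9, ST = 0.8,
                                          alpha = 1, Q = 0)
  expect_equal(out2, X)
  # origin is a fixed point of both branches at Q = 0
  X0 <- matrix(0, 1, 3)
  expect_equal(sparrowforge:::.discoverer_step(X0, 500, 0.1, 0.8, 1, 0), X0)
  expect_equal(sparrowforge:::.discoverer_step(X0, 500, 0.9, 0.8, 1, 0), X0)
})

test_that("follower kernel matches the hand pseudo-inverse example", {
  # A = (1,-1), x - xb = (2,4): s = (2*1 + 4*(-1))/2 = -1
  xb <- c(0, 0)
  X <- matrix(c(2, 4), 1, 2)
  out <- sparrowforge:::.follower_step(X, ranks = 1, N = 30, xb = xb,
                                       xw = c(9, 9),
                                       A = matrix(c(1, -1), 1, 2), Q = 0)
  expect_equal(out[1, ], c(-1, -1))
  # x at xb stays at xb (s = 0)
  out2 <- sparrowforge:::.follower_step(matrix(xb, 1, 2), 1, 30, xb,
                                        c(9, 9), matrix(c(1, 1), 1, 2), 0)
  expect_equal(out2[1, ], xb)
  # hungry branch with forced Q = 0 gives the zero vector
  out3 <- sparrowforge:::.follower_step(matrix(c(2, 4), 1, 2), ranks = 16,
                                        N = 30, xb = xb, xw = c(1, 1),
                                        A = matrix(c(1, 1), 1, 2), Q = 0)
  expect_equal(out3[1, ], c(0, 0))
})

test_that("pseudo-inverse identity A %*% A+ = 1 holds for random sign vectors", {
  set.seed(11)
  ok <- vapply(1:200, function(r) {
    D <- sample(2:40, 1)
    A <- sample(c(-1, 1), D, replace = TRUE)
    # A+ = t(A) (A t(A))^-1 = t(A)/D for a +-1 row; apply the division
    # after the inner product so the identity is exact in doubles
    identical(sum(A * A) / D, 1)
  }, TRUE)
  expect_true(all(ok))
})

test_that("baseline reaches 1e-10 on Sphere d=2 at full length", {
  res <- run_ssa(sphere, sparrow_config(D = 2, lb = -10, ub = 10, N = 30,
                                        T = 500, seed = 1))
  expect_lt(res$best_f, 1e-10)
})

test_that("scout kernel fixed points match the zero-draw contracts", {
  xb <- c(1, 2); xw <- c(5, 5)
  X <- matrix(c(3, 4), 1, 2)
  # away from the best, beta = 0 lands exactly on xb
  out <- sparrowforge:::.scout_step(X, f = 2, fg = 1, fw = 10, xb = xb,
                                    xw = xw, beta = 0, K = 0.5,
                                    epsilon = 1e-50)
  expect_equal(out[1, ], xb)
  # at the best with K = 0 the position is unchanged
  out2 <- sparrowforge:::.scout_step(X, f = 1, fg = 1, fw = 10, xb = xb,
                                     xw = xw, beta = 1, K = 0,
                                     epsilon = 1e-50)
  expect_equal(out2[1, ], c(3, 4))
  # at the best sitting on the worst position, any K leaves it fixed
  out3 <- sparrowforge:::.scout_step(matrix(xw, 1, 2), f = 1, fg = 1,
                                     fw = 10, xb = xb, xw = xw, beta = 1,
                                     K = 0.8, epsilon = 1e-50)
  expect_equal(out3[1, ], xw)
})

test_that("gaussian mutation is multiplicative with fixed points", {
  cfg <- cfg2()
  x <- c(2, -1)
  expect_equal(gaussian_mutate(x, cfg, G = c(0, 0)), x)
  expect_equal(gaussian_mutate(c(0, 0), cfg, G = rnorm(2)), c(0, 0))
  expect_equal(gaussian_mutate(c(2, 2), cfg, G = c(0.5, 0.5)), c(3, 3))
})

test_that("runs are deterministic under a fixed seed", {
  r1 <- run_ssa(sphere, cfg2(seed = 3))
  r2 <- run_ssa(sphere, cfg2(seed = 3))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_x, r2$best_x)
  m <- chaotic_map("iterative")
  c1 <- run_cgssa(sphere, cfg2(seed = 3, map = m))
  c2 <- run_cgssa(sphere, cfg2(seed = 3, map = m))
  expect_identical(c1$trace, c2$trace)
})

test_that("traces are non-increasing and T = 1 honours the greedy contract", {
  for (mk in list(NULL, chaotic_map("iterative"), chaotic_map("logistic"))) {
    for (s in 1:3) {
      cfg <- cfg2(seed = s, T = 50, map = mk)
      res <- if (is.null(mk)) run_ssa(sphere, cfg)
             else run_cgssa(sphere, cfg)
      expect_true(all(diff(res$trace) <= 0))
    }
  }
  res1 <- run_ssa(sphere, cfg2(seed = 4, T = 1))
  expect_length(res1$trace, 1)
  set.seed(4)
  X0 <- matrix(runif(30 * 2), 30, 2) * 20 - 10
  expect_lte(res1$best_f, min(apply(X0, 1, sphere)))
})

test_that("all positions and the answer stay inside the box", {
  shifted <- function(x) sum((x - 3)^2)   # optimum outside reach of origin
  cfg <- sparrow_config(D = 4, lb = -2, ub = 2, N = 20, T = 60,
                        map = chaotic_map("iterative"), seed = 8)
  res <- run_cgssa(shifted, cfg)
  expect_true(all(res$best_x >= -2 & res$best_x <= 2))
  expect_equal(res$best_x, rep(2, 4), tolerance = 0.2)
})

test_that("non-finite objective values are treated as +Inf, run proceeds", {
  nasty <- function(x) if (abs(x[1]) < 0.5) NaN else sum(x^2)
  res <- run_ssa(nasty, cfg2(seed = 2, T = 30))
  expect_true(is.finite(res$best_f))
})

test_that("improved runs dominate the baseline on Sphere in paired seeds", {
  m <- chaotic_map("iterative")
  wins <- 0
  for (s in 1:20) {
    b <- run_ssa(sphere, sparrow_config(D = 2, lb = -10, ub = 10, N = 30,
                                        T = 100, seed = s))$best_f
    i <- run_cgssa(sphere, sparrow_config(D = 2, lb = -10, ub = 10, N = 30,
                                          T = 100, map = m,
                                          seed = s))$best_f
    wins <- wins + (i <= b)
  }
  expect_gte(wins, 15)
})

test_that("CGSSA reaches 1e-8 on Sphere d=2 in at least 19/20 seeded runs", {
  m <- chaotic_map("iterative")
  hits <- sum(vapply(1:20, function(s) {
    run_cgssa(sphere, sparrow_config(D = 2, lb = -10, ub = 10, N = 30,
                                     T = 500, map = m, seed = s))$best_f < 1e-8
  }, TRUE))
  expect_gte(hits, 19)
})

test_that("config validation rejects bad settings", {
  expect_error(sparrow_config(D = 2, lb = 1, ub = -1))
  expect_error(sparrow_config(D = 2, lb = -1, ub = 1, ST = 0.3))
  expect_error(run_cgssa(sphere, cfg2()), "chaotic map")
  expect_error(run_ssa(sphere, cfg2(map = chaotic_map("tent"))), "map")
})
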