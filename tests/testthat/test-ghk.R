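test_that("degenerate one-dimensional rectangles are exact normal intervals", {
  expect_identical(ghk_mvn_rectangle(-Inf, 0, matrix(1)), pnorm(0))
  expect_equal(ghk_mvn_rectangle(-1, 2, matrix(4)),
               pnorm(1) - pnorm(-0.5))
})

test_that("bivariate orthant probability matches the arcsine closed form", {
  # P(w1 > 0, w2 > 0) = 1/4 + arcsin(rho) / (2 pi)
  for (rho in c(-0.4, 0.2, 0.5)) {
    sig <- matrix(c(1, rho, rho, 1), 2)
    closed <- 1 / 4 + asin(rho) / (2 * pi)
    expect_equal(ghk_mvn_rectangle(c(0, 0), c(Inf, Inf), sig, n_draws = 500),
                 closed, tolerance = 0.003)
  }
})

test_that("GHK matches deterministic quadrature on random 4-d rectangles", {
  set.seed(11)
  for (i in 1:10) {
    A <- matrix(rnorm(16), 4)
    sig <- stats::cov2cor(A %*% t(A) + diag(4) * 0.5)
    lo <- runif(4, -2, 0)
    hi <- lo + runif(4, 0.5, 3)
    g <- ghk_mvn_rectangle(lo, hi, sig, n_draws = 500, seed = i)
    q <- mvn_rectangle_quadrature(lo, hi, sig, nodes = 32)
    expect_lt(abs(g - q), 0.005)
  }
})

test_that("GHK is deterministic given seed and draws", {
  sig <- stats::cov2cor(crossprod(matrix(rnorm(16), 4)) + diag(4))
  a <- ghk_mvn_rectangle(rep(-1, 4), rep(1, 4), sig, 300, seed = 9)
  b <- ghk_mvn_rectangle(rep(-1, 4), rep(1, 4), sig, 300, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, ghk_mvn_rectangle(rep(-1, 4), rep(1, 4), sig,
                                              300, seed = 10)))
})

test_that("non-positive-definite covariances are rejected", {
  sig <- matrix(c(1, 2, 2, 1), 2)
  expect_error(ghk_mvn_rectangle(c(0, 0), c(1, 1), sig),
               "not positive definite")
})

test_that("choice regions encode the argmax condition", {
  # all utilities zero: reference region is the negative orthant of u
  r1 <- alternative_region(1, matrix(0, 1, 3), 1)
  expect_equal(r1$M, -diag(3))
  expect_equal(r1$c, c(0, 0, 0))
  # alternative 2: u2 > 0, u2 > u3, u2 > u4
  r2 <- alternative_region(2, matrix(0, 1, 3), 1)
  expect_equal(r2$M, rbind(c(1, 0, 0), c(1, -1, 0), c(1, 0, -1)))
  # nonzero utilities shift the offsets
  b2 <- rbind(c(0.5, -0.2, 0.1))
  r3 <- alternative_region(3, b2, 1)
  expect_equal(r3$c, c(-0.2, -0.2 - 0.5, -0.2 - 0.1))
  # regions partition u-space: empirical check by plain Monte Carlo
  set.seed(21)
  eta <- c(0.3, -0.2, 0.1)
  u <- matrix(rnorm(3 * 2000), ncol = 3) %*% chol(matrix(1, 3, 3) + diag(3))
  util <- cbind(0, sweep(u, 2, eta, "+"))
  pick <- max.col(util)
  for (j in 1:4) {
    reg <- alternative_region(j, matrix(eta, 1), 1)
    inside <- rowSums(u %*% t(reg$M) +
                        rep(reg$c, each = nrow(u)) > 0) == 3
    expect_equal(inside, pick == j)
  }
})

test_that("symmetric utilities give equal quarter shares per alternative", {
  p <- selmnp_params(beta1 = 0, beta2 = matrix(0, 1, 3))
  cp <- choice_probabilities(p, x1 = 1, x2 = 1, n_draws = 1000)
  # exchangeable alternatives: each region has probability 1/4, split by the
  # independent selection probability 1/2
  expect_equal(cp$p_nonneeds, 0.5)
  expect_lt(max(abs(cp$p_joint - 0.125)), 0.002)
})

test_that("probabilities factorise when selection correlation is zero", {
  b2 <- rbind(c(-0.6, -0.2, -1.0))
  p0 <- selmnp_params(beta1 = 0.4, beta2 = b2, rho = c(0, 0, 0))
  cp <- choice_probabilities(p0, x1 = 1, x2 = 1, n_draws = 2000, seed = 5)
  # region probabilities from an independent probability object
  regions <- vapply(1:4, function(j) {
    reg <- alternative_region(j, b2, 1)
    sig <- reg$M %*% (matrix(1, 3, 3) + diag(3)) %*% t(reg$M)
    mvn_rectangle_quadrature(-reg$c, rep(Inf, 3), sig, nodes = 40)
  }, numeric(1))
  expect_lt(max(abs(cp$p_joint - pnorm(0.4) * regions)), 0.003)
})

test_that("joint probabilities sum to one and match a brute-force oracle", {
  truth <- small_truth(rho = c(0.45, 0.2, -0.3))
  x1 <- c(1, 1, -10.2, 0)
  x2 <- c(1, 1, -10.2, 1)
  cp <- choice_probabilities(truth, x1, x2, n_draws = 1000, seed = 3)
  expect_equal(cp$p_nonneeds + sum(cp$p_joint), 1, tolerance = 0.004)

  # brute force: a million joint normal draws
  set.seed(99)
  n <- 1e6
  sig <- attr(truth, "joint_sigma")       # (u2, u3, u4, eps1)
  z <- matrix(rnorm(4 * n), n) %*% chol(sig)
  s1 <- sum(x1 * truth$beta1)
  eta <- as.numeric(crossprod(truth$beta2, x2))
  sel <- s1 + z[, 4] > 0
  util <- cbind(0, sweep(z[, 1:3], 2, eta, "+"))
  pick <- max.col(util)
  mc <- vapply(1:4, function(j) mean(sel & pick == j), numeric(1))
  expect_lt(max(abs(cp$p_joint - mc)), 0.003)
})

test_that("raising the selection intercept raises the selection probability", {
  b2 <- rbind(c(-0.5, 0.3, -0.2))
  p_sel <- vapply(c(-1, -0.3, 0.2, 1), function(b0) {
    p <- selmnp_params(beta1 = b0, beta2 = b2, rho = c(0.3, 0.3, 0.3))
    1 - choice_probabilities(p, 1, 1, n_draws = 500)$p_nonneeds
  }, numeric(1))
  expect_true(all(diff(p_sel) > 0))
})

test_that("compiled GHK agrees with the pure-R reference implementation", {
  truth <- small_truth(rho = c(0.3, -0.2, 0.5))
  unif <- selmnp:::halton_raw(200, 3)
  shift <- selmnp:::ghk_shifts(1, 3, seed = 17)
  chols <- selmnp:::mnp_chols(truth$rho, truth$omega, selection = TRUE)
  shifted <- (sweep(unif, 2, shift[1, ], "+")) %% 1
  for (j in 1:4) {
    s1 <- 0.7; eta <- c(-0.4, 0.2, -1.1)
    cpp <- selmnp_probs_cpp(s1, matrix(eta, 1), chols, unif, shift, TRUE)[1, j]
    ref <- joint_prob_r(s1, eta, j, truth$rho, unif = shifted)
    expect_equal(cpp, unname(ref), tolerance = 1e-7)
  }
})
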