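test_that("sandwich variance matches a hand-assembled A^-1 B A^-1", {
  # 3 clusters x 2 observations, 2 parameters, arbitrary scores and weights
  set.seed(42)
  S <- matrix(rnorm(12), 6, 2)
  w <- c(0.5, 1.5, 1, 1, 2, 0.3)
  cl <- c("a", "a", "b", "b", "c", "c")
  A <- crossprod(S, S * w)
  G <- rbind(colSums(S[1:2, ] * w[1:2]),
             colSums(S[3:4, ] * w[3:4]),
             colSums(S[5:6, ] * w[5:6]))
  B <- t(G) %*% G
  by_hand <- solve(A) %*% B %*% solve(A)
  expect_equal(sandwich_vcov(S, A, cl, w), by_hand, tolerance = 1e-12)
})

test_that("with singleton clusters and unit weights the sandwich is the HC form", {
  set.seed(7)
  S <- matrix(rnorm(20), 10, 2)
  A <- crossprod(S)
  v <- sandwich_vcov(S, A, cluster_ids = 1:10, weights = rep(1, 10))
  hc <- solve(A) %*% crossprod(S) %*% solve(A)
  expect_equal(v, hc, tolerance = 1e-12)
})

test_that("duplicating rows within clusters while halving weights changes nothing", {
  des <- small_design(n_individuals = 120, seed = 19)
  dup <- function(x) if (is.matrix(x)) x[rep(seq_len(nrow(x)), each = 2), ]
                     else x[rep(seq_along(x), each = 2)]
  des2 <- des
  des2$X1 <- dup(des$X1); des2$X2 <- dup(des$X2)
  des2$y1 <- dup(des$y1); des2$y2 <- dup(des$y2)
  des2$weights <- dup(des$weights) / 2
  des2$cluster_ids <- dup(des$cluster_ids)
  des2$n_obs <- 2L * des$n_obs
  # the weighted objective itself is exactly invariant ...
  e1 <- selmnp:::msl_env(des, 60, 2, "iid", TRUE)
  e2 <- selmnp:::msl_env(des2, 60, 2, "iid", TRUE)
  tr <- small_truth()
  th <- selmnp:::theta_pack(tr$beta1, tr$beta2, tr$rho, tr$omega, "iid")
  expect_identical(selmnp:::env_negloglik(e1, th),
                   selmnp:::env_negloglik(e2, th))
  # ... and so are the estimates and the cluster sandwich (correlations held
  # fixed: the likelihood is flat in them for this toy design, and any flat
  # direction lets two optimiser paths end at different ridge points)
  f1 <- fit_selmnp(des, n_draws = 60, seed = 2, maxit = 60,
                   fix_rho = c(0.25, 0.25, 0.25))
  f2 <- fit_selmnp(des2, n_draws = 60, seed = 2, maxit = 60,
                   fix_rho = c(0.25, 0.25, 0.25))
  expect_equal(f1$theta, f2$theta, tolerance = 1e-4)
  expect_equal(f1$vcov_robust, f2$vcov_robust, tolerance = 1e-3)
})

test_that("estimation requires outcome information", {
  des <- small_design(n_individuals = 60, seed = 23)
  des0 <- des
  des0$y1 <- rep(0L, des$n_obs)
  des0$y2 <- rep(NA_integer_, des$n_obs)
  expect_error(fit_selmnp(des0), "needs observations")
})

test_that("the joint fit at zero correlation factorises into the pilots", {
  cfg <- small_config(n_individuals = 600, n_waves = 3, seed = 29,
                      rho = c(0, 0, 0))
  coded <- derive_outcomes(simulate_panel(cfg))
  des <- build_design(coded$data, small_spec(cfg$age_center))
  fit <- fit_selmnp(des, n_draws = 100, pilot_draws = 100, seed = 5,
                    fix_rho = c(0, 0, 0))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates$beta1 - fit$pilot$probit)), 0.02)
  expect_lt(max(abs(fit$estimates$beta2 - fit$pilot$mnp)), 0.02)
})

test_that("the optimiser does not decrease the likelihood with more iterations", {
  des <- small_design(n_individuals = 150, seed = 37)
  f_short <- fit_selmnp(des, n_draws = 60, seed = 3, maxit = 3)
  f_long <- fit_selmnp(des, n_draws = 60, seed = 3, maxit = 60)
  expect_gte(f_long$loglik, f_short$loglik - 1e-8)
})

test_that("Hosmer-Lemeshow statistic follows its defining formula", {
  # perfect calibration: observed = expected in every group -> statistic 0
  set.seed(13)
  p <- rep(seq(0.1, 0.9, by = 0.2), each = 10)
  y <- unlist(lapply(seq(0.1, 0.9, by = 0.2), function(q)
    rep(c(1, 0), round(c(10 * q, 10 * (1 - q))))))
  hl0 <- hosmer_lemeshow(y, p, groups = 5)
  expect_equal(hl0$statistic, 0, tolerance = 1e-12)
  expect_equal(hl0$df, 3L)

  # two-group hand computation
  p2 <- c(rep(0.2, 10), rep(0.7, 10))
  y2 <- c(rep(1, 3), rep(0, 7), rep(1, 6), rep(0, 4))
  hl2 <- hosmer_lemeshow(y2, p2, groups = 2)
  by_hand <- 1 / (10 * 0.2 * 0.8) + 1 / (10 * 0.7 * 0.3)
  expect_equal(hl2$statistic, by_hand, tolerance = 1e-12)
  expect_equal(hl2$df, 0L)
})

test_that("information criteria follow their definitions and reject k = 0", {
  ic <- information_criteria(-100, 10, 100)
  expect_equal(ic$aic, 220)
  expect_equal(ic$bic, 200 + 10 * log(100))
  expect_error(information_criteria(-100, 0, 100), "k must be")
})

test_that("coefficient bias shrinks as the simulated sample grows", {
  truth <- small_truth()
  tv <- c(truth$beta1, as.numeric(truth$beta2))
  mab <- vapply(c(150, 900), function(n) {
    cfg <- small_config(n_individuals = n, n_waves = 3, seed = 41)
    coded <- derive_outcomes(simulate_panel(cfg))
    des <- build_design(coded$data, small_spec(cfg$age_center))
    fit <- fit_selmnp(des, n_draws = 100, seed = 6)
    mean(abs(fit$theta[seq_along(tv)] - tv))
  }, numeric(1))
  expect_lt(mab[2], mab[1])
})

test_that("the unrestricted error-structure mode keeps the scale normalisation", {
  des <- small_design(n_individuals = 150, n_waves = 2, seed = 59)
  fit <- fit_selmnp(des, n_draws = 60, seed = 8, maxit = 40,
                    mode = "unrestricted")
  om <- fit$estimates$omega
  expect_equal(om[1, 1], 2, tolerance = 1e-10)       # fixed by normalisation
  expect_true(all(eigen(om, symmetric = TRUE)$values > 0))
  expect_equal(fit$k_free, length(fit$theta))
  # iid mode is nested: its omega is a special case of the unrestricted one
  expect_equal(dim(om), c(3L, 3L))
})
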