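# Shared fixtures: a small generating truth (4 terms per equation) so unit
# tests fit in seconds, and a pure-R reference GHK used as an independent
# implementation check of the compiled path.

small_truth <- function(rho = c(0.3, 0.3, 0.3)) {
  b1 <- c("(Intercept)" = 0.8, man = -0.4, age = 0.01, unmarried = -0.3)
  b2 <- cbind(financial = c(-1.0, 0.2, -0.005, 0.3),
              time = c(-0.8, -0.1, -0.01, 0.1),
              lack = c(-1.2, 0.1, 0.008, 0.2))
  rownames(b2) <- c("(Intercept)", "man", "age", "unmarried")
  selmnp_params(b1, b2, rho = rho)
}

small_spec <- function(age_center = 52.753) {
  model_spec(c("man", "age", "unmarried"), c("man", "age", "unmarried"),
             age_center = age_center)
}

small_config <- function(n_individuals = 400, n_waves = 3, seed = 7,
                         rho = c(0.3, 0.3, 0.3), ...) {
  synthetic_config(n_individuals = n_individuals, n_waves = n_waves,
                   truth = small_truth(rho), seed = seed, ...)
}

small_design <- function(...) {
  cfg <- small_config(...)
  coded <- derive_outcomes(simulate_panel(cfg))
  build_design(coded$data, small_spec(cfg$age_center))
}

# Pure-R GHK for P(w > a), w ~ N(0, L L'), same draw scheme as the compiled
# kernel (antithetic pairs, no draw in the last dimension).
ghk_lower_r <- function(a, L, unif) {
  d <- length(a)
  npairs <- nrow(unif)
  acc <- 0
  for (r in seq_len(npairs)) {
    for (anti in 0:1) {
      prod <- 1
      z <- numeric(d)
      for (k in seq_len(d)) {
        m <- if (k > 1) sum(L[k, 1:(k - 1)] * z[1:(k - 1)]) else 0
        tt <- (a[k] - m) / L[k, k]
        pk <- pnorm(-tt)
        prod <- prod * pk
        if (prod <= 0) break
        if (k < d) {
          u <- unif[r, k]
          if (anti == 1) u <- 1 - u
          z[k] <- -qnorm(max(pk * (1 - u), 1e-310))
        }
      }
      acc <- acc + prod
    }
  }
  acc / (2 * npairs)
}

# Independent assembly of the joint probability P(y1 = 1, y2 = j) for one
# observation: builds M_j, the joint covariance and the bounds from first
# principles, then runs the R reference GHK.
joint_prob_r <- function(s1, eta, j, rho, omega = matrix(1, 3, 3) + diag(3),
                         unif) {
  if (j == 1) {
    M <- -diag(3)
    a <- eta
  } else {
    jj <- j - 1
    e <- diag(3)
    M <- rbind(e[jj, ], t(sapply(setdiff(1:3, jj), function(k) e[jj, ] - e[k, ])))
    a <- c(-eta[jj], eta[setdiff(1:3, jj)] - eta[jj])
  }
  r <- rho * sqrt(diag(omega))
  v <- M %*% omega %*% t(M)
  mr <- as.numeric(M %*% r)
  sig <- rbind(cbind(v, mr), c(mr, 1))
  L <- t(chol(sig))
  ghk_lower_r(c(a, -s1), L, unif)
}
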