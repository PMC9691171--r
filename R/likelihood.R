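# Weighted simulated log-likelihood of the two-equation selection system and
# its finite-difference machinery.
#
# The log-probability of observation i depends on the parameters only through
# four scalars: the selection index s1 = x1'beta1 and the three outcome
# indices eta_j = x2'beta_2j.  Finite differences are therefore taken in this
# reduced index space (2 bumps for s1, 6 for eta, plus bumps of the free
# error-structure parameters) and chained to the coefficients, which costs
# ~14 likelihood passes per gradient instead of two per coefficient.

fd_h <- 1e-4   # central-difference step in index space

# Cholesky factors of the per-alternative region covariances from raw (rho,
# omega); NULL when the implied joint covariance is not positive definite.
mnp_chols <- function(rho, omega, selection, margin = 0.005) {
  r <- rho * sqrt(diag(omega))
  sig <- rbind(cbind(omega, r), c(r, 1))
  if (inherits(tryCatch(chol(sig), error = identity), "error")) return(NULL)
  # keep the conditional selection-error variance bounded away from zero:
  # near-singular joint covariances destabilise the simulated likelihood
  if (selection && 1 - sum(r * solve(omega, r)) < margin) return(NULL)
  lapply(1:4, function(j) {
    M <- region_matrix(j)
    v <- M %*% omega %*% t(M)
    if (selection) {
      mr <- as.numeric(M %*% r)
      v <- rbind(cbind(v, mr), c(mr, 1))
    }
    t(chol(v))
  })
}

# Per-observation log-probabilities given index vectors.  `chols` from
# mnp_chols(); unif/shift common across evaluations (common random numbers).
index_logprobs <- function(s1, eta, y1, y2, chols, unif, shift, selection) {
  y2c <- y2
  y2c[is.na(y2c)] <- 1L   # ignored when y1 == 0
  selmnp_logprobs_cpp(as.numeric(s1), eta, as.integer(y1), as.integer(y2c),
                      chols, unif, shift, selection)
}

#' Weighted simulated log-likelihood
#'
#' Evaluates \eqn{\sum_i w_i \log p_i} where \eqn{p_i} is
#' \eqn{\Phi(-x_1'\beta_1)} for non-needs observations and the GHK-simulated
#' joint probability \eqn{P(y_1 = 1, y_2 = j)} otherwise.  Deterministic
#' given \code{(seed, n_draws)}; the same shifted-Halton draws are reused
#' across parameter evaluations.
#'
#' @param params a [selmnp_params()] object.
#' @param design a [build_design()] result.
#' @param n_draws GHK draws per observation (antithetic pairs count as two).
#' @param seed integer seed for the Halton shift.
#' @return list with \code{loglik}, per-observation \code{contributions}
#'   (weighted log-probabilities), and \code{n_floored}, the number of
#'   probabilities floored at 1e-300 before taking logs.
#' @export
selmnp_loglik <- function(params, design, n_draws = 200, seed = 1L) {
  stopifnot(inherits(params, "selmnp_params"),
            inherits(design, "selmnp_design"))
  b1 <- align_coef(params$beta1, colnames(design$X1), "beta1")
  b2 <- align_coef_mat(params$beta2, colnames(design$X2))
  s1 <- as.numeric(design$X1 %*% b1)
  eta <- design$X2 %*% b2
  chols <- mnp_chols(params$rho, params$omega, selection = TRUE)
  if (is.null(chols))
    stop("implied joint error covariance is not positive definite",
         call. = FALSE)
  unif <- halton_raw(n_draws, 3L)
  shift <- design_shifts(design, seed)
  lp <- index_logprobs(s1, eta, design$y1, design$y2, chols, unif, shift, TRUE)
  n_floored <- sum(lp <= log(1e-300) + 1)
  if (n_floored > 0)
    warning(n_floored, " probability value(s) floored at 1e-300")
  contrib <- design$weights * lp
  list(loglik = sum(contrib), contributions = contrib,
       n_floored = n_floored)
}

align_coef <- function(beta, cols, what) {
  if (!is.null(names(beta)) && all(cols %in% names(beta)))
    return(beta[cols])
  if (length(beta) != length(cols))
    stop(what, " has length ", length(beta), " but the design has ",
         length(cols), " columns", call. = FALSE)
  beta
}

align_coef_mat <- function(beta2, cols) {
  if (!is.null(rownames(beta2)) && all(cols %in% rownames(beta2)))
    return(beta2[cols, , drop = FALSE])
  if (nrow(beta2) != length(cols))
    stop("beta2 has ", nrow(beta2), " rows but the design has ",
         length(cols), " columns", call. = FALSE)
  beta2
}

# --- packed-parameter objective used by the optimiser ------------------------

# Layout: beta1 (k1) | beta2 alt2 (k2) | alt3 | alt4 | zeta (3) [iid mode]
# or | zeta (3) | lfree (5) [unrestricted: l21, log l22, l31, l32, log l33,
# with l11 = sqrt(2) fixed].
theta_pack <- function(beta1, beta2, rho, omega, mode) {
  th <- c(beta1, as.numeric(beta2), atanh(rho))
  if (mode == "unrestricted") {
    L <- t(chol(omega))
    th <- c(th, L[2, 1], log(L[2, 2]), L[3, 1], L[3, 2], log(L[3, 3]))
  }
  th
}

theta_unpack <- function(theta, k1, k2, mode) {
  beta1 <- theta[seq_len(k1)]
  beta2 <- matrix(theta[k1 + seq_len(3 * k2)], k2, 3)
  zeta <- theta[k1 + 3 * k2 + 1:3]
  rho <- tanh(zeta)
  if (mode == "unrestricted") {
    lf <- theta[k1 + 3 * k2 + 3 + 1:5]
    L <- matrix(0, 3, 3)
    L[1, 1] <- sqrt(2)
    L[2, 1] <- lf[1]; L[2, 2] <- exp(lf[2])
    L[3, 1] <- lf[3]; L[3, 2] <- lf[4]; L[3, 3] <- exp(lf[5])
    omega <- L %*% t(L)
  } else {
    omega <- iid_omega()
  }
  list(beta1 = beta1, beta2 = beta2, rho = rho, omega = omega)
}

n_error_params <- function(mode) if (mode == "unrestricted") 8L else 3L

# Objective environment: shared draws, data and bookkeeping for the joint
# (selection = TRUE) or outcome-only pilot (selection = FALSE) likelihood.
msl_env <- function(design, n_draws, seed, mode, selection = TRUE,
                    subset = NULL) {
  e <- new.env(parent = emptyenv())
  idx <- if (is.null(subset)) seq_along(design$y1) else subset
  e$X1 <- design$X1[idx, , drop = FALSE]
  e$X2 <- design$X2[idx, , drop = FALSE]
  e$y1 <- design$y1[idx]
  e$y2 <- design$y2[idx]
  e$w <- design$weights[idx]
  e$w <- e$w / mean(e$w)
  e$n <- length(idx)
  e$cluster <- design$cluster_ids[idx]
  e$unif <- halton_raw(n_draws, 3L)
  e$shift <- design_shifts(design, seed)[idx, , drop = FALSE]
  e$mode <- mode
  e$selection <- selection
  e$k1 <- if (selection) ncol(e$X1) else 0L
  e$k2 <- ncol(e$X2)
  e$n_eval <- 0L
  e
}

# per-observation log-probs at packed theta; NULL if infeasible covariance
env_logprobs <- function(e, theta, s1_shift = 0, eta_shift = c(0, 0, 0)) {
  if (e$selection) {
    p <- theta_unpack(theta, e$k1, e$k2, e$mode)
    s1 <- as.numeric(e$X1 %*% p$beta1) + s1_shift
    rho <- p$rho
  } else {
    # outcome-only pilot: iid error structure, no selection correlation
    p <- list(beta2 = matrix(theta, e$k2, 3), omega = iid_omega())
    s1 <- numeric(length(e$y1))
    rho <- c(0, 0, 0)
  }
  eta <- e$X2 %*% p$beta2
  if (any(eta_shift != 0)) eta <- sweep(eta, 2L, eta_shift, "+")
  chols <- mnp_chols(rho, p$omega, e$selection)
  if (is.null(chols)) return(NULL)
  e$n_eval <- e$n_eval + 1L
  index_logprobs(s1, eta, if (e$selection) e$y1 else rep(1L, length(e$y2)),
                 e$y2, chols, e$unif, e$shift, e$selection)
}

# Objective on the weight-sum-normalised scale (divided by n): exactly
# invariant under splitting a row's weight across identical copies, so the
# optimiser path does not depend on such reweightings.  The reported
# log-likelihood is this value times n (mean-1-weight scale).
env_negloglik <- function(e, theta) {
  lp <- env_logprobs(e, theta)
  if (is.null(lp)) return(1e10)   # infeasible covariance: penalty
  -sum(e$w * lp) / e$n
}

# Per-observation derivatives of log p w.r.t. the reduced indices at common
# draws; columns: s1 (if selection), eta2, eta3, eta4.  Central differences
# for the final score matrix; forward differences (against a shared baseline)
# inside the optimiser, where they cost half as much and the O(h) error is
# far below the curvature scale.
env_index_scores <- function(e, theta, order = c("central", "forward")) {
  order <- match.arg(order)
  cols <- list()
  base <- if (order == "forward") env_logprobs(e, theta) else NULL
  diffq <- function(up, dn) {
    if (order == "forward") (up - base) / fd_h else (up - dn) / (2 * fd_h)
  }
  if (e$selection) {
    up <- env_logprobs(e, theta, s1_shift = fd_h)
    dn <- if (order == "central") env_logprobs(e, theta, s1_shift = -fd_h)
    cols$s1 <- diffq(up, dn)
  }
  for (j in 1:3) {
    sh <- c(0, 0, 0); sh[j] <- fd_h
    up <- env_logprobs(e, theta, eta_shift = sh)
    dn <- if (order == "central") env_logprobs(e, theta, eta_shift = -sh)
    cols[[paste0("eta", j + 1)]] <- diffq(up, dn)
  }
  cols
}

# Per-observation derivatives w.r.t. the free error-structure parameters.
env_error_scores <- function(e, theta, order = c("central", "forward")) {
  order <- match.arg(order)
  if (!e$selection) return(NULL)
  p <- length(theta)
  np <- n_error_params(e$mode)
  base <- if (order == "forward") env_logprobs(e, theta) else NULL
  out <- matrix(0, length(e$y1), np)
  for (k in seq_len(np)) {
    i <- p - np + k
    h <- fd_h
    repeat {   # shrink the step when a bump leaves the feasible region
      tp <- theta; tp[i] <- tp[i] + h
      up <- env_logprobs(e, tp)
      if (order == "forward") {
        if (!is.null(up)) { out[, k] <- (up - base) / h; break }
      } else {
        tm <- theta; tm[i] <- tm[i] - h
        dn <- env_logprobs(e, tm)
        if (!is.null(up) && !is.null(dn)) {
          out[, k] <- (up - dn) / (2 * h)
          break
        }
      }
      h <- h / 10
      if (h < fd_h / 1000) break
    }
  }
  out
}

# Full score matrix (n x p): chain the reduced index scores through the
# covariate rows.
env_scores <- function(e, theta, order = "central") {
  isc <- env_index_scores(e, theta, order)
  blocks <- list()
  if (e$selection) blocks$beta1 <- e$X1 * isc$s1
  for (j in 1:3)
    blocks[[paste0("beta2_", j + 1)]] <- e$X2 * isc[[paste0("eta", j + 1)]]
  S <- do.call(cbind, blocks)
  if (e$selection) S <- cbind(S, env_error_scores(e, theta, order))
  S
}

env_gradient <- function(e, theta, order = "forward") {
  S <- env_scores(e, theta, order)
  -as.numeric(crossprod(S, e$w)) / e$n
}
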