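# Maximum simulated likelihood estimation with pilot starting values and
# cluster-robust weighted sandwich variance.

#' Fit the panel multinomial probit with sample selection
#'
#' Maximum simulated likelihood.  Starting values come from pilot fits: a
#' weighted univariate probit for the selection equation and an independent
#' multinomial probit (iid error structure, zero selection correlation) for
#' the outcome equation, itself warm-started from a scaled multinomial logit.
#' The joint weighted log-likelihood is then maximised by BFGS with common
#' random numbers; the robust variance is the cluster sandwich
#' \eqn{A^{-1} B A^{-1}} with clusters equal to individuals.
#'
#' Weights are normalised to mean 1 before fitting (invariant for the
#' estimates, keeps log-likelihood magnitudes comparable).
#'
#' @param design a [build_design()] result.
#' @param n_draws GHK draws per observation for the joint fit.
#' @param seed integer seed for the Halton shifts.
#' @param mode \code{"iid"} fixes the differenced-error covariance at the iid
#'   structure and estimates only the three selection correlations;
#'   \code{"unrestricted"} additionally estimates the free Cholesky entries
#'   of the differenced covariance (weakly identified without
#'   alternative-specific regressors).
#' @param pilot_draws GHK draws for the outcome-equation pilot.
#' @param maxit,reltol BFGS iteration cap and relative tolerance.
#' @param abstol absolute stopping rule: quit when a 20-iteration BFGS cycle
#'   improves the log-likelihood by less than this (log-points); movements at
#'   that scale are below the simulation noise of the GHK likelihood.
#' @param hessian \code{"bhhh"} (weighted outer product of scores, the
#'   default) or \code{"numeric"} (finite-difference Hessian of the gradient;
#'   p extra gradient passes).
#' @param start optional [selmnp_params()] overriding the pilot start.
#' @param rho_prestage optimise the three selection correlations alone before
#'   the full quasi-Newton stage (cheap, and the pilots already sit near the
#'   factorised optimum in the coefficients).
#' @param fix_rho optional length-3 vector: hold the selection correlations
#'   fixed at these values instead of estimating them (iid mode only).  At
#'   \code{c(0, 0, 0)} the joint likelihood factorises exactly into the
#'   selection probit and the outcome-equation multinomial probit.
#' @param bic_n \code{"obs"} (default) or \code{"individuals"}: the n used in
#'   the BIC penalty.
#' @param verbose print optimiser progress.
#' @return an object of class \code{selmnp_fit}.
#' @export
fit_selmnp <- function(design, n_draws = 200, seed = 1L,
                       mode = c("iid", "unrestricted"),
                       pilot_draws = max(100, n_draws / 2), maxit = 200L,
                       reltol = 1e-7, abstol = 0.05,
                       hessian = c("bhhh", "numeric"),
                       start = NULL, bic_n = c("obs", "individuals"),
                       rho_prestage = TRUE, fix_rho = NULL, verbose = FALSE) {
  stopifnot(inherits(design, "selmnp_design"))
  mode <- match.arg(mode)
  hessian <- match.arg(hessian)
  bic_n <- match.arg(bic_n)
  if (sum(design$y1 == 1L) == 0L)
    stop("no needs observations: the conditional equation is unidentifiable",
         call. = FALSE)
  if (length(unique(design$y2[design$y1 == 1L])) < 2L)
    stop("outcome variation required within the needs group", call. = FALSE)

  w <- design$weights / mean(design$weights)
  k1 <- ncol(design$X1); k2 <- ncol(design$X2)

  # --- pilot fits -------------------------------------------------------------
  pilot_probit <- fit_pilot_probit(design$X1, design$y1, w)
  pilot_mnp <- fit_pilot_mnp(design, n_draws = pilot_draws, seed = seed,
                             maxit = maxit, reltol = reltol, abstol = abstol,
                             verbose = verbose)

  # --- joint fit --------------------------------------------------------------
  e <- msl_env(design, n_draws, seed, mode, selection = TRUE)
  if (is.null(start)) {
    theta0 <- theta_pack(pilot_probit$coef, pilot_mnp$beta2, c(0, 0, 0),
                         iid_omega(), mode)
  } else {
    theta0 <- theta_pack(align_coef(start$beta1, colnames(design$X1), "beta1"),
                         align_coef_mat(start$beta2, colnames(design$X2)),
                         start$rho, start$omega, mode)
  }
  nb <- k1 + 3 * k2
  if (!is.null(fix_rho)) {
    stopifnot(mode == "iid", length(fix_rho) == 3L, all(abs(fix_rho) < 1))
    theta0[nb + 1:3] <- atanh(fix_rho)
    rho_prestage <- FALSE
  }
  # stage 1: move the cross-equation correlations alone (3 cheap parameters)
  # before releasing all coefficients -- the pilots already sit near the
  # factorised optimum, so most of the remaining movement is in rho
  if (rho_prestage && is.null(start)) {
    beta_part <- theta0[seq_len(nb)]
    zopt <- stats::optim(theta0[nb + 1:3],
                         fn = function(z)
                           env_negloglik(e, c(beta_part, z,
                                              theta0[-seq_len(nb + 3)])),
                         method = "BFGS",
                         control = list(maxit = 30L, reltol = 1e-6))
    theta0[nb + 1:3] <- zopt$par
  }

  # parameter scaling: coefficient curvature is proportional to the squared
  # column dispersion, so optimise on a standardised scale
  ps <- c(1 / col_scale(design$X1), rep(1 / col_scale(design$X2), 3),
          rep(1, n_error_params(mode)))
  if (is.null(fix_rho)) {
    opt <- run_bfgs(theta0, fn = function(th) env_negloglik(e, th),
                    gr = function(th) env_gradient(e, th), ps = ps,
                    maxit = maxit, reltol = reltol, abstol = abstol / e$n,
                    trace = as.integer(verbose))
    theta <- opt$par
  } else {
    zfix <- theta0[nb + 1:3]
    opt <- run_bfgs(theta0[seq_len(nb)],
                    fn = function(th) env_negloglik(e, c(th, zfix)),
                    gr = function(th) env_gradient(e, c(th, zfix))[seq_len(nb)],
                    ps = ps[seq_len(nb)],
                    maxit = maxit, reltol = reltol, abstol = abstol / e$n,
                    trace = as.integer(verbose))
    theta <- c(opt$par, zfix)
  }
  grad <- env_gradient(e, theta)
  converged <- opt$convergence == 0L

  up <- theta_unpack(theta, k1, k2, mode)
  beta1 <- stats::setNames(up$beta1, colnames(design$X1))
  beta2 <- up$beta2
  dimnames(beta2) <- list(colnames(design$X2),
                          c("financial", "time", "lack"))
  params <- selmnp_params(beta1, beta2, up$rho, up$omega)

  # --- robust variance --------------------------------------------------------
  free_idx <- if (is.null(fix_rho)) seq_along(theta) else seq_len(nb)
  S <- env_scores(e, theta)[, free_idx, drop = FALSE]
  A <- if (hessian == "bhhh") crossprod(S, S * e$w) else
    numeric_hessian(e, theta)[free_idx, free_idx]
  V0 <- sandwich_vcov(S, A, e$cluster, e$w)
  V <- matrix(0, length(theta), length(theta))
  V[free_idx, free_idx] <- V0
  pn <- free_param_names(design, mode)
  dimnames(V) <- list(pn, pn)

  loglik <- -opt$value * e$n
  kfree <- length(free_idx)
  n_ic <- if (bic_n == "obs") design$n_obs else design$n_individuals
  ic <- information_criteria(loglik, kfree, n_ic)

  fit <- structure(list(
    estimates = params, vcov_robust = V, loglik = loglik,
    n_obs = design$n_obs, n_individuals = design$n_individuals,
    converged = converged,
    gradient_norm = sqrt(sum(((grad * ps)[free_idx])^2)),
    n_draws = n_draws, seed = seed, mode = mode,
    aic = ic$aic, bic = ic$bic, k_free = kfree,
    theta = theta, design_colnames = list(eq1 = colnames(design$X1),
                                          eq2 = colnames(design$X2)),
    pilot = list(probit = pilot_probit$coef, mnp = pilot_mnp$beta2),
    spec = design$spec,
    n_likelihood_evals = e$n_eval), class = "selmnp_fit")
  fit$table <- fit_table(fit)
  fit
}

fit_pilot_probit <- function(X1, y1, w) {
  fit <- suppressWarnings(
    stats::glm.fit(X1, y1, weights = w,
                   family = stats::binomial(link = "probit")))
  if (!fit$converged || any(abs(fit$coefficients) > 12))
    stop("pilot probit did not converge (possible separation)", call. = FALSE)
  mu <- fit$fitted.values
  if (all(mu > 1 - 1e-12) || all(mu < 1e-12))
    stop("separation detected in the pilot probit", call. = FALSE)
  list(coef = stats::setNames(fit$coefficients, colnames(X1)))
}

#' Pilot independent multinomial probit (no selection correlation)
#'
#' MSL fit of the outcome equation alone on the needs subsample, iid error
#' structure, warm-started from a multinomial logit scaled by
#' \eqn{\sqrt{2 / (\pi^2/3)}} (the ratio of differenced-error standard
#' deviations).  Used for starting values and as the factorisation benchmark
#' when the selection correlations are zero.
#'
#' @inheritParams fit_selmnp
#' @return list with \code{beta2} (k2 x 3) and \code{loglik}.
#' @export
fit_pilot_mnp <- function(design, n_draws = 100, seed = 1L, maxit = 200L,
                          reltol = 1e-7, abstol = 0.05, verbose = FALSE) {
  idx <- which(design$y1 == 1L)
  if (!length(idx)) stop("no needs observations", call. = FALSE)
  X2 <- design$X2[idx, , drop = FALSE]
  y2 <- factor(design$y2[idx], levels = 1:4)
  w <- design$weights[idx]; w <- w / mean(w)
  k2 <- ncol(X2)

  mnl <- nnet::multinom(y2 ~ X2 - 1, weights = w, trace = FALSE,
                        maxit = 300L, MaxNWts = 5000L)
  b0 <- t(stats::coef(mnl)) * sqrt(2 / (pi^2 / 3))   # k2 x 3

  e <- msl_env(design, n_draws, seed, mode = "iid", selection = FALSE,
               subset = idx)
  ps <- rep(1 / col_scale(X2), 3)
  opt <- run_bfgs(as.numeric(b0),
                  fn = function(th) env_negloglik(e, th),
                  gr = function(th) env_gradient(e, th), ps = ps,
                  maxit = maxit, reltol = reltol, abstol = abstol / e$n,
                  trace = as.integer(verbose))
  beta2 <- matrix(opt$par, k2, 3)
  dimnames(beta2) <- list(colnames(X2), c("financial", "time", "lack"))
  list(beta2 = beta2, loglik = -opt$value * e$n,
       converged = opt$convergence == 0L)
}

# Quasi-Newton driver for the simulated likelihood: BFGS in cycles of 20
# iterations, stopping when the optimiser itself reports convergence or when
# a full cycle improves the objective by less than `abstol` -- movements at
# that scale sit below the GHK simulation noise and carry no information
# about the estimates.
run_bfgs <- function(par, fn, gr, ps, maxit, reltol, abstol, chunk = 20L,
                     trace = 0L) {
  chunk <- min(chunk, maxit)
  val_prev <- fn(par)
  val <- val_prev
  convergence <- 1L
  for (cycle in seq_len(max(1L, ceiling(maxit / chunk)))) {
    opt <- stats::optim(par, fn, gr, method = "BFGS",
                        control = list(maxit = chunk, reltol = reltol,
                                       parscale = ps, trace = trace,
                                       REPORT = 1L))
    par <- opt$par
    val <- opt$value
    if (opt$convergence == 0L || val_prev - val < abstol) {
      convergence <- 0L
      break
    }
    val_prev <- val
  }
  list(par = par, value = val, convergence = convergence)
}

# per-column dispersion used for optimiser scaling (intercepts -> 1);
# population form so it is invariant to duplicating rows
col_scale <- function(X) {
  s <- apply(X, 2L, function(v) sqrt(mean((v - mean(v))^2)))
  ifelse(s < 1e-12, 1, s)
}

numeric_hessian <- function(e, theta) {
  p <- length(theta)
  H <- matrix(0, p, p)
  h <- 1e-4
  for (k in seq_len(p)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    H[, k] <- (env_gradient(e, tp) - env_gradient(e, tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

free_param_names <- function(design, mode) {
  nm <- c(paste0("needs:", colnames(design$X1)),
          paste0(rep(c("financial:", "time:", "lack:"),
                     each = ncol(design$X2)), colnames(design$X2)),
          paste0("atanh_rho_", 2:4))
  if (mode == "unrestricted")
    nm <- c(nm, paste0("omega_l", c("21", "22", "31", "32", "33")))
  nm
}

#' Cluster-robust weighted sandwich variance
#'
#' \eqn{A^{-1} B A^{-1}} where \code{A} is (minus) the Hessian of the
#' weighted log-likelihood (or its BHHH approximation) and
#' \eqn{B = \sum_c g_c g_c'} with \eqn{g_c} the within-cluster sum of
#' weighted per-observation scores.  With one observation per cluster and
#' unit weights this reduces to the standard heteroskedasticity-robust form.
#'
#' @param scores n x p matrix of per-observation score contributions
#'   (derivatives of the unweighted log-probabilities).
#' @param hessian p x p matrix: minus the Hessian of the weighted
#'   log-likelihood, or an approximation of it.
#' @param cluster_ids length-n cluster labels (individuals).
#' @param weights length-n positive weights.
#' @return symmetric p x p covariance matrix.
#' @export
sandwich_vcov <- function(scores, hessian, cluster_ids, weights) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(cluster_ids) == n, length(weights) == n)
  ws <- scores * weights
  G <- rowsum(ws, group = cluster_ids, reorder = FALSE)
  B <- crossprod(G)
  Ainv <- tryCatch(solve(hessian), error = function(err) {
    warning("singular Hessian approximation; using pseudo-inverse")
    pseudo_inverse(hessian)
  })
  V <- Ainv %*% B %*% t(Ainv)
  (V + t(V)) / 2
}

pseudo_inverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Coefficient table on the reporting scale (age terms x10 / x1000).
fit_table <- function(fit) {
  info <- term_info()
  disp_scale <- function(cols) {
    s <- rep(1, length(cols))
    m <- match(cols, info$term)
    s[!is.na(m)] <- info$scale[m[!is.na(m)]]
    s
  }
  eqs <- c("needs", "financial", "time", "lack")
  cn1 <- fit$design_colnames$eq1
  cn2 <- fit$design_colnames$eq2
  est <- c(fit$estimates$beta1, as.numeric(fit$estimates$beta2))
  terms <- c(cn1, rep(cn2, 3))
  equation <- c(rep("needs", length(cn1)), rep(eqs[-1], each = length(cn2)))
  scale <- c(disp_scale(cn1), rep(disp_scale(cn2), 3))
  se <- sqrt(pmax(diag(fit$vcov_robust), 0))[seq_along(est)]
  # selection correlations, delta method through tanh
  nz <- n_error_params(fit$mode)
  zeta_idx <- length(est) + 1:3
  zeta <- fit$theta[zeta_idx]
  rho <- tanh(zeta)
  se_z <- sqrt(pmax(diag(fit$vcov_robust), 0))[zeta_idx]
  se_rho <- se_z * (1 - rho^2)
  se_rho[se_z == 0] <- NA_real_   # held fixed, not estimated
  tab <- data.frame(
    equation = c(equation, rep("error structure", 3)),
    term = c(terms, paste0("rho_", c("financial", "time", "lack"))),
    estimate = c(est * scale, rho),
    se = c(se * scale, se_rho),
    stringsAsFactors = FALSE)
  tab$z <- tab$estimate / tab$se
  tab$p_value <- 2 * stats::pnorm(-abs(tab$z))
  tab
}

#' Information criteria
#'
#' \eqn{AIC = -2\ell + 2k}, \eqn{BIC = -2\ell + k\log n}.
#'
#' @param loglik log-likelihood at the optimum.
#' @param k number of free parameters (>= 1).
#' @param n effective sample size for the BIC penalty.
#' @return list with \code{aic} and \code{bic}.
#' @export
information_criteria <- function(loglik, k, n) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  list(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n))
}

#' @export
print.selmnp_fit <- function(x, ...) {
  cat("Panel multinomial probit with sample selection (", x$mode,
      " error structure)\n", sep = "")
  cat("  ", x$n_obs, " observations, ", x$n_individuals, " individuals; ",
      x$n_draws, " GHK draws, seed ", x$seed, "\n", sep = "")
  cat("  log-likelihood ", format(x$loglik, digits = 8), ", AIC ",
      format(x$aic, digits = 8), ", BIC ", format(x$bic, digits = 8),
      "\n", sep = "")
  cat("  converged: ", x$converged, " (|gradient| = ",
      format(x$gradient_norm, digits = 3), ")\n", sep = "")
  cat("  rho: ", paste(format(x$estimates$rho, digits = 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.selmnp_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficients (age terms on the x10 / x1000 reporting scale):\n")
  tab <- object$table
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$z <- round(tab$z, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.selmnp_fit <- function(object, ...) {
  stats::setNames(object$theta,
                  c(paste0("needs:", object$design_colnames$eq1),
                    paste0(rep(c("financial:", "time:", "lack:"),
                               each = length(object$design_colnames$eq2)),
                           object$design_colnames$eq2),
                    paste0("atanh_rho_", 2:4),
                    if (object$mode == "unrestricted")
                      paste0("omega_l", c("21", "22", "31", "32", "33"))))
}

#' @export
vcov.selmnp_fit <- function(object, ...) object$vcov_robust

#' @export
logLik.selmnp_fit <- function(object, ...) {
  structure(object$loglik, df = object$k_free, class = "logLik")
}

#' Export a fitted model as flat tables
#'
#' Writes (a) the per-term coefficient table (term, equation, estimate on the
#' reporting scale, robust SE, z, p) and (b) a key-value summary with
#' log-likelihood, information criteria and convergence metadata.
#'
#' @param fit a [fit_selmnp()] result.
#' @param dir output directory.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$table, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  meta <- c(loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
            k_free = fit$k_free, n_obs = fit$n_obs,
            n_individuals = fit$n_individuals, n_draws = fit$n_draws,
            seed = fit$seed, converged = as.numeric(fit$converged),
            gradient_norm = fit$gradient_norm)
  utils::write.table(data.frame(key = names(meta), value = unname(meta)),
                     file.path(dir, "fit_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
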