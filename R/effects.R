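# Average adjusted probabilities (AAP) over an age-by-gender grid.

#' Average adjusted probabilities across age by gender
#'
#' For each grid point (gender g, age a), every observation's gender and age
#' -- and all terms derived from them (centred age, quadratics, gender
#' interactions) -- are overwritten with (g, a) while the remaining
#' covariates keep their observed values; the weighted average of the
#' predicted probabilities is the AAP.  Reported columns: probability of
#' experiencing healthcare needs, of unmet needs in total, and of each
#' barrier (financial difficulty, time constraint, lack of caring and
#' support).  With \code{type = "joint"} the barrier columns are the joint
#' probabilities \eqn{P(y_1 = 1, y_2 = j)}, which sum to the unmet total;
#' with \code{type = "conditional"} they are conditional on experiencing
#' needs.  95% confidence intervals use the delta method: the numerical
#' Jacobian of each AAP with respect to the free parameters (finite
#' differences in the reduced index space) times the robust covariance.
#'
#' @param fit a [fit_selmnp()] result.
#' @param coded_data the estimation sample (coded outcomes + covariates).
#' @param ages grid of ages (default 20 to 90 by 5).
#' @param type joint (default) or conditional barrier probabilities.
#' @param ci compute delta-method confidence intervals.
#' @param n_draws,seed GHK controls; default to those of the fit.
#' @param age_range plausible age range; grid points outside it draw a
#'   warning but are computed.
#' @return data frame of class \code{selmnp_aap}: one row per gender x age
#'   with point values and (if requested) CI bounds.
#' @export
average_adjusted_probability <- function(fit, coded_data,
                                         ages = seq(20, 90, by = 5),
                                         type = c("joint", "conditional"),
                                         ci = TRUE,
                                         n_draws = fit$n_draws,
                                         seed = fit$seed,
                                         age_range = c(15, 100)) {
  stopifnot(inherits(fit, "selmnp_fit"))
  type <- match.arg(type)
  if (!fit$converged)
    warning("fit is not flagged as converged; AAP may be unreliable")
  if (any(ages < age_range[1] | ages > age_range[2]))
    warning("grid ages outside the plausible range [", age_range[1], ", ",
            age_range[2], "]")
  spec <- fit$spec
  w <- coded_data$weight / mean(coded_data$weight)
  unif <- halton_raw(n_draws, 3L)
  shift <- design_shifts(build_design(coded_data, spec), seed)
  params <- fit$estimates
  chols <- mnp_chols(params$rho, params$omega, selection = TRUE)

  grid <- expand.grid(man = c(1, 0), age = ages)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pt <- aap_point(params, chols, unif, shift, coded_data, spec, w,
                    man = grid$man[i], age = grid$age[i], type = type)
    row <- data.frame(gender = if (grid$man[i] == 1) "man" else "woman",
                      age = grid$age[i], t(pt$aap))
    if (ci) {
      jac <- aap_jacobian(fit, coded_data, spec, w, unif, shift,
                          man = grid$man[i], age = grid$age[i], type = type)
      se <- sqrt(pmax(rowSums((jac %*% fit$vcov_robust) * jac), 0))
      row[paste0(names(pt$aap), "_lo")] <- pmax(pt$aap - 1.96 * se, 0)
      row[paste0(names(pt$aap), "_hi")] <- pmin(pt$aap + 1.96 * se, 1)
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gender, out$age), ]
  rownames(out) <- NULL
  structure(out, class = c("selmnp_aap", "data.frame"), type = type)
}

# Predicted-probability columns at one grid point; returns the weighted AAP
# vector and (optionally) the per-observation probability matrix.
aap_point <- function(params, chols, unif, shift, coded_data, spec, w, man,
                      age, type, keep_obs = FALSE,
                      s1_shift = 0, eta_shift = c(0, 0, 0)) {
  dat <- coded_data
  dat$man <- man
  dat$age <- age
  age_c <- dat$age - spec$age_center
  X1 <- build_matrix(spec$eq1_terms, dat, age_c, check = FALSE)
  X2 <- build_matrix(spec$eq2_terms, dat, age_c, check = FALSE)
  s1 <- as.numeric(X1 %*% align_coef(params$beta1, colnames(X1), "beta1")) +
    s1_shift
  eta <- X2 %*% align_coef_mat(params$beta2, colnames(X2))
  if (any(eta_shift != 0)) eta <- sweep(eta, 2L, eta_shift, "+")
  pj <- selmnp_probs_cpp(s1, eta, chols, unif, shift, TRUE)
  p_needs <- stats::pnorm(s1)
  if (type == "conditional") {
    barrier <- pj[, 2:4, drop = FALSE] / pmax(rowSums(pj), 1e-300) # P(j | y1=1)
  } else {
    barrier <- pj[, 2:4, drop = FALSE]
  }
  obs <- cbind(p_needs = p_needs,
               p_unmet_total = rowSums(barrier),
               p_financial = barrier[, 1], p_time = barrier[, 2],
               p_lack = barrier[, 3])
  aap <- as.numeric(crossprod(obs, w) / sum(w))
  names(aap) <- colnames(obs)
  if (keep_obs) list(aap = aap, obs = obs) else list(aap = aap)
}

# Jacobian of the 5 AAP columns w.r.t. the free parameters, using central
# differences in the reduced index space chained through the covariate rows.
aap_jacobian <- function(fit, coded_data, spec, w, unif, shift, man, age,
                         type) {
  params <- fit$estimates
  chols <- mnp_chols(params$rho, params$omega, selection = TRUE)
  dat <- coded_data
  dat$man <- man
  dat$age <- age
  age_c <- dat$age - spec$age_center
  X1 <- build_matrix(spec$eq1_terms, dat, age_c, check = FALSE)
  X2 <- build_matrix(spec$eq2_terms, dat, age_c, check = FALSE)
  h <- fd_h
  ww <- w / sum(w)

  point <- function(s1s = 0, es = c(0, 0, 0), par = params, ch = chols)
    aap_point(par, ch, unif, shift, coded_data, spec, w, man, age, type,
              keep_obs = TRUE, s1_shift = s1s, eta_shift = es)$obs

  # d obs / d s1 and d obs / d eta_j, per observation
  d_s1 <- (point(s1s = h) - point(s1s = -h)) / (2 * h)
  d_eta <- lapply(1:3, function(j) {
    sh <- c(0, 0, 0); sh[j] <- h
    (point(es = sh) - point(es = -sh)) / (2 * h)
  })
  k1 <- ncol(X1); k2 <- ncol(X2)
  ncolumns <- 5L
  p_free <- length(fit$theta)
  J <- matrix(0, ncolumns, p_free)
  for (cc in seq_len(ncolumns)) {
    g1 <- as.numeric(crossprod(X1, ww * d_s1[, cc]))
    g2 <- unlist(lapply(1:3, function(j)
      as.numeric(crossprod(X2, ww * d_eta[[j]][, cc]))))
    J[cc, seq_len(k1)] <- g1
    J[cc, k1 + seq_len(3 * k2)] <- g2
  }
  # error-structure parameters by direct bumps
  np <- n_error_params(fit$mode)
  for (k in seq_len(np)) {
    i <- p_free - np + k
    tp <- fit$theta; tp[i] <- tp[i] + h
    tm <- fit$theta; tm[i] <- tm[i] - h
    pu <- theta_unpack(tp, k1, k2, fit$mode)
    pd <- theta_unpack(tm, k1, k2, fit$mode)
    chu <- mnp_chols(pu$rho, pu$omega, TRUE)
    chd <- mnp_chols(pd$rho, pd$omega, TRUE)
    if (is.null(chu) || is.null(chd)) next
    paru <- params; paru$rho <- pu$rho; paru$omega <- pu$omega
    pard <- params; pard$rho <- pd$rho; pard$omega <- pd$omega
    du <- aap_point(paru, chu, unif, shift, coded_data, spec, w, man, age,
                    type, keep_obs = FALSE)$aap
    dd <- aap_point(pard, chd, unif, shift, coded_data, spec, w, man, age,
                    type, keep_obs = FALSE)$aap
    J[, i] <- (du - dd) / (2 * h)
  }
  J
}

#' @export
print.selmnp_aap <- function(x, ...) {
  cat("Average adjusted probabilities (", attr(x, "type"),
      " barrier probabilities), ", nrow(x), " grid points\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Plot AAP trajectories
#'
#' Two standard displays: the needs probability across age by gender, and the
#' three barrier probabilities across age, one panel per gender.
#'
#' @param aap an [average_adjusted_probability()] result.
#' @param which \code{"needs"} or \code{"barriers"}.
#' @return a ggplot object.
#' @export
plot_aap <- function(aap, which = c("needs", "barriers")) {
  which <- match.arg(which)
  df <- as.data.frame(aap)
  has_ci <- "p_needs_lo" %in% names(df)
  if (which == "needs") {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = age, y = p_needs,
                                          colour = gender))
    if (has_ci)
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = p_needs_lo, ymax = p_needs_hi,
                     fill = gender), alpha = 0.2, colour = NA)
    p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "Age (years)",
                    y = "P(experiencing healthcare needs)",
                    title = "Average adjusted probability of healthcare needs")
  } else {
    long <- do.call(rbind, lapply(c("p_financial", "p_time", "p_lack"),
      function(v) {
        d <- df[c("gender", "age", v,
                  if (has_ci) paste0(v, c("_lo", "_hi")))]
        names(d) <- c("gender", "age", "p", if (has_ci) c("lo", "hi"))
        d$barrier <- c(p_financial = "financial difficulty",
                       p_time = "time constraint",
                       p_lack = "lack of caring and support")[v]
        d
      }))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = age, y = p,
                                            colour = barrier))
    if (has_ci)
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = lo, ymax = hi, fill = barrier),
        alpha = 0.2, colour = NA)
    p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::facet_wrap(~gender) +
      ggplot2::labs(x = "Age (years)", y = "Probability",
                    title = "Barriers leading to unmet healthcare needs")
  }
}

#' Write an AAP grid as delimited text
#' @param aap an [average_adjusted_probability()] result.
#' @param path file path.
#' @export
write_aap <- function(aap, path) {
  utils::write.csv(as.data.frame(aap), path, row.names = FALSE)
  invisible(path)
}
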