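# Parameter container for the two-equation selection system and the
# linear-algebra reduction of the four-alternative choice problem to
# differenced utilities.

#' Parameter vector of the selection multinomial probit
#'
#' Collects the coefficients and error-structure parameters of the
#' two-equation system: a binary selection equation
#' \eqn{y_1 = 1\{x_1'\beta_1 + \epsilon_1 > 0\}} with \eqn{Var(\epsilon_1)=1},
#' and a four-alternative outcome equation with latent utilities
#' \eqn{y^*_{2j} = x_2'\beta_{2j} + \epsilon_{2j}} observed only when
#' \eqn{y_1 = 1}.  Alternative 1 (met needs) is the reference:
#' \eqn{\beta_{21} \equiv 0}.  The error structure is expressed on the
#' differenced scale \eqn{u_j = \epsilon_{2j} - \epsilon_{21}} (j = 2, 3, 4)
#' with covariance \code{omega}; the scale normalisation fixes
#' \code{omega[1,1] = 2}, the value implied by iid standard-normal
#' alternative-level errors.  \code{rho[j]} is the correlation between the
#' selection error and \eqn{u_{j+1}}.
#'
#' @param beta1 numeric vector, selection-equation coefficients.
#' @param beta2 numeric matrix with 3 columns (alternatives 2, 3, 4).
#' @param rho length-3 vector of cross-equation correlations, each in (-1, 1).
#' @param omega 3x3 covariance of the differenced outcome errors; default is
#'   the iid structure (2 on the diagonal, 1 off it).
#' @return an object of class \code{selmnp_params}.
#' @export
selmnp_params <- function(beta1, beta2, rho = c(0, 0, 0), omega = NULL) {
  stopifnot(is.numeric(beta1))
  beta1 <- stats::setNames(as.numeric(beta1), names(beta1))
  beta2 <- as.matrix(beta2)
  if (ncol(beta2) != 3L)
    stop("beta2 must have 3 columns (alternatives 2, 3, 4)", call. = FALSE)
  if (length(rho) != 3L || any(abs(rho) >= 1))
    stop("rho must be 3 correlations in (-1, 1)", call. = FALSE)
  if (is.null(omega)) omega <- iid_omega()
  omega <- as.matrix(omega)
  if (!isTRUE(all.equal(omega[1, 1], 2, tolerance = 1e-10)))
    stop("omega[1,1] must equal 2 (scale normalization)", call. = FALSE)
  if (max(abs(omega - t(omega))) > 1e-10)
    stop("omega must be symmetric", call. = FALSE)
  p <- structure(list(beta1 = beta1, beta2 = beta2,
                      rho = as.numeric(rho), omega = omega),
                 class = "selmnp_params")
  sig <- joint_sigma(p)   # errors if not PD
  attr(p, "joint_sigma") <- sig
  p
}

iid_omega <- function() matrix(1, 3, 3) + diag(3)

#' @export
print.selmnp_params <- function(x, ...) {
  cat("Selection multinomial probit parameters\n")
  cat("  selection equation: ", length(x$beta1), " coefficients\n", sep = "")
  cat("  outcome equation:   ", nrow(x$beta2),
      " coefficients x 3 non-reference alternatives\n", sep = "")
  cat("  rho (sel ~ u_2..4): ", paste(format(x$rho, digits = 3), collapse = ", "),
      "\n", sep = "")
  iid <- isTRUE(all.equal(x$omega, iid_omega(), check.attributes = FALSE))
  cat("  omega: ", if (iid) "iid structure" else "unrestricted", "\n", sep = "")
  invisible(x)
}

# Joint covariance of (u_2, u_3, u_4, eps_1); errors if not PD.
joint_sigma <- function(params) {
  r <- params$rho * sqrt(diag(params$omega))
  sig <- rbind(cbind(params$omega, r), c(r, 1))
  dimnames(sig) <- NULL
  ev <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(ev))
    stop("implied joint error covariance is not positive definite",
         call. = FALSE)
  sig
}

# M_j such that alternative j is chosen iff M_j u + c_j > 0 (u = differenced
# errors).  Row convention: j = 1 -> -I; j >= 2 -> own-utility row first, then
# e_j - e_k for the other non-reference alternatives in ascending order.
# Must stay in lock-step with region_lower() in src/ghk.cpp.
region_matrix <- function(j) {
  if (j == 1L) return(-diag(3))
  jj <- j - 1L                       # index of u_j among (u_2, u_3, u_4)
  e <- diag(3)
  rows <- e[jj, , drop = FALSE]
  for (kk in setdiff(1:3, jj)) rows <- rbind(rows, e[jj, ] - e[kk, ])
  unname(rows)
}

#' Choice region of an alternative in differenced-utility space
#'
#' Reduces the argmax condition \eqn{y^*_{2j} = \max_k y^*_{2k}} to a set of
#' three linear inequalities \eqn{M_j u + c_j > 0} in the differenced errors
#' \eqn{u = (u_2, u_3, u_4)}.
#'
#' @param j alternative, 1 to 4 (1 = reference).
#' @param beta2 coefficient matrix as in [selmnp_params()].
#' @param x2 covariate vector for the outcome equation.
#' @return list with the 3x3 matrix \code{M} and offset vector \code{c}.
#' @export
alternative_region <- function(j, beta2, x2) {
  stopifnot(j %in% 1:4)
  eta <- as.numeric(crossprod(as.matrix(beta2), as.numeric(x2)))  # eta_2..4
  M <- region_matrix(j)
  if (j == 1L) {
    cc <- -eta
  } else {
    jj <- j - 1L
    cc <- c(eta[jj], eta[jj] - eta[setdiff(1:3, jj)])
  }
  list(M = M, c = cc)
}

# Cholesky factors of the per-alternative region covariances; selection = TRUE
# appends the selection error as the last GHK dimension (no draw needed there).
region_chols <- function(params, selection = TRUE) {
  sig <- attr(params, "joint_sigma")
  if (is.null(sig)) sig <- joint_sigma(params)
  omega <- sig[1:3, 1:3]
  r <- sig[1:3, 4]
  lapply(1:4, function(j) {
    M <- region_matrix(j)
    v <- M %*% omega %*% t(M)
    if (selection) {
      mr <- as.numeric(M %*% r)
      v <- rbind(cbind(v, mr), c(mr, 1))
    }
    chol_lower(v)
  })
}

#' Joint outcome probabilities for one covariate profile
#'
#' Computes \eqn{P(y_1 = 0) = \Phi(-x_1'\beta_1)} and the joint probabilities
#' \eqn{P(y_1 = 1, y_2 = j)} for the four alternatives under the full
#' correlated error structure, by GHK simulation.  The five probabilities sum
#' to one up to simulation error.
#'
#' @param params a [selmnp_params()] object.
#' @param x1,x2 covariate vectors for the two equations.
#' @param n_draws,seed GHK simulation controls.
#' @return list with \code{p_nonneeds} and \code{p_joint} (length 4).
#' @export
choice_probabilities <- function(params, x1, x2, n_draws = 500, seed = 1L) {
  s1 <- sum(as.numeric(x1) * params$beta1)
  eta <- matrix(as.numeric(crossprod(params$beta2, as.numeric(x2))), nrow = 1)
  chols <- region_chols(params, selection = TRUE)
  unif <- ghk_unif(n_draws, 3L, seed)
  pj <- selmnp_probs_cpp(s1, eta, chols, unif, matrix(0, 1, 3), TRUE)
  list(p_nonneeds = stats::pnorm(-s1), p_joint = as.numeric(pj))
}

# --- flat text serialization -------------------------------------------------

#' Write / read a parameter vector as flat name-value text
#'
#' @param params a [selmnp_params()] object.
#' @param path file path.
#' @return \code{read_params} returns a [selmnp_params()] object.
#' @export
write_params <- function(params, path) {
  k2 <- nrow(params$beta2)
  nm2 <- rownames(params$beta2)
  if (is.null(nm2)) nm2 <- paste0("x", seq_len(k2))
  nm1 <- names(params$beta1)
  if (is.null(nm1)) nm1 <- paste0("x", seq_along(params$beta1))
  rows <- rbind(
    data.frame(name = paste0("beta1.", nm1), value = params$beta1),
    data.frame(name = paste0("beta2.", rep(2:4, each = k2), ".", rep(nm2, 3)),
               value = as.numeric(params$beta2)),
    data.frame(name = paste0("rho.", 2:4), value = params$rho),
    data.frame(name = paste0("omega.", rep(1:3, 3), ".", rep(1:3, each = 3)),
               value = as.numeric(params$omega)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  get_block <- function(prefix) tab[startsWith(tab$name, prefix), , drop = FALSE]
  b1 <- get_block("beta1.")
  beta1 <- stats::setNames(b1$value, sub("^beta1\\.", "", b1$name))
  b2 <- get_block("beta2.")
  k2 <- nrow(b2) / 3L
  beta2 <- matrix(b2$value, nrow = k2, ncol = 3)
  rownames(beta2) <- sub("^beta2\\.2\\.", "", b2$name[seq_len(k2)])
  rho <- get_block("rho.")$value
  om <- get_block("omega.")
  omega <- matrix(om$value, 3, 3)
  selmnp_params(beta1, beta2, rho, omega)
}
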