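# Quasi-random draws and multivariate-normal rectangle probabilities.

halton_bases <- c(2L, 3L, 5L, 7L)

radical_inverse <- function(idx, base) {
  r <- numeric(length(idx))
  f <- 1 / base
  while (any(idx > 0L)) {
    r <- r + f * (idx %% base)
    idx <- idx %/% base
    f <- f / base
  }
  r
}

# Evaluate expr with a private RNG stream, leaving the global seed untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Shifted Halton sequence
#'
#' Low-discrepancy uniforms used by the GHK simulator.  The raw Halton points
#' (prime bases 2, 3, 5, 7; the first \code{skip} points dropped) are shifted
#' modulo 1 by a uniform offset drawn from \code{seed}, so that different
#' seeds give different (but internally deterministic) draw sets -- the common
#' random numbers that keep the simulated likelihood smooth across parameter
#' evaluations.
#'
#' @param n number of points.
#' @param dims number of coordinates (at most 4).
#' @param seed integer seed controlling the random shift.
#' @param skip leading points of the raw sequence to drop.
#' @return an \code{n} by \code{dims} matrix of values in (0, 1).
#' @export
halton_sequence <- function(n, dims, seed = 1L, skip = 10L) {
  stopifnot(dims >= 1L, dims <= length(halton_bases), n >= 1L)
  idx <- seq.int(skip + 1L, skip + n)
  h <- vapply(halton_bases[seq_len(dims)], function(b) radical_inverse(idx, b),
              numeric(n))
  h <- matrix(h, nrow = n)
  shift <- with_local_seed(seed, stats::runif(dims))
  h <- sweep(h, 2L, shift, "+") %% 1
  pmin(pmax(h, 1e-12), 1 - 1e-12)
}

ghk_unif <- function(n_draws, dims, seed) {
  npairs <- as.integer(ceiling(n_draws / 2))
  halton_sequence(npairs, dims, seed = seed)
}

# Raw (unshifted) Halton points shared across observations.
halton_raw <- function(n_draws, dims, skip = 10L) {
  npairs <- as.integer(ceiling(n_draws / 2))
  idx <- seq.int(skip + 1L, skip + npairs)
  h <- vapply(halton_bases[seq_len(dims)], function(b) radical_inverse(idx, b),
              numeric(npairs))
  matrix(h, nrow = npairs)
}

# Per-observation random shifts (mod 1): decorrelate the simulation error
# across observations while keeping every draw set low-discrepancy and
# deterministic given the seed.
ghk_shifts <- function(n_obs, dims, seed) {
  with_local_seed(seed, matrix(stats::runif(n_obs * dims), n_obs, dims))
}

# Shifts keyed on (cluster, row content) rather than row position: rows with
# identical content within a cluster share a draw set, so reweighting
# transformations that duplicate rows (split a weight across identical
# copies) leave the simulated likelihood identical; distinct rows keep
# independent shifts.
design_shifts <- function(design, seed, dims = 3L) {
  content <- do.call(paste, c(list(design$y1, design$y2),
                              split(design$X1, col(design$X1)),
                              split(design$X2, col(design$X2)),
                              list(sep = "\r")))
  cl <- as.character(design$cluster_ids)
  groups <- split(seq_along(cl), factor(cl, levels = unique(cl)))
  shift <- matrix(0, length(cl), dims)
  with_local_seed(seed, {
    for (idx in groups) {
      key <- match(content[idx], unique(content[idx]))
      draws <- matrix(stats::runif(max(key) * dims), ncol = dims)
      shift[idx, ] <- draws[key, , drop = FALSE]
    }
  })
  shift
}

#' GHK estimate of a multivariate-normal rectangle probability
#'
#' Geweke--Hajivassiliou--Keane recursive importance sampling for
#' \eqn{P(lower < W < upper)} with \eqn{W \sim N(0, \Sigma)}, using
#' antithetically paired shifted-Halton uniforms.  Deterministic given
#' \code{(seed, n_draws)}.
#'
#' @param lower,upper bound vectors; entries may be \code{-Inf} / \code{Inf}.
#' @param sigma positive-definite covariance matrix.
#' @param n_draws total number of draws (antithetic pairs count as two).
#' @param seed integer seed for the Halton shift.
#' @return probability estimate in [0, 1].
#' @examples
#' ghk_mvn_rectangle(-Inf, 0, matrix(1), n_draws = 2)   # exactly pnorm(0)
#' @export
ghk_mvn_rectangle <- function(lower, upper, sigma, n_draws = 500, seed = 1L) {
  sigma <- as.matrix(sigma)
  d <- nrow(sigma)
  stopifnot(length(lower) == d, length(upper) == d, all(lower <= upper))
  L <- chol_lower(sigma)
  if (d == 1L) {
    # degenerate path: exact normal interval, no simulation
    s <- sqrt(sigma[1, 1])
    return(stats::pnorm(upper / s) - stats::pnorm(lower / s))
  }
  unif <- ghk_unif(n_draws, d - 1L, seed)
  ghk_rect_cpp(as.numeric(lower), as.numeric(upper), L, unif)
}

chol_lower <- function(sigma) {
  ev <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ev))
    stop("covariance matrix is not positive definite", call. = FALSE)
  t(ev)
}

#' Deterministic MVN rectangle probability by tensor quadrature
#'
#' Reference integrator for the same rectangle probabilities the GHK
#' simulator estimates: the separation-of-variables transform maps the
#' integral to the unit cube, where it is evaluated on a tensor
#' Gauss--Legendre grid.  Intended as an independent deterministic check of
#' the simulator at small dimension (d <= 4); cost grows as
#' \code{nodes^(d-1)}.
#'
#' @inheritParams ghk_mvn_rectangle
#' @param nodes Gauss--Legendre nodes per transformed coordinate.
#' @return probability estimate.
#' @export
mvn_rectangle_quadrature <- function(lower, upper, sigma, nodes = 24L) {
  sigma <- as.matrix(sigma)
  d <- nrow(sigma)
  stopifnot(length(lower) == d, length(upper) == d)
  L <- chol_lower(sigma)
  if (d == 1L)
    return(stats::pnorm(upper / L[1, 1]) - stats::pnorm(lower / L[1, 1]))
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  z <- matrix(numeric(0), nrow = 1L)   # grid of transformed draws
  wt <- 1
  prob <- 1
  for (k in seq_len(d)) {
    m <- if (k == 1L) 0 else as.numeric(z %*% L[k, seq_len(k - 1L)])
    lo <- (lower[k] - m) / L[k, k]
    hi <- (upper[k] - m) / L[k, k]
    plo <- stats::pnorm(lo)
    phi <- stats::pnorm(hi)
    pk <- pmax(phi - plo, 0)
    prob <- prob * pk
    if (k < d) {
      g <- length(pk)
      # expand the grid by one tensor coordinate
      zk <- stats::qnorm(rep(plo, each = nodes) +
                           rep(gl$x, times = g) * rep(pk, each = nodes))
      zk[!is.finite(zk)] <- 0
      z <- cbind(z[rep(seq_len(g), each = nodes), , drop = FALSE], zk)
      wt <- rep(wt, each = nodes) * rep(gl$w, times = g)
      prob <- rep(prob, each = nodes)
    }
  }
  sum(wt * prob)
}
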