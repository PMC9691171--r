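# Model diagnostics: Hosmer-Lemeshow calibration test for the selection
# equation and convenience wrappers.

#' Hosmer--Lemeshow goodness-of-fit test
#'
#' Groups observations into deciles of fitted risk and compares observed and
#' expected event counts: \eqn{\sum_g (O_g - n_g \bar p_g)^2 /
#' (n_g \bar p_g (1 - \bar p_g))}, referred to a chi-square with
#' \code{groups - 2} degrees of freedom.  Groups whose mean fitted
#' probability is exactly 0 or 1 are merged with their neighbour (noted in
#' the result).
#'
#' @param y binary outcomes (0/1).
#' @param p fitted probabilities in (0, 1).
#' @param groups number of risk groups (default 10).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{groups_used} and \code{merged}.
#' @export
hosmer_lemeshow <- function(y, p, groups = 10L) {
  stopifnot(length(y) == length(p), groups >= 2L,
            all(y %in% 0:1), all(p > 0), all(p < 1))
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1L),
                               names = FALSE))
  g <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  # merge groups whose mean fitted risk is numerically 0 or 1 into a neighbour
  merged <- FALSE
  repeat {
    pbar <- tapply(p, g, mean)
    lev <- as.integer(names(pbar))
    bad <- lev[pbar < 1e-12 | pbar > 1 - 1e-12]
    if (!length(bad) || length(lev) <= 2L) break
    k <- bad[1L]
    nb <- if (k == min(lev)) lev[which(lev > k)[1L]] else max(lev[lev < k])
    g[g == k] <- nb
    merged <- TRUE
  }
  O <- tapply(y, g, sum)
  n_g <- tapply(y, g, length)
  pbar <- tapply(p, g, mean)
  stat <- sum((O - n_g * pbar)^2 / (n_g * pbar * (1 - pbar)))
  df <- length(O) - 2L
  list(statistic = as.numeric(stat), df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       groups_used = length(O), merged = merged)
}

#' Hosmer--Lemeshow test of the selection equation
#'
#' Refits the selection equation as an unweighted univariate probit (the
#' calibration test has no survey-weighted analogue here) and applies
#' [hosmer_lemeshow()] to its fitted probabilities.
#'
#' @param design a [build_design()] result.
#' @param groups number of risk groups.
#' @return as [hosmer_lemeshow()].
#' @export
hl_first_equation <- function(design, groups = 10L) {
  fit <- suppressWarnings(
    stats::glm.fit(design$X1, design$y1,
                   family = stats::binomial(link = "probit")))
  p <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  hosmer_lemeshow(design$y1, p, groups = groups)
}
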