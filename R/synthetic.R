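# Synthetic panel generator.  Emulates the structure of the Korea Health
# Panel analysis sample: ~5 annual waves, ~2% attrition per wave, covariate
# marginals matching the pooled descriptive table, outcomes generated from
# the latent two-equation model with the published coefficient estimates as
# the default truth, positive longitudinal weights, clustering by individual.

# Pooled covariate marginals (proportions; age is mean/sd, truncated 19-95).
default_covariate_params <- function() {
  list(man = 0.462,
       age_mean = 52.753, age_sd = 17.668, age_min = 19, age_max = 95,
       unmarried = 0.324, seoul = 0.376, college = 0.316,
       occupation = c(no_job = 0.402, blue_collar = 0.404,
                      white_collar = 0.193),
       income = c(lowest = 0.200, medium = 0.601, highest = 0.199),
       mca = 0.033, private_ins = 0.715, funclim = 0.066, smoker = 0.183,
       alcohol = 0.652, exercise = 0.380, obese = 0.258, poor_health = 0.849,
       chronic = 0.630)
}

# Headline coefficient estimates, display scaling (x10 / x1000 on age terms)
# undone, used as the generating truth.  Order matches default_model_spec()
# with the intercept first.
default_truth <- function(rho = c(0.3, 0.3, 0.3)) {
  beta1 <- c("(Intercept)" = 1.930, man = -0.395, age = 0.0148,
             man_age_sq = 0.000388, woman_age_sq = 0.000114,
             unmarried = -0.294, seoul = -0.254, college = 0.064,
             occ_blue = 0.053, occ_white = 0.076, inc_medium = 0.055,
             inc_highest = 0.057, mca = 0.299, private_ins = 0.083,
             funclim = 0.437, smoker = -0.122, exercise = 0.021,
             obese = -0.036, poor_health = 0.332, chronic = 0.418)
  nm2 <- c("(Intercept)", "man", "age", "age_sq", "man_age", "man_age_sq",
           "unmarried", "seoul", "college", "occ_blue", "occ_white",
           "inc_medium", "inc_highest", "mca", "private_ins", "funclim",
           "smoker", "alcohol", "poor_health", "chronic")
  financial <- c(-2.118, 0.018, -0.0035, -0.000179, 0.0037, -0.000188,
                 0.279, 0.387, -0.225, 0.042, -0.017, -0.579, -1.178,
                 0.142, -0.152, 0.389, 0.234, 0.029, 0.634, -0.028)
  time_con <- c(-1.724, -0.064, -0.0085, -0.000192, -0.0039, -0.000257,
                0.039, 0.050, -0.051, 0.477, 0.478, -0.003, -0.077,
                -0.156, 0.027, 0.021, 0.090, 0.116, 0.312, 0.028)
  lack <- c(-2.327, -0.033, 0.0060, 0.000062, 0.0001, -0.000261,
            0.087, 0.173, 0.037, -0.040, -0.251, -0.138, -0.164,
            0.203, -0.002, 0.655, 0.164, 0.078, 0.453, -0.156)
  beta2 <- cbind(financial = financial, time = time_con, lack = lack)
  rownames(beta2) <- nm2
  selmnp_params(beta1, beta2, rho = rho)
}

#' Configuration of the synthetic panel generator
#'
#' Defaults are the study conditions the generator emulates: five annual
#' waves, 2 percentage-point attrition per wave, covariate marginals equal to
#' the pooled descriptive statistics of the emulated survey, and the
#' published coefficient estimates (display scaling undone) as the generating
#' truth, with cross-equation correlations of 0.3 as a configurable default.
#'
#' @param n_individuals individuals entering at wave 1.
#' @param n_waves number of annual waves.
#' @param attrition_per_wave probability of (permanent) drop-out before each
#'   wave after the first.
#' @param covariate_params named marginals; see
#'   \code{selmnp:::default_covariate_params()}.
#' @param truth generating [selmnp_params()].
#' @param transition_prob per-wave probability that a time-varying covariate
#'   is redrawn from its marginal (keeps marginals stationary).
#' @param weight_sdlog log-normal dispersion of the longitudinal weights
#'   (normalised to mean 1).
#' @param age_center centring constant tying the truth's age coefficients to
#'   raw age in years.
#' @param first_year calendar year of wave 1.
#' @param seed integer seed; the generated table is bit-reproducible given it.
#' @return an object of class \code{selmnp_config}.
#' @export
synthetic_config <- function(n_individuals = 2000L, n_waves = 5L,
                             attrition_per_wave = 0.02,
                             covariate_params = default_covariate_params(),
                             truth = default_truth(),
                             transition_prob = 0.05,
                             weight_sdlog = 0.3,
                             age_center = 52.753,
                             first_year = 2014L,
                             seed = 1L) {
  stopifnot(n_individuals >= 1L, n_waves >= 1L,
            attrition_per_wave >= 0, attrition_per_wave <= 1,
            transition_prob >= 0, transition_prob <= 1,
            inherits(truth, "selmnp_params"))
  structure(list(n_individuals = as.integer(n_individuals),
                 n_waves = as.integer(n_waves),
                 attrition_per_wave = attrition_per_wave,
                 covariate_params = covariate_params,
                 truth = truth,
                 transition_prob = transition_prob,
                 weight_sdlog = weight_sdlog,
                 age_center = age_center,
                 first_year = as.integer(first_year),
                 seed = as.integer(seed)),
            class = "selmnp_config")
}

#' @rdname synthetic_config
#' @export
default_config <- function(seed = 1L) synthetic_config(seed = seed)

#' @export
print.selmnp_config <- function(x, ...) {
  cat("synthetic panel config: ", x$n_individuals, " individuals x ",
      x$n_waves, " waves, attrition ", x$attrition_per_wave, "/wave, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

draw_baseline <- function(n, cp) {
  age_z <- stats::runif(n,
                        stats::pnorm((cp$age_min - cp$age_mean) / cp$age_sd),
                        stats::pnorm((cp$age_max - cp$age_mean) / cp$age_sd))
  data.frame(
    man = stats::rbinom(n, 1L, cp$man),
    age = round(cp$age_mean + cp$age_sd * stats::qnorm(age_z)),
    unmarried = stats::rbinom(n, 1L, cp$unmarried),
    seoul = stats::rbinom(n, 1L, cp$seoul),
    college = stats::rbinom(n, 1L, cp$college),
    occupation = sample(names(cp$occupation), n, TRUE,
                        prob = cp$occupation / sum(cp$occupation)),
    income = sample(names(cp$income), n, TRUE,
                    prob = cp$income / sum(cp$income)),
    mca = stats::rbinom(n, 1L, cp$mca),
    private_ins = stats::rbinom(n, 1L, cp$private_ins),
    funclim = stats::rbinom(n, 1L, cp$funclim),
    smoker = stats::rbinom(n, 1L, cp$smoker),
    alcohol = stats::rbinom(n, 1L, cp$alcohol),
    exercise = stats::rbinom(n, 1L, cp$exercise),
    obese = stats::rbinom(n, 1L, cp$obese),
    poor_health = stats::rbinom(n, 1L, cp$poor_health),
    chronic = stats::rbinom(n, 1L, cp$chronic),
    stringsAsFactors = FALSE)
}

# Time-varying covariates: binary and categorical covariates redrawn from
# their marginal with probability `tp` (marginal-preserving); age advances.
evolve_covariates <- function(cov, cp, tp) {
  n <- nrow(cov)
  redraw <- function(cur, new) ifelse(stats::runif(n) < tp, new, cur)
  cov$age <- cov$age + 1L
  for (v in c("unmarried", "seoul", "college", "mca", "private_ins",
              "funclim", "smoker", "alcohol", "exercise", "obese",
              "poor_health", "chronic"))
    cov[[v]] <- redraw(cov[[v]], stats::rbinom(n, 1L, cp[[v]]))
  cov$occupation <- redraw(cov$occupation,
                           sample(names(cp$occupation), n, TRUE,
                                  prob = cp$occupation / sum(cp$occupation)))
  cov$income <- redraw(cov$income,
                       sample(names(cp$income), n, TRUE,
                              prob = cp$income / sum(cp$income)))
  cov
}

#' Simulate a survey-like panel from the latent selection model
#'
#' Draws baseline covariates from the configured marginals, evolves
#' time-varying covariates by marginal-preserving transitions, applies
#' permanent attrition before each wave after the first, draws the correlated
#' error vector per person-year from the truth's joint normal, forms the
#' needs indicator and the utility-maximising barrier outcome, and inverts
#' the outcome coding back to raw survey answer codes.  Longitudinal weights
#' are log-normal, normalised to mean 1.
#'
#' @param config a [synthetic_config()].
#' @return data frame of person-year records (columns \code{person_id},
#'   \code{year}, \code{weight}, \code{q1}, \code{q2}, covariates) with the
#'   generator's internal outcomes attached as attribute
#'   \code{latent_outcomes}.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "selmnp_config"))
  cp <- config$covariate_params
  with_local_seed(config$seed, {
    n <- config$n_individuals
    cov <- draw_baseline(n, cp)
    active <- rep(TRUE, n)
    rows <- vector("list", config$n_waves)
    for (w in seq_len(config$n_waves)) {
      if (w > 1L) {
        active <- active & (stats::runif(n) >= config$attrition_per_wave)
        cov <- evolve_covariates(cov, cp, config$transition_prob)
      }
      idx <- which(active)
      rows[[w]] <- cbind(person_id = idx,
                         year = config$first_year + w - 1L,
                         cov[idx, , drop = FALSE])
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$person_id, tab$year), , drop = FALSE]
    rownames(tab) <- NULL
    m <- nrow(tab)

    # latent outcomes from the truth
    truth <- config$truth
    spec <- default_spec_for(truth, config$age_center)
    age_c <- tab$age - config$age_center
    X1 <- build_matrix(spec$eq1_terms, tab, age_c, check = FALSE)
    X2 <- build_matrix(spec$eq2_terms, tab, age_c, check = FALSE)
    s1 <- as.numeric(X1 %*% truth$beta1)
    eta <- X2 %*% truth$beta2
    Lj <- chol_lower(attr(truth, "joint_sigma"))   # (u2,u3,u4,eps1)
    z <- matrix(stats::rnorm(4L * m), m, 4L) %*% t(Lj)
    y1 <- as.integer(s1 + z[, 4L] > 0)
    util <- cbind(0, eta + z[, 1:3])
    y2 <- max.col(util, ties.method = "first")
    y2[y1 == 0L] <- NA_integer_
    codes <- outcomes_to_codes(y1, y2)

    w <- stats::rlnorm(m, 0, config$weight_sdlog)
    w <- w / mean(w)

    out <- cbind(data.frame(person_id = tab$person_id, year = tab$year,
                            weight = w, q1 = codes$q1, q2 = codes$q2),
                 tab[, setdiff(names(tab), c("person_id", "year")),
                     drop = FALSE])
    attr(out, "latent_outcomes") <- data.frame(y1 = y1, y2 = y2)
    out
  })
}

# Model spec whose term order matches a truth parameter vector.
default_spec_for <- function(truth, age_center) {
  nm1 <- setdiff(names(truth$beta1), "(Intercept)")
  nm2 <- setdiff(rownames(truth$beta2), "(Intercept)")
  if (length(nm1) && length(nm2))
    model_spec(nm1, nm2, age_center = age_center)
  else
    default_model_spec(age_center = age_center)
}
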