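# Model specification and design-matrix construction.

# Term vocabulary.  Derived age terms are built from centred age in raw years;
# the x10 / x1000 factors are *display* scales applied only when reporting, so
# printed age coefficients match the conventional per-decade magnitudes.
term_info <- function() {
  data.frame(
    term = c("man", "age", "age_sq", "man_age", "man_age_sq", "woman_age_sq",
             "unmarried", "seoul", "college", "occ_blue", "occ_white",
             "inc_medium", "inc_highest", "mca", "private_ins", "funclim",
             "smoker", "alcohol", "exercise", "obese", "poor_health",
             "chronic"),
    label = c("Man (R: woman)", "Age, 0", "Age-squared, 000",
              "Man*age, 0", "Man*age-squared, 000", "Woman*age-squared, 000",
              "Unmarried (R: married)", "Seoul metropolitan area",
              "College or higher", "Blue-collar job (R: no job)",
              "White-collar job (R: no job)",
              "Medium income (R: lowest quintile)",
              "Highest quintile (R: lowest quintile)",
              "Medical Care Aid (R: NHI)", "Private health insurance",
              "Functional limitation", "Current smoker", "Alcohol consumer",
              "Active physical exercise", "Obese", "Poor self-assessed health",
              "Chronic disease"),
    scale = c(1, 10, 1000, 10, 1000, 1000, rep(1, 16)),
    stringsAsFactors = FALSE)
}

covariate_columns <- c("man", "age", "unmarried", "seoul", "college",
                       "occupation", "income", "mca", "private_ins",
                       "funclim", "smoker", "alcohol", "exercise", "obese",
                       "poor_health", "chronic")

#' Model specification for the two-equation system
#'
#' Ordered term lists per equation, the reference alternative, and the age
#' centring constant.  The default layout mirrors the headline model: the
#' selection equation carries gender-specific age-squared terms and excludes
#' alcohol consumption; the outcome equation carries main age-squared plus
#' gender interactions and excludes exercise and obesity.  These exclusion
#' restrictions identify the selection system.
#'
#' @param eq1_terms,eq2_terms character vectors of term names (see
#'   \code{selmnp:::term_info()} for the vocabulary); the intercept is always
#'   included and need not be listed.
#' @param reference_alternative outcome category treated as reference
#'   (1 = met needs).
#' @param age_center years subtracted from age before forming age terms;
#'   \code{NULL} means the unweighted sample mean at build time.
#' @return an object of class \code{selmnp_spec}.
#' @export
model_spec <- function(eq1_terms, eq2_terms, reference_alternative = 1L,
                       age_center = NULL) {
  known <- term_info()$term
  bad <- setdiff(c(eq1_terms, eq2_terms), known)
  if (length(bad))
    stop("unknown term name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(reference_alternative %in% 1:4)
  structure(list(eq1_terms = eq1_terms, eq2_terms = eq2_terms,
                 reference_alternative = as.integer(reference_alternative),
                 age_center = age_center),
            class = "selmnp_spec")
}

#' @rdname model_spec
#' @export
default_model_spec <- function(age_center = NULL) {
  model_spec(
    eq1_terms = c("man", "age", "man_age_sq", "woman_age_sq", "unmarried",
                  "seoul", "college", "occ_blue", "occ_white", "inc_medium",
                  "inc_highest", "mca", "private_ins", "funclim", "smoker",
                  "exercise", "obese", "poor_health", "chronic"),
    eq2_terms = c("man", "age", "age_sq", "man_age", "man_age_sq",
                  "unmarried", "seoul", "college", "occ_blue", "occ_white",
                  "inc_medium", "inc_highest", "mca", "private_ins",
                  "funclim", "smoker", "alcohol", "poor_health", "chronic"),
    age_center = age_center)
}

#' @export
print.selmnp_spec <- function(x, ...) {
  cat("selmnp model specification\n")
  cat("  eq1 (selection):", length(x$eq1_terms), "terms + intercept\n")
  cat("  eq2 (outcome):  ", length(x$eq2_terms), "terms + intercept\n")
  cat("  reference alternative:", x$reference_alternative, "\n")
  cat("  age centre:", if (is.null(x$age_center)) "sample mean"
      else x$age_center, "\n")
  invisible(x)
}

term_column <- function(term, data, age_c) {
  switch(term,
    age = age_c,
    age_sq = age_c^2,
    man_age = data$man * age_c,
    man_age_sq = data$man * age_c^2,
    woman_age_sq = (1 - data$man) * age_c^2,
    occ_blue = as.numeric(data$occupation == "blue_collar"),
    occ_white = as.numeric(data$occupation == "white_collar"),
    inc_medium = as.numeric(data$income == "medium"),
    inc_highest = as.numeric(data$income == "highest"),
    as.numeric(data[[term]]))
}

build_matrix <- function(terms, data, age_c, check = TRUE) {
  cols <- vapply(terms, term_column, numeric(nrow(data)), data = data,
                 age_c = age_c)
  X <- cbind("(Intercept)" = 1, cols)
  if (check) {
    const <- apply(X[, -1, drop = FALSE], 2L, function(v) diff(range(v)) == 0)
    if (any(const))
      stop("degenerate design: constant column(s) ",
           paste(names(const)[const], collapse = ", "), call. = FALSE)
  }
  X
}

#' Build the design matrices for both equations
#'
#' Centres age, forms the quadratic and gender-by-age interaction terms from
#' the centred variable, dummy-codes the categorical covariates against their
#' reference categories, and returns aligned matrices, outcomes, weights and
#' cluster ids.  Rows with any missing covariate or outcome are not allowed;
#' run [derive_outcomes()] and complete-case selection upstream.
#'
#' @param coded_data data frame with \code{y1}, \code{y2}, \code{person_id},
#'   \code{weight} and the covariate columns.
#' @param spec a [model_spec()].
#' @return an object of class \code{selmnp_design}: list with \code{X1},
#'   \code{X2}, \code{y1}, \code{y2}, \code{weights}, \code{cluster_ids} and
#'   the resolved spec.
#' @export
build_design <- function(coded_data, spec = default_model_spec()) {
  stopifnot(inherits(spec, "selmnp_spec"))
  need <- c("y1", "y2", "person_id", "weight",
            intersect(covariate_columns, union_terms_covariates(spec)))
  miss <- setdiff(need, names(coded_data))
  if (length(miss))
    stop("coded data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cc <- coded_data[, setdiff(need, "y2"), drop = FALSE]
  if (anyNA(cc))
    stop("missing values in outcomes or covariates; apply listwise deletion upstream",
         call. = FALSE)
  if (anyNA(coded_data$y2[coded_data$y1 == 1L]))
    stop("y2 missing within the needs group", call. = FALSE)
  if (any(coded_data$weight <= 0))
    stop("weights must be positive", call. = FALSE)

  age_center <- spec$age_center
  if (is.null(age_center)) age_center <- mean(coded_data$age)
  age_c <- coded_data$age - age_center
  spec$age_center <- age_center

  X1 <- build_matrix(spec$eq1_terms, coded_data, age_c)
  X2 <- build_matrix(spec$eq2_terms, coded_data, age_c)
  structure(list(X1 = X1, X2 = X2,
                 y1 = as.integer(coded_data$y1),
                 y2 = as.integer(coded_data$y2),
                 weights = as.numeric(coded_data$weight),
                 cluster_ids = coded_data$person_id,
                 spec = spec,
                 n_obs = nrow(coded_data),
                 n_individuals = length(unique(coded_data$person_id))),
            class = "selmnp_design")
}

# covariate columns a spec's terms touch (age terms need man + age)
union_terms_covariates <- function(spec) {
  terms <- union(spec$eq1_terms, spec$eq2_terms)
  covs <- intersect(terms, covariate_columns)
  if (any(grepl("age", terms))) covs <- union(covs, c("age", "man"))
  if (any(startsWith(terms, "occ_"))) covs <- union(covs, "occupation")
  if (any(startsWith(terms, "inc_"))) covs <- union(covs, "income")
  covs
}

#' @export
print.selmnp_design <- function(x, ...) {
  cat("selmnp design: ", x$n_obs, " observations, ", x$n_individuals,
      " individuals\n", sep = "")
  cat("  X1: ", ncol(x$X1), " columns; X2: ", ncol(x$X2), " columns\n",
      sep = "")
  cat("  needs share: ", format(mean(x$y1), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Variance inflation factors
#'
#' For each non-intercept column, \eqn{VIF = 1 / (1 - R^2)} from the linear
#' regression of that column on all other columns (with intercept).  Exactly
#' collinear designs are reported as an error naming the offending columns.
#'
#' @param X design matrix including an intercept column.
#' @return list with per-column \code{vif} and \code{max}.
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  icpt <- apply(X, 2L, function(v) diff(range(v)) == 0)
  Z <- X[, !icpt, drop = FALSE]
  if (ncol(Z) < 2L)
    stop("need at least 2 non-intercept columns", call. = FALSE)
  vif <- vapply(seq_len(ncol(Z)), function(k) {
    fit <- stats::lm.fit(cbind(1, Z[, -k, drop = FALSE]), Z[, k])
    tss <- sum((Z[, k] - mean(Z[, k]))^2)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(Z)
  if (any(is.infinite(vif)))
    stop("infinite VIF (exact collinearity) in column(s): ",
         paste(names(vif)[is.infinite(vif)], collapse = ", "), call. = FALSE)
  list(vif = vif, max = max(vif))
}

#' Write / read a model specification as a structured config file
#'
#' @param spec a [model_spec()].
#' @param path file path (YAML).
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  model_spec(x$eq1_terms, x$eq2_terms,
             reference_alternative = x$reference_alternative %||% 1L,
             age_center = x$age_center)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export design matrices as delimited text (debugging aid)
#' @param design a [build_design()] result.
#' @param dir output directory.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cbind(person_id = design$cluster_ids, y1 = design$y1,
                         y2 = design$y2, weight = design$weights, design$X1),
                   file.path(dir, "design_eq1.csv"), row.names = FALSE)
  utils::write.csv(cbind(person_id = design$cluster_ids, y1 = design$y1,
                         y2 = design$y2, weight = design$weights, design$X2),
                   file.path(dir, "design_eq2.csv"), row.names = FALSE)
  invisible(dir)
}
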