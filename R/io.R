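# Panel file format, configuration and the end-to-end pipeline.
#
# Interchange format: comma-delimited text, one row per person-year, header
# mandatory, missing values as empty fields.  Required columns: person_id,
# year, weight, q1, q2, plus the covariate columns used by the model spec.

panel_required <- c("person_id", "year", "weight", "q1", "q2")

#' Read / write a long-format panel file
#'
#' \code{read_panel} validates the schema: required columns present,
#' (person_id, year) unique, weights positive.  Records with q2 filled
#' although q1 is not 1 are accepted but counted in the \code{consistency}
#' attribute (q2 is only meaningful for respondents reporting an unmet
#' need).  \code{write_panel} followed by \code{read_panel} is the identity
#' on the schema columns.
#'
#' @param path file path.
#' @return data frame of person-year records.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(panel_required, names(tab))
  if (length(miss))
    stop("panel file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dup <- duplicated(tab[c("person_id", "year")])
  if (any(dup)) {
    off <- tab[dup, c("person_id", "year")]
    stop("duplicate (person_id, year) pairs: ",
         paste(utils::head(paste0(off$person_id, "/", off$year), 5L),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(tab$weight) & tab$weight <= 0))
    stop("non-positive weight(s) found", call. = FALSE)
  flagged <- sum(!is.na(tab$q2) & (is.na(tab$q1) | tab$q1 != 1L))
  attr(tab, "consistency") <-
    list(q2_without_unmet = flagged)
  tab
}

#' @rdname read_panel
#' @param data data frame of person-year records.
#' @export
write_panel <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> code outcomes -> build designs -> fit -> diagnostics
#' -> average adjusted probabilities, writing every artifact to
#' \code{output_dir}: the coded data, exclusion log, Table-style estimates,
#' diagnostics (max VIF per equation, Hosmer--Lemeshow, AIC/BIC), the AAP
#' table and figures, and a run log with seeds and versions.
#'
#' @param config either a path to a YAML file or a list with entries:
#'   \code{input} (panel file path) or \code{simulate} (list of
#'   [synthetic_config()] arguments); \code{spec} (list with
#'   \code{eq1_terms}, \code{eq2_terms}, optional \code{age_center}) or
#'   omitted for the default; \code{fit} (options for [fit_selmnp()]);
#'   \code{aap} (options for [average_adjusted_probability()]);
#'   \code{output_dir}; \code{seed}.
#' @return (invisibly) a list with the fit, the AAP grid and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(err)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(err),
           call. = FALSE))
  }
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config must name output_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  # --- input ------------------------------------------------------------------
  raw <- stage("input", {
    if (!is.null(config$input)) {
      read_panel(config$input)
    } else if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- as.integer(args$seed %||% seed)
      cfg <- do.call(synthetic_config, args)
      tab <- simulate_panel(cfg)
      write_panel(tab, file.path(out_dir, "simulated_panel.csv"))
      tab
    } else stop("config must provide input or simulate")
  })

  # --- outcome coding ---------------------------------------------------------
  coded <- stage("code", derive_outcomes(raw))
  utils::write.csv(coded$data, file.path(out_dir, "coded.csv"),
                   row.names = FALSE, na = "")
  write_exclusion_log(coded$exclusions, file.path(out_dir, "exclusions.txt"))

  # --- design -----------------------------------------------------------------
  spec <- stage("design", {
    if (is.null(config$spec)) default_model_spec()
    else model_spec(config$spec$eq1_terms, config$spec$eq2_terms,
                    reference_alternative =
                      config$spec$reference_alternative %||% 1L,
                    age_center = config$spec$age_center)
  })
  design <- stage("design", build_design(coded$data, spec))
  vifs <- stage("design", list(eq1 = compute_vif(design$X1),
                               eq2 = compute_vif(design$X2)))

  # --- fit --------------------------------------------------------------------
  fit_args <- config$fit %||% list()
  fit_args$design <- design
  if (is.null(fit_args$seed)) fit_args$seed <- seed
  fit <- stage("fit", do.call(fit_selmnp, fit_args))
  write_fit(fit, out_dir)

  # --- diagnostics ------------------------------------------------------------
  hl <- stage("diagnostics", hl_first_equation(design))
  ic <- information_criteria(fit$loglik, fit$k_free, fit$n_obs)
  writeLines(c(
    sprintf("max VIF eq1: %.3f", vifs$eq1$max),
    sprintf("max VIF eq2: %.3f", vifs$eq2$max),
    sprintf("Hosmer-Lemeshow: chi2 = %.3f, df = %d, p = %.4f",
            hl$statistic, hl$df, hl$p_value),
    sprintf("AIC: %.2f", ic$aic),
    sprintf("BIC: %.2f", ic$bic),
    sprintf("converged: %s", fit$converged)),
    file.path(out_dir, "diagnostics.txt"))

  # --- average adjusted probabilities ------------------------------------------
  aap_args <- config$aap %||% list()
  aap_args$fit <- fit
  aap_args$coded_data <- coded$data
  aap <- stage("aap", do.call(average_adjusted_probability, aap_args))
  write_aap(aap, file.path(out_dir, "aap.csv"))
  stage("aap", {
    ggplot2::ggsave(file.path(out_dir, "aap_needs.pdf"),
                    plot_aap(aap, "needs"), width = 7, height = 5)
    ggplot2::ggsave(file.path(out_dir, "aap_barriers.pdf"),
                    plot_aap(aap, "barriers"), width = 9, height = 5)
  })

  # --- run log ----------------------------------------------------------------
  spec_file <- file.path(out_dir, "model_spec.yaml")
  write_model_spec(design$spec, spec_file)
  writeLines(c(
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", seed),
    sprintf("fit seed: %d", fit$seed),
    sprintf("n_draws: %d", fit$n_draws),
    sprintf("spec md5: %s", unname(tools::md5sum(spec_file))),
    sprintf("n_obs: %d; n_individuals: %d", fit$n_obs, fit$n_individuals),
    sprintf("converged: %s; gradient norm: %.3g", fit$converged,
            fit$gradient_norm),
    sprintf("package version: %s",
            as.character(utils::packageVersion("selmnp"))),
    sprintf("R version: %s", R.version.string)),
    file.path(out_dir, "run_log.txt"))

  invisible(list(fit = fit, aap = aap, design = design,
                 vif = vifs, hosmer_lemeshow = hl, output_dir = out_dir))
}

#' Sample-flow accounting for a panel analysis
#'
#' Bookkeeping arithmetic for reporting how an analysis sample was formed
#' from raw person-year records: the retained count after exclusions, the
#' retention percentage, and observations per individual.
#'
#' @param n_total raw person-year observations.
#' @param n_excluded vector of excluded counts (any length).
#' @param n_individuals distinct individuals in the final sample.
#' @return list with \code{n_final}, \code{retained_pct} (one decimal),
#'   \code{obs_per_individual} (one decimal).
#' @export
sample_accounting <- function(n_total, n_excluded, n_individuals) {
  n_final <- n_total - sum(n_excluded)
  list(n_final = n_final,
       retained_pct = round(100 * n_final / n_total, 1),
       obs_per_individual = round(n_final / n_individuals, 1))
}

#' Panel retention after attrition
#'
#' @param n_first respondents in the first wave.
#' @param n_last of those, respondents still present in the last wave.
#' @return retention percentage (one decimal).
#' @export
attrition_retention <- function(n_first, n_last) {
  round(100 * n_last / n_first, 1)
}
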