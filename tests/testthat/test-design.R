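coded_fixture <- function(n = 60, seed = 2) {
  tab <- simulate_panel(small_config(n_individuals = n, n_waves = 2,
                                     seed = seed))
  derive_outcomes(tab)$data
}

test_that("age is centred and derived terms are formed from centred age", {
  dat <- coded_fixture()
  spec <- model_spec(c("man", "age", "age_sq", "man_age"),
                     c("man", "age"), age_center = 50)
  des <- build_design(dat, spec)
  expect_equal(des$X1[, "age"], dat$age - 50)
  expect_equal(des$X1[, "age_sq"], (dat$age - 50)^2)
  expect_equal(des$X1[, "man_age"], dat$man * (dat$age - 50))
  expect_equal(unname(des$X1[, 1]), rep(1, nrow(dat)))   # intercept present
  expect_equal(unname(des$X2[, 1]), rep(1, nrow(dat)))
  # mean-centring by default
  des2 <- build_design(dat, model_spec(c("man", "age"), c("man", "age")))
  expect_equal(mean(des2$X1[, "age"]), 0, tolerance = 1e-12)
})

test_that("the default specification carries the exclusion restrictions", {
  spec <- default_model_spec()
  expect_false("alcohol" %in% spec$eq1_terms)
  expect_true("alcohol" %in% spec$eq2_terms)
  expect_false(any(c("exercise", "obese") %in% spec$eq2_terms))
  expect_true(all(c("exercise", "obese") %in% spec$eq1_terms))
  # gender-specific age-squared terms in eq1; main + interactions in eq2
  expect_true(all(c("man_age_sq", "woman_age_sq") %in% spec$eq1_terms))
  expect_true(all(c("age_sq", "man_age", "man_age_sq") %in% spec$eq2_terms))
})

test_that("categorical covariates are dummy-coded against their references", {
  dat <- coded_fixture(n = 120)
  spec <- model_spec(c("occ_blue", "occ_white", "inc_medium", "inc_highest"),
                     c("occ_blue", "occ_white"), age_center = 50)
  des <- build_design(dat, spec)
  expect_equal(des$X1[, "occ_white"],
               as.numeric(dat$occupation == "white_collar"))
  expect_equal(des$X1[, "occ_blue"],
               as.numeric(dat$occupation == "blue_collar"))
  nojob <- dat$occupation == "no_job"
  expect_true(all(des$X1[nojob, c("occ_blue", "occ_white")] == 0))
  expect_equal(des$X1[, "inc_medium"] + des$X1[, "inc_highest"],
               as.numeric(dat$income != "lowest"))
})

test_that("build_design is deterministic and validates its input", {
  dat <- coded_fixture()
  spec <- small_spec(50)
  expect_identical(build_design(dat, spec), build_design(dat, spec))
  expect_error(model_spec("man", "not_a_term"), "unknown term")
  dat_na <- dat; dat_na$man[1] <- NA
  expect_error(build_design(dat_na, spec), "missing values")
  dat_const <- dat; dat_const$man <- 1
  expect_error(build_design(dat_const, spec), "constant column")
})

test_that("VIF matches the closed form and its invariances", {
  # two columns with correlation 0.9 -> VIF = 1/(1 - 0.81) for each
  set.seed(4)
  n <- 4000
  z <- rnorm(n)
  x1 <- z
  x2 <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  r <- cor(x1, x2)
  X <- cbind(1, x1, x2)
  v <- compute_vif(X)
  expect_equal(unname(v$vif), rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  # independent check by direct regression
  r2 <- summary(lm(x1 ~ x2))$r.squared
  expect_equal(unname(v$vif[1]), 1 / (1 - r2), tolerance = 1e-10)

  # orthogonal columns -> VIF 1; VIF >= 1 always; scale invariance
  Q <- qr.Q(qr(scale(matrix(rnorm(40 * 3), 40), scale = FALSE)))
  expect_equal(unname(compute_vif(cbind(1, Q))$vif), rep(1, 3),
               tolerance = 1e-8)
  X3 <- cbind(1, matrix(rnorm(600), 200))
  v3 <- compute_vif(X3)
  expect_true(all(v3$vif >= 1))
  X3s <- X3; X3s[, 2] <- X3s[, 2] * 37.5
  expect_equal(compute_vif(X3s)$vif, v3$vif, tolerance = 1e-8)

  # duplicated column -> infinite-VIF error naming the offender
  expect_error(compute_vif(cbind(1, a = x1, b = x1, c = x2)),
               "infinite VIF")
})

test_that("model specs round-trip through the YAML config format", {
  spec <- default_model_spec(age_center = 52.753)
  path <- tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$eq1_terms, spec$eq1_terms)
  expect_equal(back$eq2_terms, spec$eq2_terms)
  expect_equal(back$age_center, spec$age_center)
})
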