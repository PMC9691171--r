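test_that("the default configuration encodes the study conditions", {
  cfg <- default_config()
  cp <- cfg$covariate_params
  expect_equal(cp$man, 0.462)
  expect_equal(cp$age_mean, 52.753)
  expect_equal(cfg$attrition_per_wave, 0.02)
  expect_equal(cfg$n_waves, 5L)
  # truth on the undone display scale
  expect_equal(unname(cfg$truth$beta1["unmarried"]), -0.294)
  expect_equal(unname(cfg$truth$beta1["age"]), 0.148 / 10)
  expect_equal(unname(cfg$truth$beta2["inc_highest", "financial"]), -1.178)
  expect_equal(unname(cfg$truth$beta2["man_age_sq", "time"]), -0.257 / 1000)
})

test_that("simulation is bit-reproducible given the seed", {
  cfg <- small_config(n_individuals = 100, seed = 77)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a, b)
  c2 <- simulate_panel(small_config(n_individuals = 100, seed = 78))
  expect_false(identical(a, c2))
})

test_that("simulated covariate marginals match their targets", {
  cfg <- synthetic_config(n_individuals = 20000, n_waves = 1, seed = 101)
  tab <- simulate_panel(cfg)
  cp <- cfg$covariate_params
  n <- nrow(tab)
  for (v in c("man", "unmarried", "seoul", "college", "mca", "private_ins",
              "funclim", "smoker", "alcohol", "exercise", "obese",
              "poor_health", "chronic")) {
    target <- cp[[v]]
    mcse <- sqrt(target * (1 - target) / n)
    expect_lt(abs(mean(tab[[v]]) - target), 3.5 * mcse)
  }
  expect_lt(abs(mean(tab$age) - cp$age_mean), 1)
  expect_lt(abs(mean(tab$occupation == "blue_collar") - 0.404 / 0.999), 0.01)
  expect_lt(abs(mean(tab$income == "medium") - 0.601), 0.01)
  # weights positive with mean 1
  expect_true(all(tab$weight > 0))
  expect_equal(mean(tab$weight), 1, tolerance = 1e-12)
})

test_that("attrition yields the expected retention profile", {
  cfg <- synthetic_config(n_individuals = 20000, n_waves = 5, seed = 55,
                          truth = small_truth())
  tab <- simulate_panel(cfg)
  by_wave <- table(tab$year)
  expect_equal(unname(by_wave[1]), 20000)
  retain5 <- unname(by_wave[5]) / 20000
  expect_equal(retain5, 0.98^4, tolerance = 0.01)
  # retention is monotone
  expect_true(all(diff(as.numeric(by_wave)) <= 0))
  # drop-out is permanent: no gaps in individual year sequences
  yrs <- split(tab$year, tab$person_id)
  gaps <- vapply(yrs, function(y) any(diff(sort(y)) != 1), logical(1))
  expect_false(any(gaps))
})

test_that("derive_outcomes inverts the generator's coding exactly", {
  tab <- simulate_panel(small_config(n_individuals = 500, seed = 91))
  lat <- attr(tab, "latent_outcomes")
  res <- derive_outcomes(tab)
  expect_identical(res$data$y1, lat$y1)
  expect_identical(res$data$y2, lat$y2)
  expect_equal(sum(res$exclusions$n), 0L)
  # q2 present iff q1 = 1
  expect_true(all(is.na(tab$q2) == (tab$q1 != 1L)))
})

test_that("simulated outcome shares match aggregated choice probabilities", {
  cfg <- small_config(n_individuals = 8000, n_waves = 1, seed = 61)
  tab <- simulate_panel(cfg)
  lat <- attr(tab, "latent_outcomes")
  spec <- small_spec(cfg$age_center)
  coded <- derive_outcomes(tab)$data
  des <- build_design(coded, spec)

  # oracle: average the model-implied joint probabilities over the simulated
  # covariates (computed by GHK at many draws)
  truth <- cfg$truth
  s1 <- as.numeric(des$X1 %*% truth$beta1)
  eta <- des$X2 %*% truth$beta2
  chols <- selmnp:::mnp_chols(truth$rho, truth$omega, TRUE)
  unif <- selmnp:::halton_raw(2000, 3)
  shift <- selmnp:::ghk_shifts(nrow(des$X1), 3, 1)
  pj <- selmnp_probs_cpp(s1, eta, chols, unif, shift, TRUE)
  implied <- colMeans(pj)
  observed <- vapply(1:4, function(j) mean(lat$y1 == 1L & lat$y2 == j,
                                           na.rm = FALSE), numeric(1))
  observed[is.na(observed)] <- 0
  expect_lt(max(abs(observed - implied)), 0.013)
  expect_lt(abs(mean(lat$y1 == 0L) - mean(pnorm(-s1))), 0.013)
})
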