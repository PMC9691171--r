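# Small fitted model reused across AAP tests.
aap_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config(n_individuals = 250, n_waves = 2, seed = 47)
      coded <- derive_outcomes(simulate_panel(cfg))
      des <- build_design(coded$data, small_spec(cfg$age_center))
      fit <- fit_selmnp(des, n_draws = 80, seed = 9, maxit = 80)
      cache <<- list(fit = fit, coded = coded$data, cfg = cfg)
    }
    cache
  }
})

test_that("AAP grid values equal brute-force re-averaged per-observation probabilities", {
  fx <- aap_fixture()
  aap <- average_adjusted_probability(fx$fit, fx$coded, ages = c(30, 60),
                                      ci = FALSE)
  # brute force: rebuild the design at the grid point and recompute every
  # observation's probabilities with the pure-R GHK, then weight-average
  params <- fx$fit$estimates
  spec <- fx$fit$spec
  w <- fx$coded$weight / mean(fx$coded$weight)
  unif <- selmnp:::halton_raw(fx$fit$n_draws, 3)
  shift <- selmnp:::design_shifts(build_design(fx$coded, spec), fx$fit$seed)
  for (g in c(1, 0)) {
    for (a in c(30, 60)) {
      dat <- fx$coded
      dat$man <- g; dat$age <- a
      age_c <- dat$age - spec$age_center
      X1 <- selmnp:::build_matrix(spec$eq1_terms, dat, age_c, check = FALSE)
      X2 <- selmnp:::build_matrix(spec$eq2_terms, dat, age_c, check = FALSE)
      s1 <- as.numeric(X1 %*% params$beta1)
      eta <- X2 %*% params$beta2
      pj <- t(vapply(seq_len(nrow(dat)), function(i) {
        ui <- (sweep(unif, 2, shift[i, ], "+")) %% 1
        vapply(2:4, function(j) joint_prob_r(s1[i], eta[i, ], j, params$rho,
                                             unif = ui), numeric(1))
      }, numeric(3)))
      brute <- c(p_needs = weighted.mean(pnorm(s1), w),
                 p_financial = weighted.mean(pj[, 1], w),
                 p_time = weighted.mean(pj[, 2], w),
                 p_lack = weighted.mean(pj[, 3], w))
      row <- aap[aap$gender == ifelse(g == 1, "man", "woman") &
                   aap$age == a, ]
      expect_equal(row$p_needs, unname(brute["p_needs"]), tolerance = 1e-6)
      expect_equal(row$p_financial, unname(brute["p_financial"]),
                   tolerance = 1e-6)
      expect_equal(row$p_time, unname(brute["p_time"]), tolerance = 1e-6)
      expect_equal(row$p_lack, unname(brute["p_lack"]), tolerance = 1e-6)
    }
  }
})

test_that("barrier AAPs add up to the unmet total at every grid point", {
  fx <- aap_fixture()
  aap <- average_adjusted_probability(fx$fit, fx$coded,
                                      ages = seq(20, 90, by = 10), ci = FALSE)
  expect_equal(aap$p_unmet_total, aap$p_financial + aap$p_time + aap$p_lack,
               tolerance = 1e-12)
  expect_true(all(aap$p_needs >= 0 & aap$p_needs <= 1))
  expect_true(all(aap$p_unmet_total >= 0 & aap$p_unmet_total <= 1))
})

test_that("conditional barrier probabilities divide the joint by the needs probability", {
  fx <- aap_fixture()
  joint <- average_adjusted_probability(fx$fit, fx$coded, ages = 40,
                                        ci = FALSE, type = "joint")
  cond <- average_adjusted_probability(fx$fit, fx$coded, ages = 40,
                                       ci = FALSE, type = "conditional")
  # conditional >= joint (division by a probability <= 1), same ordering
  expect_true(all(cond$p_financial >= joint$p_financial))
  expect_equal(cond$p_unmet_total,
               cond$p_financial + cond$p_time + cond$p_lack,
               tolerance = 1e-12)
})

test_that("delta-method intervals bracket the point values and are deterministic", {
  fx <- aap_fixture()
  aap1 <- average_adjusted_probability(fx$fit, fx$coded, ages = c(30, 70))
  aap2 <- average_adjusted_probability(fx$fit, fx$coded, ages = c(30, 70))
  expect_identical(aap1, aap2)
  for (v in c("p_needs", "p_unmet_total", "p_financial", "p_time", "p_lack")) {
    expect_true(all(aap1[[paste0(v, "_lo")]] <= aap1[[v]] + 1e-12))
    expect_true(all(aap1[[paste0(v, "_hi")]] >= aap1[[v]] - 1e-12))
  }
})

test_that("a model with no age or gender terms gives a flat AAP surface", {
  cfg <- small_config(n_individuals = 150, n_waves = 2, seed = 53)
  coded <- derive_outcomes(simulate_panel(cfg))
  spec <- model_spec("unmarried", "unmarried", age_center = 50)
  des <- build_design(coded$data, spec)
  fit <- fit_selmnp(des, n_draws = 60, seed = 4, maxit = 60)
  aap <- average_adjusted_probability(fit, coded$data, ages = c(20, 50, 80),
                                      ci = FALSE)
  expect_equal(diff(range(aap$p_needs)), 0, tolerance = 1e-12)
  expect_equal(diff(range(aap$p_financial)), 0, tolerance = 1e-12)
})

test_that("AAP plots build without error", {
  fx <- aap_fixture()
  aap <- average_adjusted_probability(fx$fit, fx$coded, ages = c(30, 60))
  expect_s3_class(plot_aap(aap, "needs"), "ggplot")
  expect_s3_class(plot_aap(aap, "barriers"), "ggplot")
})
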