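test_that("conditional outcomes honour the half-open window convention", {
  co <- mini_cohort(fu = c(6, 12, 36, 60, 45), dead = c(1, 1, 1, 0, 1))
  w1 <- make_conditional_outcome(co, 1)
  w2 <- make_conditional_outcome(co, 2)
  w3 <- make_conditional_outcome(co, 3)
  # death at 6: window-1 event, out of risk afterwards
  expect_equal(w1$y[1], 1L); expect_false(w2$at_risk[1])
  # death at exactly 12 falls in (0,12]
  expect_equal(w1$y[2], 1L); expect_false(w2$at_risk[2])
  # death at 36: at risk in windows 1-2, event in window 2, not at risk in 3
  expect_equal(w1$y[3], 0L); expect_equal(w2$y[3], 1L)
  expect_false(w3$at_risk[3])
  # administrative censor at 60: at risk everywhere, no events
  expect_equal(c(w1$y[4], w2$y[4], w3$y[4]), c(0L, 0L, 0L))
  # death at 45: window-3 event
  expect_equal(w3$y[5], 1L)
  expect_error(make_conditional_outcome(co, c(36, 12)),
               class = "medroute_input_error")
})

test_that("mediator imputation is seeded, counted and complete-case safe", {
  co <- generate_cohort(default_scenario(20000, seed = 31))
  wo <- make_conditional_outcome(co, 1)
  dat <- co[wo$at_risk, ]
  dat$y <- wo$y[wo$at_risk]
  dat$m <- ifelse(is.na(dat$route), NA_integer_,
                  as.integer(dat$route == "emergency"))

  done <- impute_missing_mediator(dat, seed = 9)
  expect_false(anyNA(done$m))
  expect_equal(attr(done, "n_imputed"), sum(is.na(dat$m)))
  expect_identical(done$m, impute_missing_mediator(dat, seed = 9)$m)
  expect_false(identical(done$m, impute_missing_mediator(dat, seed = 10)$m))

  # no missing values: output identical to input
  full <- dat; full$m[is.na(full$m)] <- 0L
  expect_identical(impute_missing_mediator(full, seed = 1)$m, full$m)
  expect_equal(attr(impute_missing_mediator(full, seed = 1), "n_imputed"), 0L)

  none <- dat; none$m <- NA_integer_
  expect_error(impute_missing_mediator(none, seed = 1),
               class = "medroute_input_error")

  # 5.8% missingness at this n gives the expected imputed count
  p <- 0.058
  expect_lt(abs(sum(is.na(dat$m)) / nrow(dat) - p),
            3 * sqrt(p * (1 - p) / nrow(dat)))
})

test_that("counterfactual risks collapse when the mediator is irrelevant", {
  co <- generate_cohort(default_scenario(2000, seed = 32))
  mm <- list(coefficients = c(-0.7, 0.4, rep(0.1, 7)))
  om_null_m <- list(coefficients = c(-1, 0.3, 0, 0, rep(0.05, 7)))
  r11 <- gcomp_counterfactual_risk(mm, om_null_m, co, 1, 1, mode = "closed_form")
  r10 <- gcomp_counterfactual_risk(mm, om_null_m, co, 1, 0, mode = "closed_form")
  expect_equal(r11, r10, tolerance = 1e-15) # exact in closed form
  r11_mc <- gcomp_counterfactual_risk(mm, om_null_m, co, 1, 1, mc_draws = 50,
                                      seed = 3)
  expect_equal(r11_mc, r11, tolerance = 1e-12) # M draws never change the prediction
  expect_error(gcomp_counterfactual_risk(mm, om_null_m, co, 1, 1, mc_draws = 0),
               class = "medroute_input_error")
  expect_error(gcomp_counterfactual_risk(mm, om_null_m, co, 2, 0),
               class = "medroute_input_error")
})

test_that("g-computation with the true parameters matches the enumeration oracle", {
  spec <- default_scenario(50000, seed = 33)
  co <- generate_cohort(spec)
  mm <- list(coefficients = unname(spec$gamma))
  om <- list(coefficients = unname(spec$theta[[1]]))
  tr <- true_natural_effects(spec, 1)
  for (leg in list(c(1, 1), c(1, 0), c(0, 0))) {
    est <- gcomp_counterfactual_risk(mm, om, co, leg[1], leg[2],
                                     mode = "closed_form")
    truth <- tr$risks[[paste0("p", leg[1], leg[2])]]
    # only confounder sampling error remains; bound it by 3 SE of the mean
    se <- sqrt(truth * (1 - truth) / nrow(co))
    expect_lt(abs(est - truth), 3 * se + 0.002)
  }
})

test_that("closed-form conditional odds ratios evaluate the natural effect model", {
  coef <- list(b1 = 0.3, b2 = 0.1, b4 = 0.05, b5 = 0, b6 = 0)
  expect_equal(nde_or_closed_form(coef, 1, 1), 1)
  expect_equal(nie_or_closed_form(coef, 0, 0), 1)
  expect_equal(nde_or_closed_form(coef, 1, 0), exp(0.3))
  expect_equal(nie_or_closed_form(coef, 1, 0), exp(0.1 + 0.05))
  expect_equal(nde_or_closed_form(coef, 1, 0) * nie_or_closed_form(coef, 1, 0),
               exp(0.45))
  # no interaction, no effect modification: NDE independent of C
  coef0 <- list(b1 = 0.3, b2 = 0.1, b4 = 0, b5 = 0, b6 = 0)
  expect_equal(nde_or_closed_form(coef0, 1, 0, C = c(1, 2)), exp(0.3))
  bad <- list(b1 = 0.3, b2 = 0.1, b4 = 0, b5 = c(1, 2, 3), b6 = 0)
  expect_error(nde_or_closed_form(bad, 1, 0, C = c(1, 2)),
               class = "medroute_input_error")
})

test_that("proportion mediated transformation has the documented surface", {
  expect_equal(proportion_mediated(1.7, 1.0), 0)
  expect_equal(proportion_mediated(1.0, 1.5), 1)
  expect_equal(round(proportion_mediated(1.36, 1.10), 4), 0.2742)
  expect_warning(out <- proportion_mediated(2, 0.5), "undefined")
  expect_true(is.na(out))
  expect_error(proportion_mediated(-1, 2), class = "medroute_input_error")
  # monotone increasing in NIE for fixed NDE when the total effect is > 1
  nie <- seq(1.01, 2, length.out = 20)
  pm <- vapply(nie, function(x) proportion_mediated(1.4, x), numeric(1))
  expect_true(all(diff(pm) > 0))
  expect_true(all(pm > 0 & pm < 1))
})

test_that("estimate_natural_effects telescopes and is reproducible", {
  co <- generate_cohort(default_scenario(20000, seed = 34))
  cfg <- list(seed = 5, n_bootstrap = 0, mc_draws = 25)
  est <- estimate_natural_effects(co, 1, cfg)
  expect_equal(est$tce_or, est$nde_or * est$nie_or, tolerance = 1e-10)
  est2 <- estimate_natural_effects(co, 1, cfg)
  expect_identical(est[c("tce_or", "nde_or", "nie_or", "pm")],
                   est2[c("tce_or", "nde_or", "nie_or", "pm")])
  # windows 2 and 3 refit on survivors and also telescope
  for (w in 2:3) {
    ew <- estimate_natural_effects(co, w, cfg)
    expect_equal(ew$tce_or, ew$nde_or * ew$nie_or, tolerance = 1e-10)
    expect_lt(ew$n_at_risk, est$n_at_risk)
  }
  expect_error(estimate_natural_effects(co, 1, list(n_bootstrap = 0)),
               class = "medroute_config_error")
  tiny <- co[1:40, ]
  expect_error(estimate_natural_effects(tiny, 1, list(seed = 1, n_bootstrap = 0,
                                                      min_events = 1000)),
               class = "medroute_input_error")
})

test_that("relabelling the exposure inverts the effects", {
  spec <- default_scenario(30000, seed = 35, theta_AM = c(0, 0, 0))
  co <- generate_cohort(spec)
  flip <- co; flip$comorbidity <- 1L - flip$comorbidity
  cfg <- list(seed = 77, n_bootstrap = 0, mode = "closed_form")
  a <- estimate_natural_effects(co, 1, cfg)
  b <- estimate_natural_effects(flip, 1, cfg)
  # the total effect inverts exactly: the relabelled fits span the same space
  expect_equal(b$tce_or, 1 / a$tce_or, tolerance = 1e-10)
  # NDE/NIE swap their reference level, so inversion is approximate
  expect_lt(abs(log(b$nde_or) + log(a$nde_or)), 0.02)
  expect_lt(abs(log(b$nie_or) + log(a$nie_or)), 0.02)
})

test_that("bootstrap replicates are seeded and guarded", {
  co <- generate_cohort(default_scenario(8000, seed = 36))
  cfg <- list(seed = 12, n_bootstrap = 25, mc_draws = 10)
  b1 <- bootstrap_natural_effects(co, 1, cfg)
  b2 <- bootstrap_natural_effects(co, 1, cfg)
  expect_identical(b1$ci, b2$ci)
  expect_equal(nrow(b1$replicates), 25)
  expect_equal(b1$n_failed, 0)
  expect_error(bootstrap_natural_effects(co, 1, list(seed = 1, n_bootstrap = 1)),
               class = "medroute_input_error")
  # a two-replicate bootstrap is legal and reproducible
  b3 <- bootstrap_natural_effects(co, 1, list(seed = 3, n_bootstrap = 2))
  expect_equal(nrow(b3$replicates), 2)
})
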