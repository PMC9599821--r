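test_that("expected hazard looks up the attained-age row and converts units", {
  lt <- zero_life_table()
  p <- mini_cohort(60, 0)[1, ]
  expect_equal(expected_hazard(p, lt, 0), 0)
  expect_equal(expected_hazard(p, lt, 59), 0)

  lt <- generate_life_table(b = 1e-4, c = 0.09, male_ratio = 1)
  # integer-year ageing: at t = 13 months a patient aged 70 uses the age-71 row
  expect_equal(expected_hazard(p, lt, 13), 1e-4 * exp(0.09 * 71) / 12)
  expect_equal(expected_hazard(p, lt, 0), 1e-4 * exp(0.09 * 70) / 12)

  off <- p; off$diagnosis_year <- 1950
  expect_error(expected_hazard(off, lt, 0), "1950",
               class = "medroute_lookup_error")
})

test_that("Pohar Perme equals Kaplan-Meier under a zero life table", {
  co <- generate_cohort(default_scenario(3000, seed = 21))
  pp <- pohar_perme(co, zero_life_table())
  km <- kaplan_meier(co)
  expect_lt(max(abs(pp$estimate - km$estimate)), 1e-12)
  # monotone non-increasing in the zero-background case
  expect_true(all(diff(pp$estimate) <= 0))
})

test_that("in-package Kaplan-Meier agrees with the survival package", {
  skip_if_not_installed("survival")
  co <- generate_cohort(default_scenario(2000, seed = 22))
  km <- kaplan_meier(co)
  sf <- survival::survfit(survival::Surv(follow_up_months, dead) ~ 1, data = co)
  sm <- summary(sf, times = km$time)
  expect_equal(km$estimate, sm$surv, tolerance = 1e-12)
  expect_equal(sqrt(km$variance), sm$std.err, tolerance = 1e-10)
})

test_that("degenerate cohorts behave", {
  # no deaths, zero background: exactly 1 everywhere
  co <- mini_cohort(fu = rep(60, 5), dead = rep(0, 5))
  pp <- pohar_perme(co, zero_life_table())
  expect_true(all(pp$estimate == 1))
  expect_true(all(pp$variance == 0))
  # no deaths, positive background: net survival >= 1 at all t
  pp <- pohar_perme(co, generate_life_table())
  expect_true(all(pp$estimate >= 1))
  # single patient dying at month 1: 0 from month 1 onwards
  km <- kaplan_meier(mini_cohort(1, 1), grid = 0:12)
  expect_equal(km$estimate, c(1, rep(0, 12)))
  # risk set emptied by censoring: truncation with a warning
  expect_warning(out <- kaplan_meier(mini_cohort(c(3, 5), c(1, 0)), grid = 0:12),
                 "truncated")
  expect_equal(max(out$time), 5)
})

test_that("3-patient weighted example matches a hand-computed oracle", {
  # deaths at months 6 and 18, one administrative censor at 60, constant
  # background rate 0.02 per person-year for every patient
  co <- mini_cohort(fu = c(6, 18, 60), dead = c(1, 1, 0))
  lt <- generate_life_table(b = 0.02, c = 0, male_ratio = 1)
  pp <- pohar_perme(co, lt, grid = 0:60)

  # oracle: literal month-by-month evaluation of the weighted estimator,
  # written out patient by patient
  lam <- 0.02 / 12
  fu <- c(6, 18, 60); dead <- c(1, 1, 0)
  est <- numeric(61); est[1] <- 1
  cum <- 1
  var_acc <- 0; varr <- numeric(61)
  for (u in 1:60) {
    num <- 0; den <- 0; death_term <- 0; var_num <- 0
    for (i in 1:3) {
      if (fu[i] >= u) {
        w_iu <- 1 / exp(-lam * u) # cumulative expected survival to month end
        den <- den + w_iu
        num <- num - w_iu * lam
        if (dead[i] == 1 && fu[i] == u) {
          num <- num + w_iu
          var_num <- var_num + w_iu^2
        }
      }
    }
    cum <- cum * (1 - num / den)
    var_acc <- var_acc + var_num / den^2
    est[u + 1] <- cum
    varr[u + 1] <- cum^2 * var_acc
  }
  expect_lt(max(abs(pp$estimate - est)), 1e-12)
  expect_lt(max(abs(pp$variance - varr)), 1e-12)

  # zero-background sanity on the same cohort: identical to Kaplan-Meier
  expect_lt(max(abs(pohar_perme(co, zero_life_table())$estimate -
                      kaplan_meier(co)$estimate)), 1e-15)
})

test_that("duplicating every patient keeps the estimate and halves the variance", {
  co <- generate_cohort(default_scenario(1500, seed = 23))
  lt <- generate_life_table()
  dup <- rbind(co, transform(co, patient_id = patient_id + nrow(co)))
  a <- pohar_perme(co, lt); b <- pohar_perme(dup, lt)
  expect_equal(b$estimate, a$estimate, tolerance = 1e-12)
  ratio <- b$variance[b$time == 60] / a$variance[a$time == 60]
  expect_gt(ratio, 0.45); expect_lt(ratio, 0.55)
})

test_that("net survival stays in (0, 1.5] with a positive background hazard", {
  co <- generate_cohort(default_scenario(4000, seed = 24))
  pp <- pohar_perme(co, generate_life_table())
  expect_true(all(pp$estimate > 0 & pp$estimate <= 1.5))
})

test_that("stratified net survival table is Table-2 shaped", {
  co <- generate_cohort(default_scenario(3000, seed = 25))
  tab <- net_survival_table(co, zero_life_table(), by = "comorbidity",
                            times = c(12, 36, 60))
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$stratum), c("0", "1"))
  expect_true(all(tab$estimate > 0 & tab$estimate <= 1))
  expect_error(net_survival_table(co, zero_life_table(), by = "nope"),
               class = "medroute_input_error")
})
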