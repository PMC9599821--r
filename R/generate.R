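#' Generate a synthetic registry cohort
#'
#' Samples a patient-level cohort from the causal mechanism encoded in a
#' [scenario_spec()]: confounders first, then comorbidity, then diagnostic
#' route, then sequential window deaths. A patient who dies in window w has
#' their death month drawn uniformly over the integer months of that window;
#' survivors of all windows are administratively censored at
#' `admin_censor_month` (there is no loss to follow-up, so `dead == 0`
#' implies censoring at the horizon). Recorded routes are independently set
#' to missing with probability `missing_route_prob`. Bit-reproducible for a
#' fixed spec seed.
#'
#' @param spec a validated [scenario_spec()].
#' @param label cohort label carried through outputs (e.g. disease subtype).
#' @return a `cohort`: a data.frame with columns `patient_id`, `age_years`,
#'   `sex`, `deprivation`, `ethnicity`, `comorbidity`, `route` (`"elective"`,
#'   `"emergency"` or `NA`), `follow_up_months`, `dead`, `diagnosis_year`,
#'   plus a `label` attribute.
#' @export
generate_cohort <- function(spec, label = "synthetic") {
  spec <- validate_scenario_spec(spec)
  n <- as.integer(spec$n_patients)
  cc <- spec$confounders
  windows <- window_bounds(spec$admin_censor_month)

  set.seed(as.integer(spec$seed))
  ages <- 45:99
  page <- stats::pnorm(ages + 0.5, cc$age_mean, cc$age_sd) -
    stats::pnorm(ages - 0.5, cc$age_mean, cc$age_sd)
  df <- data.frame(
    patient_id = seq_len(n),
    age_years = sample(ages, n, replace = TRUE, prob = page),
    sex = ifelse(stats::runif(n) < cc$p_female, "female", "male"),
    deprivation = sample(1:5, n, replace = TRUE, prob = cc$dep_probs),
    ethnicity = ifelse(stats::runif(n) < cc$p_eth_other, "other", "white"),
    stringsAsFactors = FALSE
  )
  Xc <- design_C(df)
  A <- stats::rbinom(n, 1, prob_A(spec, Xc))
  M <- stats::rbinom(n, 1, prob_M(spec, A, Xc))

  follow_up <- rep(spec$admin_censor_month, n)
  dead <- integer(n)
  alive <- rep(TRUE, n)
  for (w in seq_len(nrow(windows))) {
    idx <- which(alive)
    if (!length(idx)) break
    q <- prob_death(spec, w, A[idx], M[idx], Xc[idx, , drop = FALSE])
    dies <- idx[stats::runif(length(idx)) < q]
    # uniform integer death month within the fatal window (deaths at month-end)
    follow_up[dies] <- sample_int_range(windows[w, 1] + 1L, windows[w, 2], length(dies))
    dead[dies] <- 1L
    alive[dies] <- FALSE
  }

  route <- ifelse(M == 1L, "emergency", "elective")
  if (spec$missing_route_prob > 0) {
    route[stats::runif(n) < spec$missing_route_prob] <- NA_character_
  }

  df$comorbidity <- A
  df$route <- route
  df$follow_up_months <- follow_up
  df$dead <- dead
  df$diagnosis_year <- as.integer(spec$diagnosis_year)
  attr(df, "label") <- label
  class(df) <- c("cohort", "data.frame")
  df
}

# vectorised uniform integer draw on [lo, hi] per element
sample_int_range <- function(lo, hi, n) {
  lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
}

# Default conditional outcome windows (months): (0,12], (12,36], (36,60],
# scaled if the administrative horizon differs from 60.
window_bounds <- function(admin_censor_month = 60) {
  cuts <- c(0, 12, 36, 60)
  if (admin_censor_month != 60) cuts <- cuts * admin_censor_month / 60
  cbind(start = cuts[1:3], end = cuts[2:4])
}

#' Generate a background-mortality life table
#'
#' Produces expected mortality rates (deaths per person-year) on an
#' (age, sex, calendar year) grid from a Gompertz-type hazard
#' `rate = b * exp(c * age)`, optionally scaled for males by
#' `male_ratio` (male rates are typically higher at any given age).
#' The defaults (b = 2e-5, c = 0.1) give roughly 0.02/yr at age 70 and
#' 0.1/yr at age 85, the order of magnitude of an English life table.
#' A zero-hazard table (`b = 0`) is producible and is the reference case in
#' which net survival reduces to all-cause survival.
#'
#' @param b baseline rate at age 0 (per person-year); non-negative.
#' @param c log-rate increase per year of age; non-negative.
#' @param male_ratio multiplicative male/female rate ratio.
#' @param ages integer age grid; must reach at least `max_age_needed`.
#' @param years calendar-year grid.
#' @param max_age_needed coverage requirement: the oldest diagnosis age (99)
#'   plus 5 years of follow-up by default.
#' @return a `life_table` data.frame with columns `age`, `sex`, `year`, `rate`.
#' @export
generate_life_table <- function(b = 2e-5, c = 0.1, male_ratio = 1.3,
                                ages = 45:105, years = 2005:2021,
                                max_age_needed = 104) {
  if (b < 0 || c < 0 || male_ratio < 0) {
    config_error("life-table rate parameters must be non-negative")
  }
  if (max(ages) < max_age_needed) {
    config_error(sprintf(
      "life-table age grid reaches %d but must cover age %d (oldest diagnosis age plus follow-up)",
      max(ages), max_age_needed))
  }
  grid <- expand.grid(age = ages, sex = c("male", "female"), year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- b * exp(c * grid$age) * ifelse(grid$sex == "male", male_ratio, 1)
  class(grid) <- c("life_table", "data.frame")
  grid
}
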