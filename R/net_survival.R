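#' Expected (background) hazard for one patient at one follow-up time
#'
#' Looks up the population mortality rate for the patient's attained age and
#' calendar year at `t` months since diagnosis, using the integer-year floor
#' convention (attained age = age at diagnosis + `floor(t/12)`, calendar year
#' advances the same way), and converts it to a per-month hazard (`rate/12`).
#'
#' @param patient one cohort row (needs `age_years`, `sex`, `diagnosis_year`).
#' @param lifetable a [generate_life_table()] style data.frame
#'   (`age`, `sex`, `year`, `rate` in deaths per person-year).
#' @param t months since diagnosis.
#' @return per-month expected hazard.
#' @export
expected_hazard <- function(patient, lifetable, t) {
  age <- patient$age_years + floor(t / 12)
  year <- patient$diagnosis_year + floor(t / 12)
  hit <- lifetable$age == age & lifetable$sex == patient$sex &
    lifetable$year == year
  if (!any(hit)) {
    stop_medroute(sprintf(
      "life table has no row for (age=%d, sex=%s, year=%d)",
      age, patient$sex, year), "medroute_lookup_error")
  }
  lifetable$rate[which(hit)[1]] / 12
}

# Per-patient per-month expected hazards, vectorised: n x T matrix for
# months 1..T; hazard for month u is evaluated at the start of the month
# (t = u - 1), so the attained age steps up at months 13, 25, ...
expected_hazard_matrix <- function(cohort, lifetable, T) {
  key <- paste(lifetable$age, lifetable$sex, lifetable$year)
  rate <- stats::setNames(lifetable$rate, key)
  yrs <- floor((seq_len(T) - 1) / 12)
  out <- matrix(NA_real_, nrow(cohort), T)
  for (j in unique(yrs)) {
    cols <- which(yrs == j)
    k <- paste(cohort$age_years + j, cohort$sex, cohort$diagnosis_year + j)
    r <- rate[k]
    if (anyNA(r)) {
      bad <- k[is.na(r)][1]
      stop_medroute(sprintf("life table has no row for (%s)", bad),
                    "medroute_lookup_error")
    }
    out[, cols] <- r / 12
  }
  out
}

survival_curve <- function(time, estimate, variance, n_risk) {
  structure(list(time = time, estimate = estimate, variance = variance,
                 n_risk = n_risk), class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  show <- data.frame(time = x$time, estimate = round(x$estimate, 4),
                     se = round(sqrt(x$variance), 4), n_risk = x$n_risk)
  keep <- x$time %in% c(0, 12, 36, 60) | seq_along(x$time) == length(x$time)
  print(show[keep, ], row.names = FALSE)
  invisible(x)
}

#' Pohar Perme net survival on a monthly grid
#'
#' Discrete monthly implementation of the inverse-expected-survival weighted
#' net survival estimator. Each patient contributes with weight
#' `w_i(u) = 1 / S*_i(u)` where `S*_i(u) = exp(-sum of expected monthly
#' hazards up to u)` is the patient's cumulative expected (background)
#' survival. The excess hazard increment at month u is
#' \deqn{\Delta\Lambda_E(u) = \frac{\sum_i w_i(u)\,dN_i(u) -
#'   \sum_i w_i(u)\,Y_i(u)\,\lambda^*_i(u)}{\sum_i w_i(u)\,Y_i(u)},}
#' with `dN` the month-u death indicator and `Y` the at-risk indicator
#' (deaths and censoring at month-end). Net survival is accumulated with the
#' discrete product-integral `S(t) = prod(1 - dLambda_E(u))`, which reduces
#' exactly to the Kaplan-Meier product-limit estimator when the life table
#' is zero (all weights one, no expected hazard). The variance is the
#' weighted counting-process estimator
#' `S(t)^2 * sum_u sum_i w_i(u)^2 dN_i(u) / (sum_i w_i(u) Y_i(u))^2`.
#' With a positive background hazard the excess hazard increment may be
#' negative, so the curve need not be monotone and can locally exceed 1.
#'
#' @param cohort cohort data.frame (`follow_up_months`, `dead`, plus the
#'   life-table key columns).
#' @param lifetable background mortality rates.
#' @param grid increasing integer month grid; default `0:60`.
#' @return a `survival_curve` (time, estimate, variance, n_risk). If the
#'   risk set empties before the end of the grid the curve is truncated with
#'   a warning.
#' @export
pohar_perme <- function(cohort, lifetable, grid = 0:60) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_medroute("time grid must be strictly increasing", "medroute_input_error")
  }
  T <- max(grid)
  lam <- expected_hazard_matrix(cohort, lifetable, T)
  Sstar <- exp(-t(apply(lam, 1, cumsum)))
  if (nrow(cohort) == 1L) Sstar <- matrix(Sstar, 1)
  fu <- cohort$follow_up_months
  dead <- cohort$dead
  dLam <- numeric(T); varinc <- numeric(T); nrisk <- integer(T)
  run <- 1
  for (u in seq_len(T)) {
    at_risk <- fu >= u
    nrisk[u] <- sum(at_risk)
    if (!nrisk[u]) {
      if (run != 0) { # emptied by censoring: nothing left to estimate from
        warning(sprintf("risk set empty after month %d; curve truncated", u - 1))
        T <- u - 1
        break
      }
      next # everyone died: the survivor function stays at 0
    }
    w <- 1 / Sstar[at_risk, u]
    dN <- dead[at_risk] == 1 & fu[at_risk] == u
    denom <- sum(w)
    dLam[u] <- (sum(w[dN]) - sum(w * lam[at_risk, u])) / denom
    varinc[u] <- sum(w[dN]^2) / denom^2
    run <- run * (1 - dLam[u])
  }
  est <- cumprod(1 - dLam[seq_len(T)])
  cumvar <- cumsum(varinc[seq_len(T)])
  grid <- grid[grid <= T]
  idx <- match(grid, 0:T)
  estimate <- c(1, est)[idx]
  variance <- c(0, est^2 * cumvar)[idx]
  survival_curve(grid, estimate, variance, c(length(fu), nrisk)[idx])
}

#' Kaplan-Meier survivor function on a monthly grid
#'
#' Standard product-limit estimator with Greenwood variance, on the same
#' monthly discretisation as [pohar_perme()]; it is the exact zero-life-table
#' limit of the net survival estimator and serves as its oracle in tests.
#'
#' @inheritParams pohar_perme
#' @return a `survival_curve`.
#' @export
kaplan_meier <- function(cohort, grid = 0:60) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_medroute("time grid must be strictly increasing", "medroute_input_error")
  }
  T <- max(grid)
  fu <- cohort$follow_up_months
  dead <- cohort$dead
  frac <- rep(1, T); gw <- numeric(T); nrisk <- integer(T)
  run <- 1
  for (u in seq_len(T)) {
    n <- sum(fu >= u)
    nrisk[u] <- n
    if (!n) {
      if (run != 0) {
        warning(sprintf("risk set empty after month %d; curve truncated", u - 1))
        T <- u - 1
        break
      }
      next # all deaths: survivor function is identically 0 afterwards
    }
    d <- sum(dead == 1 & fu == u)
    frac[u] <- 1 - d / n
    gw[u] <- if (d < n) d / (n * (n - d)) else 0
    run <- run * frac[u]
  }
  est <- cumprod(frac[seq_len(T)])
  cumgw <- cumsum(gw[seq_len(T)])
  grid <- grid[grid <= T]
  idx <- match(grid, 0:T)
  survival_curve(grid, c(1, est)[idx], c(0, est^2 * cumgw)[idx],
                 c(length(fu), nrisk)[idx])
}

#' Net survival by stratum at selected times
#'
#' Convenience layer producing a long results table of Pohar Perme net
#' survival estimates per stratum of a cohort column, at the requested
#' months.
#'
#' @param cohort cohort data.frame.
#' @param lifetable background mortality rates.
#' @param by stratifying column (e.g. `"comorbidity"`, `"route"`,
#'   `"deprivation"`); `NULL` for the whole cohort.
#' @param times months at which to report.
#' @return data.frame with columns `stratum`, `time`, `estimate`, `variance`,
#'   `se`, `n_risk`.
#' @export
net_survival_table <- function(cohort, lifetable, by = NULL,
                               times = c(12, 36, 60)) {
  strata <- if (is.null(by)) list(all = cohort) else {
    if (!by %in% names(cohort)) {
      stop_medroute(sprintf("unknown column '%s'", by), "medroute_input_error")
    }
    split(cohort, cohort[[by]], drop = TRUE)
  }
  out <- lapply(names(strata), function(s) {
    cur <- pohar_perme(strata[[s]], lifetable, grid = 0:max(times))
    i <- match(times, cur$time)
    data.frame(stratum = s, time = times, estimate = cur$estimate[i],
               variance = cur$variance[i], se = sqrt(cur$variance[i]),
               n_risk = cur$n_risk[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
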