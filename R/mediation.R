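#' Conditional-window death outcome
#'
#' Converts follow-up time and vital status into the binary outcome for one
#' conditional window: patients at risk are those alive at the window start;
#' Y = 1 iff the death month falls in the half-open interval
#' (start, end]. Defaults follow the three-window layout (0,12], (12,36],
#' (36,60] months: death within 12 months, within 36 given 12-month
#' survival, within 60 given 36-month survival.
#'
#' @param cohort cohort data.frame.
#' @param window window index 1, 2, 3, or a numeric `c(start, end)` pair.
#' @param admin_censor_month horizon used to derive the default bounds.
#' @return list of class `conditional_outcome`: `window`, `bounds`,
#'   `at_risk` (logical per patient), `y` (0/1, `NA` where not at risk).
#' @export
make_conditional_outcome <- function(cohort, window, admin_censor_month = 60) {
  if (length(window) == 1 && window %in% 1:3) {
    bounds <- window_bounds(admin_censor_month)[window, ]
    widx <- as.integer(window)
  } else if (length(window) == 2) {
    bounds <- c(start = window[1], end = window[2])
    widx <- NA_integer_
  } else {
    stop_medroute("window must be 1, 2, 3 or a (start, end) pair",
                  "medroute_input_error")
  }
  if (bounds[2] <= bounds[1]) {
    stop_medroute("window bounds must be increasing", "medroute_input_error")
  }
  fu <- cohort$follow_up_months
  at_risk <- fu > bounds[1]
  y <- ifelse(at_risk,
              as.integer(cohort$dead == 1 & fu <= bounds[2]),
              NA_integer_)
  structure(list(window = widx, bounds = bounds, at_risk = at_risk, y = y),
            class = "conditional_outcome")
}

#' Single stochastic imputation of the missing diagnostic route
#'
#' Fits a logistic imputation model for the mediator on exposure,
#' confounders and the window outcome (all analysis variables enter the
#' imputation model), using complete cases, and replaces each missing
#' mediator value with one Bernoulli draw from its fitted probability.
#' Deterministic given the seed.
#'
#' @param data data.frame with columns `comorbidity`, the confounders,
#'   `m` (0/1/NA mediator) and `y` (0/1 outcome).
#' @param seed integer seed for the single draw.
#' @return the input data with `m` completed and attributes `n_imputed`.
#' @export
impute_missing_mediator <- function(data, seed) {
  if (all(is.na(data$m))) {
    stop_medroute("cannot impute: all mediator values are missing",
                  "medroute_input_error")
  }
  miss <- is.na(data$m)
  if (!any(miss)) {
    attr(data, "n_imputed") <- 0L
    return(data)
  }
  Xc <- design_C(data)
  Xi <- cbind(1, data$comorbidity, Xc, data$y)
  fit <- fit_logit(Xi[!miss, , drop = FALSE], data$m[!miss])
  p <- as.vector(expit(Xi[miss, , drop = FALSE] %*% fit$coefficients))
  set.seed(as.integer(seed))
  data$m[miss] <- stats::rbinom(sum(miss), 1, p)
  attr(data, "n_imputed") <- sum(miss)
  data
}

# ---- internal estimation core -------------------------------------------
# Operates on raw vectors/matrices so the bootstrap can re-run it cheaply.
# A: exposure 0/1; M: mediator 0/1 with NA; Y: window outcome 0/1;
# Xc: confounder design matrix. Returns the three counterfactual risks.
gcomp_core <- function(A, M, Y, Xc, mc_draws, seeds, mode = "mc",
                       starts = list()) {
  miss <- is.na(M)
  imp <- NULL
  if (any(miss)) {
    if (all(miss)) {
      stop_medroute("cannot impute: all mediator values are missing",
                    "medroute_input_error")
    }
    Xi <- cbind(1, A, Xc, Y)
    imp <- fit_logit(Xi[!miss, , drop = FALSE], M[!miss], start = starts$imp)
    p <- as.vector(expit(Xi[miss, , drop = FALSE] %*% imp$coefficients))
    set.seed(seeds[1])
    M[miss] <- stats::rbinom(sum(miss), 1, p)
  }
  mm <- fit_logit(cbind(1, A, Xc), M, start = starts$mm)
  om <- fit_logit(cbind(1, A, M, A * M, Xc), Y, start = starts$om)
  risk <- function(a, a_star, seed) {
    gcomp_risk_core(mm$coefficients, om$coefficients, Xc, a, a_star,
                    mc_draws, seed, mode)
  }
  list(p11 = risk(1, 1, seeds[2]), p10 = risk(1, 0, seeds[3]),
       p00 = risk(0, 0, seeds[4]),
       n_imputed = sum(miss), mediator_model = mm, outcome_model = om,
       imputation_model = imp)
}

gcomp_risk_core <- function(mm_coef, om_coef, Xc, a, a_star, mc_draws, seed,
                            mode = c("mc", "closed_form")) {
  mode <- match.arg(mode)
  if (mode == "mc" && mc_draws < 1) {
    stop_medroute("mc_draws must be at least 1", "medroute_input_error")
  }
  pm <- as.vector(expit(mm_coef[1] + mm_coef[2] * a_star +
                          Xc %*% mm_coef[-(1:2)]))
  eta_c <- as.vector(Xc %*% om_coef[-(1:4)])
  p_m1 <- expit(om_coef[1] + om_coef[2] * a + om_coef[3] + om_coef[4] * a + eta_c)
  p_m0 <- expit(om_coef[1] + om_coef[2] * a + eta_c)
  if (mode == "mc") {
    set.seed(as.integer(seed))
    # number of M=1 draws per subject out of mc_draws Bernoulli(pm) draws;
    # the outcome prediction depends on M only through M in {0,1}, so the
    # per-subject Monte Carlo average is (k/mc)*p(M=1) + (1-k/mc)*p(M=0)
    k <- stats::rbinom(length(pm), mc_draws, pm)
    share <- k / mc_draws
  } else {
    share <- pm
  }
  mean(share * p_m1 + (1 - share) * p_m0)
}

#' Counterfactual risk by Monte Carlo g-computation
#'
#' Estimates the marginal nested counterfactual risk
#' `P(Y_{a, M_{a*}} = 1)`: for each subject, mediator values are drawn from
#' the fitted mediator model at exposure `a_star` and the fitted outcome
#' model is evaluated at exposure `a` with those draws, averaging over
#' `mc_draws` draws and all subjects. `mode = "closed_form"` replaces the
#' Monte Carlo average over mediator draws by its exact expectation
#' (the mediator is binary, so the expectation has two terms); it is the
#' infinite-draw limit and is deterministic.
#'
#' @param mediator_model,outcome_model fits as returned inside
#'   [estimate_natural_effects()] (lists with `coefficients`; mediator model
#'   terms `(1, A, C)`, outcome model terms `(1, A, M, A*M, C)`).
#' @param data data.frame of the at-risk analysis set (confounder columns).
#' @param a,a_star exposure values in `{0, 1}` for the outcome and mediator
#'   legs of the nested counterfactual.
#' @param mc_draws Monte Carlo mediator draws per subject.
#' @param seed integer seed.
#' @param mode `"mc"` (default) or `"closed_form"`.
#' @return scalar risk estimate.
#' @export
gcomp_counterfactual_risk <- function(mediator_model, outcome_model, data,
                                      a, a_star, mc_draws = 50, seed = 1,
                                      mode = "mc") {
  if (!all(c(a, a_star) %in% c(0, 1))) {
    stop_medroute("a and a_star must be 0 or 1", "medroute_input_error")
  }
  gcomp_risk_core(mediator_model$coefficients, outcome_model$coefficients,
                  design_C(data), a, a_star, mc_draws, seed, mode)
}

#' Closed-form conditional natural effect odds ratios
#'
#' Evaluates the conditional natural direct and indirect effect odds ratios
#' implied by the natural effect model
#' `logit E[Y_{a, M_{a*}} | C] = b0 + b1*a + b2*a* + b3.C + b4*a*a* +
#' b5.(a*C) + b6.(a**C)`:
#' NDE OR = `exp((b1 + b4*a_star + b5.C) * (a - a_star))` and
#' NIE OR = `exp((b2 + b4*a + b6.C) * (a - a_star))`; their product is the
#' conditional total effect odds ratio. These conditional expressions are a
#' verification surface alongside the marginal g-computation estimator.
#'
#' @param coef list with elements `b1`, `b2`, `b4` (scalars) and `b5`, `b6`
#'   (vectors over the confounder design, or scalar 0).
#' @param a,a_star exposure values in `{0, 1}`.
#' @param C confounder design vector (matching `b5`/`b6`), or 0.
#' @return positive scalar odds ratio.
#' @export
nde_or_closed_form <- function(coef, a, a_star, C = 0) {
  check_ne_coef(coef, C)
  exp((coef$b1 + coef$b4 * a_star + sum(coef$b5 * C)) * (a - a_star))
}

#' @rdname nde_or_closed_form
#' @export
nie_or_closed_form <- function(coef, a, a_star, C = 0) {
  check_ne_coef(coef, C)
  exp((coef$b2 + coef$b4 * a + sum(coef$b6 * C)) * (a - a_star))
}

check_ne_coef <- function(coef, C) {
  for (nm in c("b1", "b2", "b4")) {
    if (is.null(coef[[nm]])) {
      stop_medroute(sprintf("natural effect coefficients missing '%s'", nm),
                    "medroute_input_error")
    }
  }
  for (nm in c("b5", "b6")) {
    v <- coef[[nm]]
    if (!is.null(v) && length(v) > 1 && length(v) != length(C)) {
      stop_medroute(sprintf("dimension mismatch between '%s' and C", nm),
                    "medroute_input_error")
    }
  }
  invisible(TRUE)
}

#' Proportion mediated on the odds-ratio scale
#'
#' Transforms the natural direct and indirect effect odds ratios into the
#' proportion of the total effect transmitted through the mediator:
#' `PM = OR_NDE * (OR_NIE - 1) / (OR_NDE * OR_NIE - 1)`. Undefined when the
#' total effect is null (`OR_NDE * OR_NIE = 1`): in that case the function
#' returns `NA` with a warning rather than a number.
#'
#' @param nde_or,nie_or positive odds ratios.
#' @param tol tolerance for declaring the denominator zero.
#' @return scalar proportion (0 = nothing mediated, 1 = fully mediated).
#' @export
proportion_mediated <- function(nde_or, nie_or, tol = 1e-12) {
  if (any(c(nde_or, nie_or) <= 0)) {
    stop_medroute("odds ratios must be positive", "medroute_input_error")
  }
  denom <- nde_or * nie_or - 1
  if (abs(denom) < tol) {
    warning("proportion mediated undefined: total effect is null")
    return(NA_real_)
  }
  nde_or * (nie_or - 1) / denom
}

#' Estimate marginal natural effects for one conditional window
#'
#' The full per-window pipeline: restrict to patients alive at the window
#' start; singly impute missing mediator values; fit the logistic mediator
#' model `M ~ A + C` and outcome model `Y ~ A + M + A:M + C`; compute the
#' three counterfactual risks `p(1,1)`, `p(1,0)`, `p(0,0)` by Monte Carlo
#' g-computation; convert to marginal odds `o(a, a*) = p / (1 - p)` and
#' report TCE = o(1,1)/o(0,0), NDE = o(1,0)/o(0,0), NIE = o(1,1)/o(1,0) and
#' the proportion mediated. TCE = NDE x NIE holds to machine precision by
#' construction (telescoping product). Percentile bootstrap intervals
#' resample at-risk patients with replacement and re-run the whole pipeline
#' (including imputation) per replicate.
#'
#' All models are refit within each window on its surviving subset; no
#' coefficients are shared across windows. Sub-seeds for imputation, the
#' three risk evaluations and the bootstrap derive from `config$seed` via
#' [split_seed()].
#'
#' @param cohort cohort data.frame.
#' @param window window index 1, 2 or 3.
#' @param config list: `mc_draws` (default 50), `n_bootstrap` (default 1000;
#'   0 skips the bootstrap), `seed` (mandatory), `min_events` (default 10),
#'   `mode` (`"mc"` or `"closed_form"`), `conf_level` (default 0.95),
#'   `admin_censor_month` (default 60).
#' @return object of class `natural_effects`: window, n_at_risk, n_events,
#'   n_imputed, `tce_or`, `nde_or`, `nie_or`, `pm`, risks, per-quantity
#'   percentile `ci`, bootstrap failure count, seeds, estimator tag.
#' @export
estimate_natural_effects <- function(cohort, window, config = list()) {
  cfg <- utils::modifyList(list(mc_draws = 50, n_bootstrap = 1000,
                                min_events = 10, mode = "mc",
                                conf_level = 0.95, admin_censor_month = 60),
                           config)
  if (is.null(cfg$seed)) config_error("config$seed is mandatory")
  co <- make_conditional_outcome(cohort, window, cfg$admin_censor_month)
  dat <- cohort[co$at_risk, , drop = FALSE]
  Y <- co$y[co$at_risk]
  A <- dat$comorbidity
  M <- ifelse(is.na(dat$route), NA_integer_,
              as.integer(dat$route == "emergency"))
  Xc <- design_C(dat)
  n_events <- sum(Y)
  if (n_events < cfg$min_events) {
    stop_medroute(sprintf(
      "only %d events in window %s (< min_events = %d); refusing to fit",
      n_events, paste(window, collapse = "-"), cfg$min_events),
      "medroute_input_error")
  }
  seeds <- split_seed(cfg$seed, 5)
  core <- gcomp_core(A, M, Y, Xc, cfg$mc_draws, seeds[1:4], cfg$mode)
  point <- risks_to_effects(core)
  ci <- NULL; n_boot_failed <- 0L
  if (cfg$n_bootstrap > 0) {
    bs <- bootstrap_core(A, M, Y, Xc, cfg, seeds[5])
    ci <- bs$ci
    n_boot_failed <- bs$n_failed
  }
  structure(
    c(list(window = co$window, bounds = co$bounds,
           n_at_risk = nrow(dat), n_events = n_events,
           n_imputed = core$n_imputed,
           risks = unlist(core[c("p11", "p10", "p00")])),
      point,
      list(ci = ci, n_bootstrap = cfg$n_bootstrap,
           n_boot_failed = n_boot_failed, mc_draws = cfg$mc_draws,
           seed = cfg$seed, estimator = paste0("gcomp-", cfg$mode),
           mediator_model = core$mediator_model,
           outcome_model = core$outcome_model)),
    class = "natural_effects"
  )
}

risks_to_effects <- function(core) {
  odds <- function(p) p / (1 - p)
  nde <- odds(core$p10) / odds(core$p00)
  nie <- odds(core$p11) / odds(core$p10)
  list(tce_or = odds(core$p11) / odds(core$p00), nde_or = nde, nie_or = nie,
       pm = suppressWarnings(proportion_mediated(nde, nie)))
}

bootstrap_core <- function(A, M, Y, Xc, cfg, seed) {
  B <- cfg$n_bootstrap
  if (B < 2) stop_medroute("n_bootstrap must be at least 2", "medroute_input_error")
  n <- length(A)
  rep_seeds <- matrix(split_seed(seed, 5L * B), ncol = 5)
  est <- matrix(NA_real_, B, 4, dimnames = list(NULL, c("tce", "nde", "nie", "pm")))
  # warm starts from the full-data fits: replicate likelihoods are close to
  # the full-data one, so Newton converges in a couple of steps
  full <- gcomp_core(A, M, Y, Xc, 1, c(1L, 1L, 1L, 1L), "closed_form")
  starts <- list(imp = full$imputation_model$coefficients,
                 mm = full$mediator_model$coefficients,
                 om = full$outcome_model$coefficients)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b, 1])
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      core <- gcomp_core(A[idx], M[idx], Y[idx], Xc[idx, , drop = FALSE],
                         cfg$mc_draws, rep_seeds[b, 2:5], cfg$mode,
                         starts = starts)
      eff <- risks_to_effects(core)
      c(eff$tce_or, eff$nde_or, eff$nie_or, eff$pm)
    }, medroute_fit_error = function(e) rep(NA_real_, 4))
    est[b, ] <- res
  }
  failed <- apply(est[, 1:3, drop = FALSE], 1, anyNA)
  n_failed <- sum(failed)
  if (n_failed > 0.05 * B) {
    stop_medroute(sprintf("%d of %d bootstrap replicates failed to converge",
                          n_failed, B), "medroute_fit_error")
  }
  probs <- c((1 - cfg$conf_level) / 2, 1 - (1 - cfg$conf_level) / 2)
  ok <- est[!failed, , drop = FALSE]
  ci <- apply(ok, 2, stats::quantile, probs = probs, na.rm = TRUE, names = FALSE)
  rownames(ci) <- c("low", "high")
  list(ci = ci, n_failed = n_failed, replicates = ok)
}

#' Percentile bootstrap intervals for the natural effects
#'
#' Standalone access to the bootstrap used by [estimate_natural_effects()]:
#' nonparametric resampling of the window's at-risk patients with full
#' re-estimation (imputation, both models, g-computation) per replicate.
#' Replicates whose model fits fail to converge are dropped and counted; an
#' error is raised if more than 5% fail.
#'
#' @inheritParams estimate_natural_effects
#' @return list with `ci` (2 x 4 matrix: low/high for tce, nde, nie, pm),
#'   `replicates` (successful replicate estimates), `n_failed`.
#' @export
bootstrap_natural_effects <- function(cohort, window, config = list()) {
  cfg <- utils::modifyList(list(mc_draws = 50, n_bootstrap = 1000,
                                min_events = 10, mode = "mc",
                                conf_level = 0.95, admin_censor_month = 60),
                           config)
  if (is.null(cfg$seed)) config_error("config$seed is mandatory")
  co <- make_conditional_outcome(cohort, window, cfg$admin_censor_month)
  dat <- cohort[co$at_risk, , drop = FALSE]
  M <- ifelse(is.na(dat$route), NA_integer_,
              as.integer(dat$route == "emergency"))
  seeds <- split_seed(cfg$seed, 5)
  bootstrap_core(dat$comorbidity, M, co$y[co$at_risk], design_C(dat), cfg,
                 seeds[5])
}

#' @export
print.natural_effects <- function(x, ...) {
  cat(sprintf("<natural effects, window %s (%g, %g] months>\n",
              ifelse(is.na(x$window), "custom", x$window),
              x$bounds[1], x$bounds[2]))
  cat(sprintf("  at risk %d, events %d, imputed routes %d [%s]\n",
              x$n_at_risk, x$n_events, x$n_imputed, x$estimator))
  fmt <- function(nm, v) {
    ci <- if (!is.null(x$ci)) sprintf(" (%.3f-%.3f)", x$ci["low", nm], x$ci["high", nm]) else ""
    cat(sprintf("  %-4s %.3f%s\n", toupper(nm), v, ci))
  }
  fmt("tce", x$tce_or); fmt("nde", x$nde_or); fmt("nie", x$nie_or)
  pmci <- if (!is.null(x$ci)) sprintf(" (%.1f%%-%.1f%%)", 100 * x$ci["low", "pm"], 100 * x$ci["high", "pm"]) else ""
  cat(sprintf("  PM   %.1f%%%s\n", 100 * x$pm, pmci))
  invisible(x)
}
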