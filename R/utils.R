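#' @keywords internal
#' @useDynLib medroute, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Confounder design columns used by every model in the package:
# age per decade centred at 70, female indicator, deprivation quintile
# contrasts against "least deprived", ethnicity "other" indicator.
C_TERMS <- c("age10", "female", "dep2", "dep3", "dep4", "dep5", "ethother")

expit <- stats::plogis

#' Derive a stream of sub-seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed; nested
#' procedures (imputation, Monte Carlo mediator draws, bootstrap replicates)
#' receive sub-seeds produced by this one documented rule, so a run is fully
#' reproducible from the master seed alone.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds required.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  out <- sample.int(2147483646L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

stop_medroute <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "medroute_error")))
}

config_error <- function(msg) stop_medroute(msg, "medroute_config_error")

# Build the confounder design matrix from patient-level columns.
# `df` needs age_years, sex, deprivation, ethnicity.
design_C <- function(df) {
  out <- cbind(
    age10    = (df$age_years - 70) / 10,
    female   = as.numeric(df$sex == "female"),
    dep2     = as.numeric(df$deprivation == 2L),
    dep3     = as.numeric(df$deprivation == 3L),
    dep4     = as.numeric(df$deprivation == 4L),
    dep5     = as.numeric(df$deprivation == 5L),
    ethother = as.numeric(df$ethnicity == "other")
  )
  storage.mode(out) <- "double"
  out
}

# Fast logistic fit on a prebuilt design matrix: Newton-Raphson with step
# halving, compiled (src/logit_newton.cpp). Equivalent to the glm.fit IRLS
# solution (the test suite checks agreement with stats::glm) but cheap
# enough that the bootstrap can afford full re-estimation per replicate.
# `start` warm-starts replicate fits at the full-data coefficients.
fit_logit <- function(X, y, max_iter = 50L, tol = 1e-10, start = NULL) {
  if (is.null(start)) start <- numeric(ncol(X))
  fit <- .logit_newton(X, as.numeric(y), start, as.integer(max_iter), tol)
  beta <- as.vector(fit$coefficients)
  if (fit$singular) {
    stop_medroute("logistic model failed: singular information (separation or collinearity)",
                  "medroute_fit_error")
  }
  if (!fit$converged || any(abs(beta) > 30)) {
    stop_medroute(
      sprintf("logistic model did not converge (max|coef|=%.3g); possible separation",
              max(abs(beta))),
      "medroute_fit_error"
    )
  }
  list(coefficients = beta, converged = TRUE, deviance = fit$deviance)
}
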