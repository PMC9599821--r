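#' Cross-tabulate a cohort characteristic against comorbidity status
#'
#' Builds the Table-1 style k x 2 contingency table of a categorical cohort
#' variable against the binary exposure, with within-column percentages.
#' Missing values of the variable are tabulated in a separate `"missing"`
#' row which is excluded from percentages and from any odds-ratio
#' computation (complete-case convention for the mediator).
#'
#' @param cohort a cohort data.frame (see [generate_cohort()] / [read_cohort()]).
#' @param variable name of a categorical column (e.g. `"route"`, `"sex"`,
#'   `"deprivation"`).
#' @param exposure name of the binary 0/1 exposure column (default
#'   `"comorbidity"`).
#' @return a `crosstab`: list with `counts` (k x 2 matrix, exposure levels in
#'   columns `unexposed`/`exposed`), `percent` (within-column percentages over
#'   non-missing rows), `missing` (length-2 count vector or NULL), `variable`.
#' @export
crosstab <- function(cohort, variable, exposure = "comorbidity") {
  if (!nrow(cohort)) stop_medroute("cannot tabulate an empty cohort", "medroute_input_error")
  for (col in c(variable, exposure)) {
    if (!col %in% names(cohort)) {
      stop_medroute(sprintf("unknown column '%s'", col), "medroute_input_error")
    }
  }
  v <- cohort[[variable]]
  e <- cohort[[exposure]]
  if (!all(e %in% c(0, 1))) {
    stop_medroute(sprintf("exposure column '%s' must be binary 0/1", exposure),
                  "medroute_input_error")
  }
  miss <- is.na(v)
  tab <- table(factor(v[!miss]), factor(e[!miss], levels = c(0, 1)))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), c("unexposed", "exposed")))
  pct <- sweep(counts, 2, colSums(counts), "/") * 100
  missing <- if (any(miss)) {
    m <- table(factor(e[miss], levels = c(0, 1)))
    stats::setNames(as.integer(m), c("unexposed", "exposed"))
  }
  structure(list(counts = counts, percent = pct, missing = missing,
                 variable = variable), class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("<crosstab: %s by exposure>\n", x$variable))
  show <- cbind(x$counts,
                round(x$percent, 1))
  colnames(show) <- c("unexposed", "exposed", "unexposed %", "exposed %")
  print(show)
  if (!is.null(x$missing)) {
    cat("missing:", paste(names(x$missing), x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

as_table2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    stop_medroute("2x2 cells must be non-negative integers", "medroute_input_error")
  }
  matrix(c(a, c, b, d), 2, 2,
         dimnames = list(c("event", "nonevent"), c("exposed", "unexposed")))
}

#' Wald odds ratio for a 2x2 table
#'
#' Computes the cross-product odds ratio `(a*d)/(b*c)` with the Wald
#' confidence interval `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and
#' the Wald p-value from the log-OR z statistic. Cells are
#' (a, b, c, d) = (exposed-event, exposed-nonevent, unexposed-event,
#' unexposed-nonevent); here "event" is usually "has at least one
#' comorbidity" so the OR reads "odds of comorbidity at this level versus
#' the reference level".
#'
#' @param a,b,c,d cell counts, all strictly positive.
#' @param conf_level confidence level (default 0.95).
#' @return an `or_estimate`: list with `or`, `ci_low`, `ci_high`, `p_value`,
#'   `method`.
#' @export
odds_ratio_wald <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop_medroute("negative cell count", "medroute_input_error")
  if (any(cells == 0)) {
    stop_medroute(
      "zero cell in 2x2 table: the plain Wald odds ratio is undefined; apply a continuity correction explicitly if intended",
      "medroute_input_error")
  }
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(or = exp(log_or),
         ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
         p_value = 2 * stats::pnorm(-abs(log_or / se)),
         method = "wald"),
    class = "or_estimate"
  )
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f-%.2f), p = %.3g [%s]\n",
              x$or, x$ci_low, x$ci_high, x$p_value, x$method))
  invisible(x)
}

#' Pearson chi-squared test of association for a k x 2 count table
#'
#' Without continuity correction, df = k - 1.
#'
#' @param counts k x 2 matrix of counts (e.g. `crosstab(...)$counts`).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi2_test <- function(counts) {
  counts <- as.matrix(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop_medroute("chi-squared test undefined: an expected cell count is zero",
                  "medroute_input_error")
  }
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Odds ratio of comorbidity per 10-year increase in age
#'
#' Univariable logistic regression of the exposure on age/10; the
#' exponentiated slope is the Table-1 style "per decade" odds ratio.
#'
#' @param cohort cohort data.frame with `age_years` and the exposure column.
#' @param exposure binary exposure column name.
#' @param conf_level confidence level.
#' @return an `or_estimate`.
#' @export
age_or_per_decade <- function(cohort, exposure = "comorbidity",
                              conf_level = 0.95) {
  if (length(unique(cohort$age_years)) < 2) {
    stop_medroute("age odds ratio undefined: all patients share one age",
                  "medroute_input_error")
  }
  y <- cohort[[exposure]]
  if (length(unique(y)) < 2) {
    stop_medroute("both exposure levels must be present", "medroute_input_error")
  }
  X <- cbind(1, cohort$age_years / 10)
  fit <- fit_logit(X, y)
  # Wald SE from the observed information at the fit
  p <- as.vector(expit(X %*% fit$coefficients))
  info <- crossprod(X, X * (p * (1 - p)))
  se <- sqrt(diag(solve(info)))[2]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- fit$coefficients[2]
  structure(
    list(or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
         p_value = 2 * stats::pnorm(-abs(b / se)),
         method = "logistic per-decade"),
    class = "or_estimate"
  )
}

#' Table-1 style descriptive summary of a cohort
#'
#' Cross-tabulations of sex, deprivation, ethnicity and diagnostic route by
#' comorbidity status, with univariable Wald odds ratios (each level against
#' its reference: male, least deprived, white, elective), chi-squared
#' p-values, and the per-decade age odds ratio. Route ORs use complete cases
#' (missing route tabulated separately).
#'
#' @param cohort a cohort data.frame.
#' @return a `descriptive_table`: data.frame with one row per variable level.
#' @export
describe_cohort <- function(cohort) {
  rows <- list()
  add_var <- function(variable) {
    ct <- crosstab(cohort, variable)
    k <- nrow(ct$counts)
    p_chi <- chi2_test(ct$counts)$p_value
    for (i in seq_len(k)) {
      orow <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      if (i > 1) {
        est <- odds_ratio_wald(ct$counts[i, "exposed"], ct$counts[i, "unexposed"],
                               ct$counts[1, "exposed"], ct$counts[1, "unexposed"])
        orow <- est[c("or", "ci_low", "ci_high")]
      }
      rows[[length(rows) + 1]] <<- data.frame(
        variable = variable, level = rownames(ct$counts)[i],
        n_no_comorbidity = ct$counts[i, "unexposed"],
        pct_no_comorbidity = ct$percent[i, "unexposed"],
        n_comorbidity = ct$counts[i, "exposed"],
        pct_comorbidity = ct$percent[i, "exposed"],
        or = orow$or, ci_low = orow$ci_low, ci_high = orow$ci_high,
        chi2_p = if (i == 1) p_chi else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    if (!is.null(ct$missing)) {
      rows[[length(rows) + 1]] <<- data.frame(
        variable = variable, level = "missing",
        n_no_comorbidity = ct$missing["unexposed"], pct_no_comorbidity = NA_real_,
        n_comorbidity = ct$missing["exposed"], pct_comorbidity = NA_real_,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, chi2_p = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  for (v in c("sex", "deprivation", "ethnicity", "route")) add_var(v)
  age <- age_or_per_decade(cohort)
  rows[[length(rows) + 1]] <- data.frame(
    variable = "age", level = "per decade",
    n_no_comorbidity = sum(cohort$comorbidity == 0), pct_no_comorbidity = NA_real_,
    n_comorbidity = sum(cohort$comorbidity == 1), pct_comorbidity = NA_real_,
    or = age$or, ci_low = age$ci_low, ci_high = age$ci_high,
    chi2_p = NA_real_, stringsAsFactors = FALSE
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("descriptive_table", "data.frame")
  out
}

# Plain-text Table-1 style rendering of a descriptive_table.
format_table1 <- function(tab) {
  fmt_n <- function(n, pct) {
    ifelse(is.na(pct), format(n, big.mark = ","),
           sprintf("%s (%.1f)", format(n, big.mark = ","), pct))
  }
  fmt_or <- function(or, lo, hi) {
    ifelse(is.na(or), "-", sprintf("%.2f (%.2f-%.2f)", or, lo, hi))
  }
  lines <- sprintf("%-14s %-12s %18s %18s %20s",
                   "variable", "level", "no comorbidity", "comorbidity", "OR (95% CI)")
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf(
      "%-14s %-12s %18s %18s %20s",
      tab$variable[i], tab$level[i],
      fmt_n(tab$n_no_comorbidity[i], tab$pct_no_comorbidity[i]),
      fmt_n(tab$n_comorbidity[i], tab$pct_comorbidity[i]),
      fmt_or(tab$or[i], tab$ci_low[i], tab$ci_high[i])))
  }
  lines
}

#' @export
print.descriptive_table <- function(x, ...) {
  cat(format_table1(x), sep = "\n")
  invisible(x)
}
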