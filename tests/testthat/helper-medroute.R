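# Fixtures are built in code: a hand-specified mini cohort for the
# conditional-outcome and survival tests, plus the published registry counts
# shipped as a plain-text fixture.

mini_cohort <- function(fu, dead, age = 70, sex = "male", dep = 1,
                        eth = "white", comorbidity = 0, route = "elective",
                        year = 2010) {
  n <- length(fu)
  data.frame(
    patient_id = seq_len(n),
    age_years = rep_len(age, n), sex = rep_len(sex, n),
    deprivation = rep_len(dep, n), ethnicity = rep_len(eth, n),
    comorbidity = rep_len(comorbidity, n), route = rep_len(route, n),
    follow_up_months = fu, dead = dead,
    diagnosis_year = rep_len(year, n), stringsAsFactors = FALSE
  )
}

zero_life_table <- function() generate_life_table(b = 0)

table1_counts <- function() {
  read.csv(system.file("extdata", "table1_counts.csv", package = "medroute"),
           stringsAsFactors = FALSE)
}

t1_cell <- function(counts, subtype, variable, level, col) {
  row <- counts$subtype == subtype & counts$variable == variable &
    counts$level == level
  counts[row, col]
}

# 2x2 helper returning the Wald OR of comorbidity at `level` vs `ref`
t1_or <- function(counts, subtype, variable, level, ref) {
  odds_ratio_wald(
    a = t1_cell(counts, subtype, variable, level, "n_comorbidity"),
    b = t1_cell(counts, subtype, variable, level, "n_no_comorbidity"),
    c = t1_cell(counts, subtype, variable, ref, "n_comorbidity"),
    d = t1_cell(counts, subtype, variable, ref, "n_no_comorbidity")
  )
}
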