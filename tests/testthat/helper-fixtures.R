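# Shared fixtures: tiny synthetic cohorts and their residualized form.

tiny_gen <- function(n_cn = 40, n_ad = 24, seed = 1, effect = 1,
                     mad_effect = 0.3, standardize = TRUE) {
  spec <- default_spec(n_cn = n_cn, n_ad = n_ad, effect = effect,
                       mad_effect = mad_effect)
  gen <- generate_cohort(spec, seed = seed)
  ref <- fit_reference_glm(gen$cohort)
  list(spec = spec, cohort = gen$cohort, truth = gen$truth, ref = ref,
       res = residualize(ref, gen$cohort, standardize = standardize))
}

# hand-built 3-subject cohort data frame with constant thickness 2.5 mm
toy_cohort_df <- function() {
  roi <- dk_roi_names()
  df <- data.frame(
    subject_id = c("S001", "S002", "S003"),
    diagnosis = c("CN", "CN", "AD"),
    visit_month = c(0, 0, 0),
    age = c(70, 75, 80),
    sex = c(0, 1, 0),
    education = c(16, 12, 14),
    icv = c(1.4e6, 1.6e6, 1.5e6)
  )
  for (r in roi) df[[r]] <- c(2.5, 2.6, 2.4)
  df
}

expect_rows_sum_to_one <- function(m, tol = 1e-12) {
  expect_true(all(abs(rowSums(m) - 1) <= tol))
}

roi_matrix_for_test <- function(x) as.matrix(x[, dk_roi_names()])

# constant-thickness cohort with one 24-month follow-up per subject
two_visit_rate_cohort <- function(th0 = 2.5, th24 = 2.3) {
  df <- toy_cohort_df()
  fup <- transform(df, visit_month = 24, age = age + 2)
  for (r in dk_roi_names()) {
    df[[r]] <- th0
    fup[[r]] <- th24
  }
  as_cohort(rbind(df, fup))
}

att_label <- function(fit, ref, row) {
  attribute_followup(fit, ref, row)$subtype
}
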