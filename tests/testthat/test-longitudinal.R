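# Annual rates, follow-up attribution, transition tables.

two_visit_cohort <- function(th0 = 2.5, th24 = 2.3) {
  df <- toy_cohort_df()
  fup <- transform(df, visit_month = 24, age = age + 2)
  for (r in dk_roi_names()) {
    df[[r]] <- th0
    fup[[r]] <- th24
  }
  as_cohort(rbind(df, fup))
}

test_that("annual rate uses the visit interval exactly", {
  rates <- annual_rate_of_change(two_visit_cohort(2.5, 2.3))
  expect_equal(unique(rates$rate), -0.1)
  expect_equal(unique(rates$months), 24)
  flat <- annual_rate_of_change(two_visit_cohort(2.5, 2.5))
  expect_equal(unique(flat$rate), 0)
})

test_that("with both follow-ups the longer interval wins by default", {
  df <- toy_cohort_df()
  v12 <- transform(df, visit_month = 12, age = age + 1)
  v24 <- transform(df, visit_month = 24, age = age + 2)
  for (r in dk_roi_names()) {
    v12[[r]] <- df[[r]] - 0.3
    v24[[r]] <- df[[r]] - 0.2
  }
  cohort <- as_cohort(rbind(df, v12, v24))
  latest <- annual_rate_of_change(cohort)
  expect_equal(unique(latest$months), 24)
  expect_equal(unique(latest$rate), -0.1)
  earliest <- annual_rate_of_change(cohort, use = "earliest")
  expect_equal(unique(earliest$months), 12)
  expect_equal(unique(earliest$rate), -0.3)
})

test_that("attribution of unmodified baseline data is idempotent", {
  g <- tiny_gen(n_cn = 50, n_ad = 30, seed = 41)
  fit <- fit_moe(g$res, K = 2, seed = 13)
  att <- attribute_followup(fit, g$ref, baseline(g$cohort))
  ad <- att[match(fit$ad_subject_id, att$subject_id), ]
  expect_identical(ad$subtype, fit$subtype)
  m <- as.matrix(ad[, paste0("m", 1:2)])
  expect_equal(unname(m), unname(fit$membership), tolerance = 1e-12)
  expect_rows_sum_to_one(m, tol = 1e-9)
})

test_that("a trajectory moved onto another pattern switches label", {
  spec <- planted_k_spec(2, effect = 3, n_cn = 60, n_ad = 40)
  gen <- generate_cohort(spec, seed = 42)
  ref <- fit_reference_glm(gen$cohort)
  res <- residualize(ref, gen$cohort)
  fit <- fit_moe(res, K = 2, seed = 4)
  # take a subject of pattern 1 and overwrite its follow-up thickness
  # with the atrophy signature of pattern 2
  sub <- gen$truth$subject_id[gen$truth$subtype_index == 1][1]
  row <- gen$cohort[gen$cohort$subject_id == sub, ]
  base_label <- att_label(fit, ref, row)
  moved <- row
  moved$visit_month <- 24
  moved[, dk_roi_names()] <- moved[, dk_roi_names()] +
    spec$noise_sd * spec$patterns[[1]]$atrophy -
    spec$noise_sd * spec$patterns[[2]]$atrophy
  fup_label <- att_label(fit, ref, moved)
  expect_false(base_label == fup_label)
})

test_that("transition tables conserve subjects and count switches", {
  b <- setNames(c(1, 1, 1, 2, 2), paste0("S", 1:5))
  stable <- transition_table(b, b, K = 2)
  expect_identical(unclass(stable)[1, 1], 3L)
  expect_identical(unclass(stable)[2, 2], 2L)
  expect_identical(sum(stable == 0), 2L)
  f <- b
  f[["S1"]] <- 2
  one <- transition_table(b, f, K = 2)
  expect_identical(unclass(one)[1, 2], 1L)
  # random labels vs an independent cross-tabulation oracle
  withr::with_seed(7, {
    bl <- setNames(sample(1:3, 50, TRUE), paste0("R", 1:50))
    fl <- setNames(sample(1:3, 40, TRUE), paste0("R", 1:40))
  })
  tt <- transition_table(bl, fl, K = 3)
  oracle <- table(factor(bl[names(fl)], levels = 1:3),
                  factor(fl, levels = 1:3))
  expect_identical(as.integer(unclass(tt)), as.integer(oracle))
  expect_identical(attr(tt, "n"), 40L)
  expect_identical(attr(tt, "excluded"), 10L)
  expect_identical(sum(tt), 40L)
  expect_identical(sum(tidy(tt)$n), 40L)
})
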