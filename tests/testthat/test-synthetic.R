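# Synthetic cohort generator: study conditions, determinism, planted
# effects, longitudinal decline.

test_that("default pattern proportions and apportionment match design", {
  spec <- default_spec()
  props <- vapply(spec$patterns, `[[`, 1, "proportion")
  expect_equal(sum(props), 1)
  gen <- generate_cohort(spec, seed = 1)
  counts <- table(factor(gen$truth$subtype,
                         levels = c("osad", "ltad", "mad", "dad")))
  expect_identical(as.integer(counts), c(56L, 43L, 31L, 62L))
  expect_identical(nrow(gen$cohort), 420L)
})

test_that("the spec serializes and round-trips exactly", {
  spec <- default_spec()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_spec(spec, f)
  back <- read_spec(f)
  expect_equal(unclass(back), unclass(spec), tolerance = 0)
})

test_that("generation is bit-identical under a fixed seed", {
  g1 <- generate_cohort(default_spec(n_cn = 30, n_ad = 20), seed = 9)
  g2 <- generate_cohort(default_spec(n_cn = 30, n_ad = 20), seed = 9)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth, g2$truth)
})

test_that("planted atrophy reproduces the requested effect size", {
  spec <- default_spec()
  gen <- generate_cohort(spec, seed = 10)
  ref <- fit_reference_glm(gen$cohort)
  res <- residualize(ref, gen$cohort)
  dad <- gen$truth$subject_id[gen$truth$subtype == "dad"]
  affected <- dk_roi_names()[spec$patterns$dad$atrophy > 0]
  X_dad <- as.matrix(res[res$subject_id %in% dad, affected])
  X_cn <- as.matrix(res[res$diagnosis == "CN", affected])
  d <- (colMeans(X_dad) - colMeans(X_cn)) /
    sqrt((apply(X_dad, 2, var) + apply(X_cn, 2, var)) / 2)
  expect_lt(max(abs(d + 1)), 0.45)      # per-ROI Cohen's d near -1
  expect_lt(abs(mean(d) + 1), 0.2)      # and -1 on average
})

test_that("zero planted effects leave CN and AD exchangeable", {
  gen <- generate_cohort(default_spec(n_cn = 100, n_ad = 100, effect = 0,
                                      mad_effect = 0), seed = 11)
  res <- residualize(fit_reference_glm(gen$cohort), gen$cohort)
  m <- rowMeans(as.matrix(res[, dk_roi_names()]))
  p <- t.test(m ~ res$diagnosis)$p.value
  expect_gt(p, 0.001)
})

test_that("longitudinal decline follows pattern rates", {
  spec <- default_spec(n_cn = 30, n_ad = 60)
  gen <- generate_cohort(spec, seed = 12)
  long <- generate_longitudinal(spec, gen$cohort, gen$truth, seed = 13,
                                attrition = c(`12` = 0, `24` = 0))
  expect_identical(nrow(long), 30L + 60L * 3L)   # all AD keep both visits
  rates <- annual_rate_of_change(long)
  per_subj <- tapply(rates$rate, rates$subject_id, mean)
  truth <- setNames(gen$truth$subtype, gen$truth$subject_id)
  mean_rate <- tapply(per_subj, truth[names(per_subj)], mean)
  expect_lt(mean_rate[["dad"]], mean_rate[["mad"]])
})

test_that("zero rates, noise and aging give identical follow-ups", {
  spec <- default_spec(n_cn = 12, n_ad = 10,
                       rates = c(osad = 0, ltad = 0, mad = 0, dad = 0))
  spec$followup_noise_sd <- 0
  spec$covariate_effects[["age"]] <- 0
  gen <- generate_cohort(spec, seed = 14)
  long <- generate_longitudinal(spec, gen$cohort, gen$truth, seed = 15,
                                visits = 12, attrition = c(`12` = 0))
  b <- as.matrix(baseline(long)[long$diagnosis[long$visit_month == 0] == "AD",
                                dk_roi_names()])
  f <- as.matrix(long[long$visit_month == 12, dk_roi_names()])
  expect_equal(unname(f), unname(b), tolerance = 1e-12)
})

test_that("planted-K specs have disjoint, orthogonal supports", {
  spec <- planted_k_spec(4, effect = 1.5, support = 10)
  A <- do.call(rbind, lapply(spec$patterns, `[[`, "atrophy"))
  expect_identical(dim(A), c(4L, 68L))
  expect_equal(max(abs(A %*% t(A) - diag(diag(A %*% t(A))))), 0)
  expect_equal(sum(vapply(spec$patterns, `[[`, 1, "proportion")), 1)
  expect_error(generate_cohort(planted_k_spec(4, n_ad = 3), seed = 1),
               "smaller than")
})
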