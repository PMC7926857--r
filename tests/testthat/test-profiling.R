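# Cross-sectional profiling statistics.

test_that("two-group ANOVA equals the squared pooled t statistic", {
  withr::with_seed(51, {
    x <- c(rnorm(20), rnorm(25, 0.5))
    g <- rep(c("a", "b"), c(20, 25))
  })
  a <- anova_groups(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(a$p.value, tt$p.value, tolerance = 1e-8)
  expect_identical(c(a$df1, a$df2), c(1, 43))
})

test_that("degenerate ANOVA inputs raise errors", {
  expect_error(anova_groups(rep(1, 10), rep(c("a", "b"), 5)),
               "zero variance")
  expect_error(anova_groups(rnorm(4), rep("a", 4)), "two groups")
  expect_error(anova_groups(rnorm(3), c("a", "a", "b")), "two subjects")
})

test_that("single-comparison Dunnett reduces to the pooled t-test", {
  withr::with_seed(52, {
    x <- c(rnorm(30), rnorm(30, 0.4))
    g <- rep(c("ctrl", "trt"), each = 30)
  })
  d <- dunnett_pairwise(x, g, control = "ctrl")
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_identical(nrow(d), 1L)
  expect_equal(d$p.adj, tt$p.value, tolerance = 0.002)
})

test_that("adjusted p-values never fall below raw ones", {
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      x <- rnorm(80)
      g <- sample(letters[1:4], 80, replace = TRUE)
    })
    d <- dunnett_pairwise(x, g, control = "a", seed = s)
    expect_true(all(d$p.adj >= d$p.raw))
    tk <- tukey_pairwise(x, g, seed = s)
    expect_true(all(tk$p.adj >= tk$p.raw))
    expect_identical(nrow(tk), 6L)
  }
  expect_error(dunnett_pairwise(rnorm(10), rep(c("a", "b"), 5), "zzz"),
               "not present")
})

test_that("a planted shift is detected by Dunnett with high power", {
  hits <- sapply(1:40, function(s) {
    withr::with_seed(200 + s, {
      x <- c(rnorm(50), rnorm(50, 1), rnorm(50))
      g <- rep(c("ctrl", "shift", "null"), each = 50)
    })
    d <- dunnett_pairwise(x, g, control = "ctrl", seed = s)
    d$p.adj[d$comparison == "shift - ctrl"] < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("chi-square without continuity correction is exact", {
  r <- chisq_categorical(matrix(c(10, 20, 20, 10), 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)
  expect_identical(r$df, 1L)
  prop <- chisq_categorical(matrix(c(10, 20, 30, 60), 2))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_identical(chisq_categorical(matrix(1:8, 2))$df, 3L)
})

test_that("abnormal proportions exclude missing and use strict bounds", {
  r <- abnormal_proportion(c(150, 200, NA), 192, "below")
  expect_identical(r$n_abnormal, 1L)
  expect_identical(r$n_observed, 2L)
  expect_equal(r$fraction, 0.5)
  boundary <- abnormal_proportion(c(192, 192), 192, "below")
  expect_identical(boundary$n_abnormal, 0L)
  above <- abnormal_proportion(c(93, 94, NA), 93, "above")
  expect_identical(above$n_abnormal, 1L)
  expect_error(abnormal_proportion(c(NA, NA), 192, "below"), "no observed")
  expect_identical(csf_thresholds()$abeta42$threshold, 192)
})

test_that("effect-size maps flag planted atrophy and only that", {
  g <- tiny_gen(n_cn = 228, n_ad = 60, seed = 53, effect = 0,
                mad_effect = 0)
  res <- g$res
  rois <- dk_roi_names()[11:20]
  ad_rows <- res$diagnosis == "AD"
  res[ad_rows, rois] <- res[ad_rows, rois] - 1   # plant -1 SD in 10 ROIs
  labels <- setNames(rep(1L, sum(ad_rows)), res$subject_id[ad_rows])
  es <- effect_size_map(res, labels)
  planted <- es$roi %in% rois
  expect_true(all(abs(es$cohens_d[planted]) >= 0.8))
  expect_true(all(es$flag[planted]))
  expect_identical(sum(es$flag[!planted]), 0L)
  expect_true(all(es$p.adj >= es$p.value))
})
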