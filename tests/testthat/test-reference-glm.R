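# CN-only covariate regression and residualization.

make_cn_cohort <- function(n = 200, beta_age = 0, sigma = 0, seed = 1,
                           base = 2.5) {
  withr::with_seed(seed, {
    roi <- dk_roi_names()
    df <- data.frame(
      subject_id = sprintf("C%03d", seq_len(n)),
      diagnosis = "CN", visit_month = 0,
      age = rnorm(n, 75, 6), sex = rbinom(n, 1, 0.5),
      education = rnorm(n, 15, 3), icv = rnorm(n, 1.5e6, 1e5)
    )
    for (r in roi) {
      df[[r]] <- base + beta_age * df$age + rnorm(n, 0, sigma) + 1
    }
    as_cohort(df)
  })
}

test_that("null-effect design recovers intercept and zero slopes", {
  cohort <- make_cn_cohort(n = 50, beta_age = 0, sigma = 0)
  fit <- fit_reference_glm(cohort)
  expect_equal(unname(fit$beta[, "(Intercept)"]), rep(3.5, 68),
               tolerance = 1e-8)
  expect_equal(max(abs(fit$beta[, -1])), 0, tolerance = 1e-8)
})

test_that("coefficients equal an independent normal-equations solve", {
  cohort <- make_cn_cohort(n = 120, beta_age = -0.01, sigma = 0.05, seed = 2)
  fit <- fit_reference_glm(cohort)
  X <- cbind(1, cohort$age, cohort$sex, cohort$education, cohort$icv)
  Y <- as.matrix(cohort[, dk_roi_names()])
  beta_oracle <- solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(unname(t(fit$beta)), unname(beta_oracle), tolerance = 1e-9)
})

test_that("age slope is recovered within Monte-Carlo error at n = 500", {
  cohort <- make_cn_cohort(n = 500, beta_age = -0.01, sigma = 0.05, seed = 3)
  fit <- fit_reference_glm(cohort)
  expect_true(all(abs(fit$beta[, "age"] - (-0.01)) < 0.002))
})

test_that("CN residuals are centered and orthogonal to covariates", {
  g <- tiny_gen(n_cn = 80, n_ad = 30, seed = 5)
  cn <- dplyr::filter(g$res, diagnosis == "CN")
  m <- as.matrix(cn[, dk_roi_names()])
  expect_lt(max(abs(colMeans(m))), 1e-10)
  covs <- as.matrix(baseline(g$cohort)[baseline(g$cohort)$diagnosis == "CN",
                                       c("age", "sex", "education", "icv")])
  cors <- abs(cor(m, covs))
  expect_lt(max(cors), 1e-8)
})

test_that("AD rows never influence the reference fit", {
  g <- tiny_gen(n_cn = 60, n_ad = 40, seed = 6)
  cn_only <- dplyr::filter(g$cohort, diagnosis == "CN")
  expect_identical(fit_reference_glm(g$cohort)$beta,
                   fit_reference_glm(cn_only)$beta)
})

test_that("subject at CN covariate means gets thickness minus CN mean", {
  g <- tiny_gen(n_cn = 50, n_ad = 10, seed = 7)
  cn <- dplyr::filter(baseline(g$cohort), diagnosis == "CN")
  probe <- cn[1, ]
  probe[, c("age", "sex", "education", "icv")] <-
    as.list(g$ref$covariate_centering)
  r <- residualize(g$ref, probe, standardize = FALSE)
  # OLS prediction at the covariate means is the per-ROI CN mean
  cn_mean <- colMeans(as.matrix(cn[, dk_roi_names()]))
  observed <- as.numeric(probe[1, dk_roi_names()])
  expect_equal(as.numeric(r[1, dk_roi_names()]), observed - unname(cn_mean),
               tolerance = 1e-10)
})

test_that("planted AD offset appears in mean residuals", {
  g <- tiny_gen(n_cn = 150, n_ad = 100, seed = 8, standardize = FALSE)
  # plant an extra -0.3 mm in 10 ROIs of the AD rows
  rois <- dk_roi_names()[1:10]
  shifted <- g$cohort
  shifted[shifted$diagnosis == "AD", rois] <-
    shifted[shifted$diagnosis == "AD", rois] - 0.3
  res <- residualize(g$ref, shifted, standardize = FALSE)
  ad <- as.matrix(dplyr::filter(res, diagnosis == "AD")[, rois])
  base_ad <- as.matrix(dplyr::filter(g$res, diagnosis == "AD")[, rois])
  expect_equal(colMeans(ad - base_ad), setNames(rep(-0.3, 10), rois),
               tolerance = 1e-10)
})

test_that("degenerate designs and missing covariates are handled", {
  cohort <- make_cn_cohort(n = 40, sigma = 0.05, seed = 9)
  const <- cohort
  const$education <- 12
  const$icv <- const$education * 2   # collinear with education
  expect_error(fit_reference_glm(const), "collinear")
  expect_error(fit_reference_glm(cohort[1:5, ]), "at least 10")
  holey <- cohort
  holey$age[1] <- NA
  expect_warning(fit <- fit_reference_glm(holey), "missing covariates")
  expect_identical(fit$n_cn, nrow(cohort) - 1L)
  expect_warning(residualize(fit, holey), "missing covariates")
})
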