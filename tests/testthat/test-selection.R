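# Cross-validation, ranking and per-subtype classifier evaluation.

test_that("the canonical hyperparameter grid has 14 powers of two", {
  grid <- eval(formals(grid_search)$C_grid)
  expect_length(grid, 14)
  expect_equal(grid[1], 2^-3)
  expect_equal(grid[14], 2^10)
  expect_identical(grid, eval(formals(grid_search)$t_grid))
})

test_that("cross-validation is deterministic and accurate on easy data", {
  gen <- generate_cohort(planted_k_spec(2, effect = 5, n_cn = 50,
                                        n_ad = 40), seed = 61)
  res <- residualize(fit_reference_glm(gen$cohort), gen$cohort)
  cv1 <- cross_validate_moe(res, K = 2, C = 1, t = 2, folds = 5, seed = 8,
                            n_restarts = 2)
  cv2 <- cross_validate_moe(res, K = 2, C = 1, t = 2, folds = 5, seed = 8,
                            n_restarts = 2)
  expect_identical(cv1$acc_mean, cv2$acc_mean)
  expect_identical(cv1$fold_metrics, cv2$fold_metrics)
  expect_gte(cv1$acc_mean, 0.95)
  expect_identical(nrow(cv1$fold_metrics[[1]]), 5L)
})

test_that("near-chance accuracy arises on null data", {
  gen <- generate_cohort(default_spec(n_cn = 80, n_ad = 76, effect = 0,
                                      mad_effect = 0), seed = 62)
  res <- residualize(fit_reference_glm(gen$cohort), gen$cohort)
  cv <- cross_validate_moe(res, K = 2, C = 1, t = 2, folds = 5, seed = 3,
                           n_restarts = 2)
  expect_gt(cv$acc_mean, 0.35)
  expect_lt(cv$acc_mean, 0.65)
})

test_that("ranking prefers accuracy, then low redundancy, then crisp bpc", {
  tbl <- tibble::tibble(
    K = c(2, 3, 4, 4),
    C = 1, t = 1, folds = 5,
    acc_mean = c(0.80, 0.95, 0.945, 0.90),
    acc_sd = 0.01, sen_mean = NA, sen_sd = NA, spe_mean = NA, spe_sd = NA,
    bpc = c(0.9, 0.8, 0.95, 0.99),
    max_inner_product = c(0.2, 0.5, 0.3, 0.1)
  )
  ranked <- rank_selection(tbl, acc_tol = 0.02)
  # rows 2 and 3 tie on accuracy; row 3 wins on lower inner product;
  # row 4 and 1 fall below the band and sort by accuracy
  expect_identical(ranked$acc_mean, c(0.945, 0.95, 0.90, 0.80))
})

test_that("failed configurations rank last instead of aborting", {
  tbl <- tibble::tibble(
    K = c(2, 3), C = 1, t = 1, folds = 5,
    acc_mean = c(0.9, NA), acc_sd = NA, sen_mean = NA, sen_sd = NA,
    spe_mean = NA, spe_sd = NA, bpc = c(0.9, NA),
    max_inner_product = c(0.4, NA)
  )
  ranked <- rank_selection(tbl)
  expect_identical(ranked$K, c(2, 3))
})

test_that("per-subtype classifiers order by planted separability", {
  spec <- default_spec(n_cn = 80, n_ad = 60, effect = 3, mad_effect = 0.3)
  gen <- generate_cohort(spec, seed = 63)
  res <- residualize(fit_reference_glm(gen$cohort), gen$cohort)
  fit <- fit_moe(res, K = 4, seed = 5, n_restarts = 5)
  out <- evaluate_final_classifiers(fit, res, folds = 5, seed = 11)
  expect_identical(nrow(out), 4L)
  expect_identical(unique(out$folds), 5)
  # strongly atrophied subtypes classify nearly perfectly; the
  # minimal-atrophy subtype is the hardest of the K groups
  expect_gte(max(out$acc_mean), 0.9)
  truth <- gen$truth
  mad_expert <- as.integer(names(which.max(table(
    fit$subtype[match(truth$subject_id[truth$subtype == "mad"],
                      fit$ad_subject_id)]))))
  expect_equal(which.min(out$acc_mean), mad_expert)
})
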