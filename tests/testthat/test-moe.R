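# Mixture-of-experts core: initialization, membership updates,
# alternating fit, hard assignment.

test_that("membership initialization is valid and deterministic", {
  expect_identical(init_membership(7, 1), matrix(1, 7, 1))
  m1 <- withr::with_seed(3, init_membership(30, 4, scheme = "dirichlet"))
  m2 <- withr::with_seed(3, init_membership(30, 4, scheme = "dirichlet"))
  expect_identical(m1, m2)
  expect_rows_sum_to_one(m1)
  expect_true(all(m1 >= 0))
  X <- matrix(rnorm(60), 20, 3)
  mk <- withr::with_seed(4, init_membership(20, 2, scheme = "kmeans",
                                            X_ad = X))
  expect_rows_sum_to_one(mk)
  expect_setequal(unique(as.vector(mk)), c(0.9, 0.1))
  expect_error(init_membership(3, 5), "exceeds")
})

test_that("softmax distance update matches closed forms", {
  e1 <- structure(list(w = c(1, 0), b = 0), class = "expert_svm")
  e2 <- structure(list(w = c(0, 1), b = 0), class = "expert_svm")
  # equidistant point -> (0.5, 0.5)
  m <- update_membership(list(e1, e2), matrix(c(2, 2), 1), t = 1)
  expect_equal(as.numeric(m), c(0.5, 0.5))
  # d = (1, 0), t = 1 -> (e/(e+1), 1/(e+1))
  m2 <- update_membership(list(e1, e2), matrix(c(1, 0), 1), t = 1)
  expect_equal(as.numeric(m2), c(exp(1), 1) / (exp(1) + 1))
  # sharpness limit: crisp without overflow
  m3 <- update_membership(list(e1, e2), matrix(c(1, 0), 1), t = 2^10)
  expect_gte(max(m3), 1 - 1e-6)
  expect_rows_sum_to_one(m3)
})

test_that("hard assignment takes argmax with deterministic ties", {
  expect_identical(assign_hard(matrix(c(0.7, 0.3), 1)), 1L)
  expect_message(lab <- assign_hard(matrix(c(0.5, 0.5), 1)), "tied")
  expect_identical(lab, 1L)
  onehot <- diag(3)
  expect_identical(assign_hard(onehot), 1:3)
})

test_that("K = 1 reduces to a single uniform-weight linear SVM", {
  g <- tiny_gen(n_cn = 40, n_ad = 24, seed = 21)
  X <- as.matrix(g$res[, dk_roi_names()])
  y <- ifelse(g$res$diagnosis == "AD", 1, -1)
  moe <- fit_moe(g$res, K = 1, C = 1, seed = 1, n_restarts = 1,
                 eps_svm = 1e-10)
  plain <- train_weighted_expert(X, y, rep(1, nrow(X)), C = 1, eps = 1e-10)
  expect_true(all(moe$membership == 1))
  d_moe <- as.numeric(X %*% moe$experts[[1]]$w + moe$experts[[1]]$b)
  d_ref <- as.numeric(X %*% plain$w + plain$b)
  expect_equal(d_moe, d_ref, tolerance = 1e-6)
})

test_that("well-separated planted patterns are recovered exactly", {
  skip_if_not_installed("mclust")
  for (s in 1:3) {
    gen <- generate_cohort(planted_k_spec(2, effect = 5, n_cn = 60,
                                          n_ad = 40), seed = 30 + s)
    res <- residualize(fit_reference_glm(gen$cohort), gen$cohort)
    fit <- fit_moe(res, K = 2, seed = s, n_restarts = 3)
    expect_equal(
      mclust::adjustedRandIndex(fit$subtype, gen$truth$subtype_index), 1)
  }
})

test_that("row permutation changes nothing up to expert relabeling", {
  skip_if_not_installed("mclust")
  g <- tiny_gen(n_cn = 50, n_ad = 30, seed = 22)
  fit1 <- fit_moe(g$res, K = 2, seed = 9)
  perm <- withr::with_seed(1, sample(nrow(g$res)))
  fit2 <- fit_moe(g$res[perm, ], K = 2, seed = 9)
  lab1 <- setNames(fit1$subtype, fit1$ad_subject_id)
  lab2 <- setNames(fit2$subtype, fit2$ad_subject_id)
  lab2 <- lab2[names(lab1)]
  expect_equal(mclust::adjustedRandIndex(lab1, lab2), 1)
})

test_that("fit is deterministic given a seed and reports diagnostics", {
  g <- tiny_gen(n_cn = 40, n_ad = 20, seed = 23)
  f1 <- fit_moe(g$res, K = 2, seed = 77, n_restarts = 3)
  f2 <- fit_moe(g$res, K = 2, seed = 77, n_restarts = 3)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$experts, f2$experts)
  expect_rows_sum_to_one(f1$membership)
  expect_true(all(is.finite(f1$objective_trace)))
  expect_identical(length(f1$objective_trace) >= 1, TRUE)
  expect_identical(glance(f1)$K, 2)
})

test_that("the distance gating remains available in the fit", {
  g <- tiny_gen(n_cn = 40, n_ad = 20, seed = 24)
  fit <- fit_moe(g$res, K = 2, seed = 5, n_restarts = 2,
                 gating = "distance")
  expect_null(fit$gating_centroids)
  X_ad <- as.matrix(g$res[g$res$diagnosis == "AD", dk_roi_names()])
  expect_equal(unname(fit$membership),
               unname(update_membership(fit$experts, X_ad, fit$t)),
               tolerance = 1e-12)
})

test_that("impossible configurations raise errors", {
  g <- tiny_gen(n_cn = 20, n_ad = 6, seed = 25)
  expect_error(fit_moe(g$res, K = 7, seed = 1), "fewer AD subjects")
})
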