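# Cross-validated model selection: for each candidate (K, C, t) the MOE
# is refit on training folds and scored on held-out subjects with the
# max-expert rule, while the partition indices (BPC, maximum pairwise
# inner product) come from the full-data fit.

# stratified fold assignment; returns integer fold id per row
.make_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    if (length(idx) < folds) {
      stop("stratification impossible: class with fewer subjects than folds",
           call. = FALSE)
    }
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validate one MOE configuration
#'
#' Stratified f-fold cross-validation of the whole model: per fold the MOE
#' is refit on the training split and each held-out subject is called AD
#' when its largest signed distance over experts is positive. Fold-level
#' accuracy/sensitivity/specificity are pooled to mean and SD. BPC and the
#' maximum pairwise inner product are computed from a fit on the full
#' data, since they describe the partition rather than generalization.
#'
#' @inheritParams fit_moe
#' @param folds Number of cross-validation folds (stratified by
#'   diagnosis).
#' @param n_restarts_cv Restarts used for the per-fold refits (the
#'   full-data fit uses `n_restarts`).
#' @return A one-row tibble of class `selection_metrics` with the
#'   configuration, `acc/sen/spe` means and SDs, `bpc`,
#'   `max_inner_product`, and a `fold_metrics` list-column.
#' @export
cross_validate_moe <- function(residuals, K, C = 1, t = 1, folds = 10,
                               seed = NULL, n_restarts = 10,
                               n_restarts_cv = n_restarts, max_iter = 100,
                               tol = 1e-4, init = "kmeans",
                               diagnosis = NULL, eps_svm = 1e-6) {
  dat <- .moe_data(residuals, diagnosis)
  run <- function() {
    fold <- .make_folds(dat$y, folds)
    per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
      tr <- fold != f
      if (length(unique(dat$y[tr])) < 2 || length(unique(dat$y[!tr])) < 2) {
        stop("fold without both classes", call. = FALSE)
      }
      m <- fit_moe(dat$X[tr, , drop = FALSE], K = K, C = C, t = t,
                   n_restarts = n_restarts_cv, max_iter = max_iter,
                   tol = tol, init = init, diagnosis = dat$y[tr],
                   eps_svm = eps_svm)
      pred <- predict(m, dat$X[!tr, , drop = FALSE], type = "diagnosis")
      dplyr::mutate(confusion_metrics(dat$y[!tr], pred), fold = f)
    })
    full <- fit_moe(dat$X, K = K, C = C, t = t, n_restarts = n_restarts,
                    max_iter = max_iter, tol = tol, init = init,
                    diagnosis = dat$y, eps_svm = eps_svm)
    out <- tibble::tibble(
      K = K, C = C, t = t, folds = folds,
      acc_mean = mean(per_fold$acc), acc_sd = sd(per_fold$acc),
      sen_mean = mean(per_fold$sen), sen_sd = sd(per_fold$sen),
      spe_mean = mean(per_fold$spe), spe_sd = sd(per_fold$spe),
      bpc = bpc(full$membership),
      max_inner_product = if (K >= 2) max_pairwise_inner_product(full) else NA_real_,
      fold_metrics = list(per_fold)
    )
    class(out) <- c("selection_metrics", class(out))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Grid search over expert number and hyperparameters
#'
#' Evaluates [cross_validate_moe()] over every combination of `K_range`,
#' `C_grid` and `t_grid` (the default grids are the 14 powers of two from
#' 2^-3 to 2^10) and ranks configurations by mean held-out accuracy, with
#' accuracies within `acc_tol` of each other treated as tied and broken
#' by lower maximum pairwise inner product, then higher BPC, then smaller
#' `K`. This makes the expert-redundancy and partition-crispness indices
#' decisive exactly where accuracy alone cannot separate candidates.
#'
#' @inheritParams cross_validate_moe
#' @param K_range Integer vector of candidate expert numbers.
#' @param C_grid,t_grid Numeric grids for the soft-margin penalty and the
#'   membership sharpness.
#' @param acc_tol Accuracy band within which configurations count as
#'   tied for ranking purposes.
#' @return A `moe_selection` list: `metrics` (the full ranked tibble) and
#'   `best` (its top row).
#' @export
grid_search <- function(residuals, K_range, C_grid = 2^(-3:10),
                        t_grid = 2^(-3:10), folds = 10, seed = NULL,
                        acc_tol = 0.02, n_restarts = 10,
                        n_restarts_cv = n_restarts, max_iter = 100,
                        tol = 1e-4, init = "kmeans", diagnosis = NULL,
                        eps_svm = 1e-6) {
  grid <- tidyr::expand_grid(K = K_range, C = C_grid, t = t_grid)
  run <- function() {
    purrr::pmap_dfr(grid, function(K, C, t) {
      # a configuration whose experts collapse in every restart is
      # evidence against it, not a reason to abort the search
      tryCatch(
        cross_validate_moe(residuals, K = K, C = C, t = t, folds = folds,
                           n_restarts = n_restarts,
                           n_restarts_cv = n_restarts_cv,
                           max_iter = max_iter, tol = tol, init = init,
                           diagnosis = diagnosis, eps_svm = eps_svm),
        error = function(e) {
          tibble::tibble(K = K, C = C, t = t, folds = folds,
                         acc_mean = NA_real_, acc_sd = NA_real_,
                         sen_mean = NA_real_, sen_sd = NA_real_,
                         spe_mean = NA_real_, spe_sd = NA_real_,
                         bpc = NA_real_, max_inner_product = NA_real_,
                         fold_metrics = list(tibble::tibble()),
                         note = conditionMessage(e))
        }
      )
    })
  }
  metrics <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  metrics <- rank_selection(metrics, acc_tol = acc_tol)
  structure(list(metrics = metrics, best = metrics[1, ], acc_tol = acc_tol),
            class = "moe_selection")
}

#' Rank a selection-metrics table
#'
#' Ordering used by [grid_search()]: configurations whose mean held-out
#' accuracy lies within `acc_tol` of the best are treated as tied on
#' accuracy and ordered by maximum pairwise inner product (ascending,
#' `NA` for K = 1 treated as 0), then BPC (descending), then `K`
#' (ascending); configurations below the band follow, by accuracy.
#' Held-out accuracy saturates quickly in the number of experts, so
#' inside the band the redundancy index (near-duplicate experts push the
#' inner product up, both when a true cluster is split and when distinct
#' clusters are merged) and partition crispness carry the decision.
#'
#' @param metrics A tibble of rows as produced by [cross_validate_moe()].
#' @param acc_tol Accuracy tie band.
#' @return The tibble sorted best-first, with an `acc_tied` column.
#' @export
rank_selection <- function(metrics, acc_tol = 0.02) {
  ip <- ifelse(metrics$K == 1 & is.na(metrics$max_inner_product),
               0, metrics$max_inner_product)
  top <- max(metrics$acc_mean, na.rm = TRUE) - acc_tol
  metrics$acc_tied <- !is.na(metrics$acc_mean) & metrics$acc_mean >= top
  ord <- order(-metrics$acc_tied,
               ifelse(metrics$acc_tied, ip, -metrics$acc_mean),
               ifelse(metrics$acc_tied, -metrics$bpc, 0),
               metrics$K, na.last = TRUE)
  metrics[ord, ]
}

#' @export
print.moe_selection <- function(x, ...) {
  cat("<moe_selection>", nrow(x$metrics), "configurations\n")
  b <- x$best
  cat(sprintf("  best: K=%d C=%g t=%g  acc=%.3f±%.3f  maxIP=%s  bpc=%.3f\n",
              b$K, b$C, b$t, b$acc_mean, b$acc_sd,
              ifelse(is.na(b$max_inner_product), "NA",
                     sprintf("%.3f", b$max_inner_product)), b$bpc))
  invisible(x)
}

#' Per-subtype classifier evaluation
#'
#' After subtypes are fixed, each expert is re-examined as a plain
#' two-class linear SVM between the CN group and the AD subjects hard-
#' assigned to that subtype, refit and scored with stratified f-fold
#' cross-validation (f = 5 by default) at the selected `C`.
#'
#' @param model A fitted `moe_model`.
#' @param residuals The residual tibble (or matrix + `diagnosis`) the
#'   model was fitted on.
#' @param folds Number of folds.
#' @param seed Integer seed for fold assignment.
#' @param diagnosis Only for matrix input.
#' @return A tibble with one row per subtype: `n_ad`, mean and SD of
#'   `acc`, `sen`, `spe` over folds.
#' @export
evaluate_final_classifiers <- function(model, residuals, folds = 5,
                                       seed = NULL, diagnosis = NULL) {
  dat <- .moe_data(residuals, diagnosis)
  ad_idx <- which(dat$y > 0)
  cn_idx <- which(dat$y < 0)
  stopifnot(length(ad_idx) == nrow(model$membership))
  run <- function() {
    purrr::map_dfr(seq_len(model$K), function(k) {
      sub_ad <- ad_idx[model$subtype == k]
      idx <- c(cn_idx, sub_ad)
      X <- dat$X[idx, , drop = FALSE]
      y <- dat$y[idx]
      fold <- .make_folds(y, folds)
      per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
        tr <- fold != f
        ex <- train_weighted_expert(X[tr, , drop = FALSE], y[tr],
                                    rep(1, sum(tr)), C = model$C)
        pred <- ifelse(signed_distance(ex, X[!tr, , drop = FALSE]) > 0, 1, -1)
        confusion_metrics(y[!tr], pred)
      })
      tibble::tibble(
        subtype = k, n_ad = length(sub_ad), folds = folds,
        acc_mean = mean(per_fold$acc), acc_sd = sd(per_fold$acc),
        sen_mean = mean(per_fold$sen), sen_sd = sd(per_fold$sen),
        spe_mean = mean(per_fold$spe), spe_sd = sd(per_fold$spe)
      )
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
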