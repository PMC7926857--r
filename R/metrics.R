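# Classifier and partition-validity metrics used for expert-number and
# hyperparameter selection.

#' Accuracy, sensitivity and specificity from labels
#'
#' Exact integer-count confusion metrics with AD (+1) as the positive
#' class: `acc = (TP + TN) / n`, `sen = TP / (TP + FN)`,
#' `spe = TN / (TN + FP)`. A rate whose denominator is empty (e.g.
#' sensitivity with no true positives in `y_true`) is reported as `NA`,
#' never 0.
#'
#' @param y_true,y_pred Vectors of labels in `{-1, +1}`, equal length.
#' @return A one-row tibble with `acc`, `sen`, `spe` and the four counts.
#' @examples
#' confusion_metrics(c(1, 1, -1, -1), c(1, -1, -1, -1))
#' @export
confusion_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% c(-1, 1)), all(y_pred %in% c(-1, 1)))
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fp <- sum(y_true == -1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  tibble::tibble(
    acc = (tp + tn) / length(y_true),
    sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

#' Fuzzy partition coefficient (BPC)
#'
#' Bezdek's partition coefficient
#' `(1/n) * sum_i sum_k m_ik^2`, a cluster-separation index on a fuzzy
#' membership matrix: exactly 1 for a crisp (one-hot) partition and
#' exactly `1/K` for uniform memberships.
#'
#' @param membership Membership matrix with rows summing to 1.
#' @return Scalar in `[1/K, 1]`.
#' @examples
#' bpc(matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE))
#' @export
bpc <- function(membership) {
  membership <- as.matrix(membership)
  sum(membership^2) / nrow(membership)
}

#' Maximum pairwise inner product of expert normals
#'
#' The largest `|w_j . w_k|` over unordered expert pairs after unit
#' normalization of each hyperplane normal. Near-duplicate experts push
#' this toward 1; well-separated atrophy directions keep it low, which is
#' why it enters expert-number selection.
#'
#' @param experts A `moe_model`, a list of `expert_svm` objects, or a
#'   K x d matrix of normals (rows).
#' @return Scalar in `[0, 1]`.
#' @export
max_pairwise_inner_product <- function(experts) {
  W <- if (inherits(experts, "moe_model")) {
    do.call(rbind, lapply(experts$experts, `[[`, "w"))
  } else if (is.list(experts)) {
    do.call(rbind, lapply(experts, `[[`, "w"))
  } else {
    as.matrix(experts)
  }
  if (nrow(W) < 2) stop("need at least two experts", call. = FALSE)
  Wn <- W / sqrt(rowSums(W^2))
  G <- abs(Wn %*% t(Wn))
  max(G[upper.tri(G)])
}
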