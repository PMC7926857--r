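# Instance-weighted soft-margin linear SVM. Each expert solves
#   min_w,b  1/2 ||w||^2 + C * sum_i u_i * max(0, 1 - y_i (w.x_i + b))
# with per-sample weights u_i >= 0 (CN rows weight 1, AD rows weighted by
# their fuzzy membership in the expert's cluster). Solved exactly in the
# dual by sequential minimal optimization (src/moe_core.cpp) with
# per-sample box constraints 0 <= alpha_i <= C * u_i and an unregularized
# bias recovered from the KKT conditions.

#' Train one instance-weighted linear expert
#'
#' @param X Numeric matrix, one row per subject (residual features).
#' @param y Labels, `+1` (affected/AD) or `-1` (reference/CN).
#' @param weights Per-sample nonnegative weights; samples with weight
#'   below `1e-8` are dropped before solving.
#' @param C Soft-margin penalty.
#' @param eps Duality-gap stopping tolerance of the SMO solver.
#' @return An `expert_svm`: hyperplane normal `w`, offset `b`, `C`, the
#'   primal objective value and solver diagnostics.
#' @examples
#' X <- rbind(matrix(rnorm(40, -1), 20), matrix(rnorm(40, 1), 20))
#' y <- rep(c(-1, 1), each = 20)
#' ex <- train_weighted_expert(X, y, rep(1, 40), C = 1)
#' @export
train_weighted_expert <- function(X, y, weights = rep(1, nrow(X)), C = 1,
                                  eps = 1e-8) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(weights) == nrow(X),
            all(y %in% c(-1, 1)), all(weights >= 0), C > 0)
  keep <- weights >= 1e-8
  if (length(unique(y[keep])) < 2) {
    stop("effective training data contain a single class", call. = FALSE)
  }
  sol <- .svm_fit_cpp(X[keep, , drop = FALSE], y[keep], C * weights[keep],
                      eps = eps)
  structure(
    list(w = as.numeric(sol$w), b = sol$b, C = C,
         objective = sol$objective, iterations = sol$iter,
         converged = sol$converged),
    class = "expert_svm"
  )
}

#' Geometric signed distance to an expert hyperplane
#'
#' Returns `(w.x + b) / ||w||` for each row of `X`; positive values lie on
#' the affected (AD) side. Invariant to rescaling of `(w, b)`.
#'
#' @param expert An `expert_svm` (or any list with `w` and `b`).
#' @param X Numeric matrix or vector of feature rows.
#' @return Numeric vector of signed distances.
#' @export
signed_distance <- function(expert, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  nw <- sqrt(sum(expert$w^2))
  if (nw == 0) stop("expert has a zero normal vector", call. = FALSE)
  as.numeric(X %*% expert$w + expert$b) / nw
}

#' @export
print.expert_svm <- function(x, ...) {
  cat("<expert_svm> linear expert, d =", length(x$w),
      " C =", format(x$C), " |w| =", format(sqrt(sum(x$w^2)), digits = 4), "\n")
  invisible(x)
}
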