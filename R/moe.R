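# Mixture of experts: fuzzy clustering of patients coupled with one
# instance-weighted linear patient-vs-control classifier per cluster.
# Alternating optimization: (1) each expert k is trained on all CN rows
# (weight 1) against the AD rows weighted by membership column k; (2) AD
# memberships are refreshed as a sharpened softmax over the geometric
# signed distances to the K hyperplanes. Repeated restarts guard against
# poor local solutions.

#' Initialize a fuzzy membership matrix
#'
#' @param n_ad Number of affected (AD) subjects.
#' @param K Number of experts.
#' @param scheme `"kmeans"`: one-hot from k-means on the AD residuals,
#'   softened so the winning cluster gets 0.9 and the rest share 0.1
#'   (requires `X_ad`); `"dirichlet"`: rows drawn from a symmetric
#'   Dirichlet(1).
#' @param X_ad AD residual matrix (`n_ad` x features), needed for the
#'   k-means scheme.
#' @return An `n_ad` x `K` matrix with nonnegative rows summing to 1.
#'   Uses the current RNG state; seed upstream for determinism.
#' @export
init_membership <- function(n_ad, K, scheme = c("kmeans", "dirichlet"),
                            X_ad = NULL) {
  scheme <- match.arg(scheme)
  if (K > n_ad) stop("K exceeds the number of AD subjects", call. = FALSE)
  if (K == 1) return(matrix(1, n_ad, 1))
  if (scheme == "kmeans") {
    if (is.null(X_ad)) stop("X_ad required for kmeans initialization", call. = FALSE)
    cl <- stats::kmeans(X_ad, centers = K, nstart = 3)$cluster
    m <- matrix(0.1 / (K - 1), n_ad, K)
    m[cbind(seq_len(n_ad), cl)] <- 0.9
  } else {
    g <- matrix(stats::rgamma(n_ad * K, shape = 1), n_ad, K)
    m <- g / rowSums(g)
  }
  m
}

#' Softmax membership update from expert distances
#'
#' Recomputes fuzzy memberships of affected subjects as
#' `m_ik = exp(t d_k(x_i)) / sum_j exp(t d_j(x_i))`, where `d_k` is the
#' geometric signed distance to expert `k` and `t` is the sharpness
#' hyperparameter: `t -> 0` gives uniform memberships, `t -> Inf` hard
#' assignment to the nearest-to-AD-side expert. Computed with
#' max-subtraction so large `t` cannot overflow.
#'
#' @param experts A list of `expert_svm` objects (or a `moe_model`).
#' @param X_ad AD residual matrix.
#' @param t Sharpness (inverse temperature), `t >= 0`.
#' @return Membership matrix with rows summing to 1.
#' @export
update_membership <- function(experts, X_ad, t) {
  if (inherits(experts, "moe_model")) experts <- experts$experts
  X_ad <- as.matrix(X_ad)
  D <- vapply(experts, function(e) signed_distance(e, X_ad),
              numeric(nrow(X_ad)))
  D <- matrix(D, nrow = nrow(X_ad))
  Z <- t * D
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Hard subtype labels from a membership matrix
#'
#' Argmax per row; exact ties go to the lowest expert index (reported via
#' a message).
#'
#' @param membership Membership matrix (rows sum to 1).
#' @return Integer vector of subtype labels in `1..K`.
#' @export
assign_hard <- function(membership) {
  membership <- as.matrix(membership)
  rowmax <- apply(membership, 1, max)
  nties <- rowSums(membership == rowmax)
  if (any(nties > 1)) {
    message(sum(nties > 1), " tied membership row(s) assigned to the ",
            "lowest expert index")
  }
  max.col(membership, ties.method = "first")
}

# pull (X, y, ids) out of a residual tibble or a plain matrix + diagnosis
.moe_data <- function(residuals, diagnosis = NULL) {
  if (is.data.frame(residuals)) {
    stopifnot("diagnosis" %in% names(residuals))
    X <- roi_matrix(residuals)
    y <- ifelse(residuals$diagnosis == "AD", 1, -1)
    ids <- residuals$subject_id
  } else {
    X <- as.matrix(residuals)
    if (is.null(diagnosis)) stop("diagnosis required with matrix input", call. = FALSE)
    y <- if (is.numeric(diagnosis)) diagnosis else ifelse(diagnosis == "AD", 1, -1)
    ids <- if (is.null(rownames(X))) as.character(seq_len(nrow(X))) else rownames(X)
  }
  stopifnot(all(y %in% c(-1, 1)))
  list(X = X, y = y, ids = ids)
}

#' Fit the mixture-of-experts subtype model
#'
#' Alternating optimization of `K` instance-weighted linear experts
#' (CN = reference class, label -1, always weight 1; AD = affected class,
#' label +1, weighted by its fuzzy membership in the expert's cluster)
#' and a fuzzy membership update at sharpness `t`, until the largest
#' membership change falls below `tol` or `max_iter` sweeps. Among
#' `n_restarts` random initializations the solution with the lowest
#' summed weighted-SVM objective is kept. With `K = 1` the model reduces
#' exactly to a single standard linear SVM.
#'
#' Two membership gatings are available:
#'
#' * `"shrunken_centroid"` (default): memberships are a softmax over
#'   `-t/2 * ||x_i - c_k||^2`, where `c_k` is the membership-weighted AD
#'   centroid of cluster `k` soft-thresholded toward the CN origin by
#'   `shrink * sqrt(2 log d) / sqrt(n_k)` per coordinate. Atrophy
#'   patterns are sparse deviations from the CN norm, and shrinking
#'   centroid coordinates that are indistinguishable from normal back to
#'   exactly zero removes most of the high-dimensional noise that
#'   otherwise swamps the mildly affected clusters. Assumes
#'   CN-standardized residuals (the [residualize()] default).
#' * `"distance"`: the softmax over `t` times the geometric signed
#'   distance to each expert hyperplane, as in [update_membership()].
#'   Simpler, but unable to tell apart subtypes whose atrophy patterns
#'   are nested (a diffuse-atrophy subject out-projects everyone on
#'   every expert), so it is not the default.
#'
#' Restarts in which an expert's total AD membership collapses below
#' `1e-6 * n_AD` are discarded (with a message); if every restart
#' collapses, an error suggests a smaller `K`.
#'
#' @param residuals Residual tibble from [residualize()] (with a
#'   `diagnosis` column), or a numeric matrix plus a `diagnosis` vector.
#' @param K Number of experts (subtypes).
#' @param C Soft-margin penalty of each expert.
#' @param t Membership sharpness.
#' @param seed Integer seed making the whole fit deterministic.
#' @param n_restarts,max_iter,tol Optimization controls.
#' @param init Membership initialization scheme (see [init_membership()]).
#' @param gating Membership update rule; see Details.
#' @param shrink Centroid soft-threshold multiplier of the
#'   shrunken-centroid gating.
#' @param diagnosis Only for matrix input: `"CN"`/`"AD"` or -1/+1 labels.
#' @param eps_svm SMO duality-gap tolerance.
#' @return A `moe_model`: `experts` (list of `expert_svm`), `membership`
#'   (AD x K, rows sum to 1), hard `subtype` labels, the hyperparameters,
#'   convergence diagnostics and the per-iteration objective trace of the
#'   retained restart.
#' @examples
#' spec <- default_spec(n_cn = 60, n_ad = 40)
#' cohort <- generate_cohort(spec, seed = 1)$cohort
#' res <- residualize(fit_reference_glm(cohort), cohort)
#' fit <- fit_moe(res, K = 2, C = 1, t = 2, seed = 1, n_restarts = 2)
#' glance(fit)
#' @export
fit_moe <- function(residuals, K, C = 1, t = 2, seed = NULL,
                    n_restarts = 10, max_iter = 100, tol = 1e-4,
                    init = c("kmeans", "dirichlet"),
                    gating = c("shrunken_centroid", "distance"),
                    shrink = 0.5, diagnosis = NULL, eps_svm = 1e-6) {
  init <- match.arg(init)
  gating <- match.arg(gating)
  dat <- .moe_data(residuals, diagnosis)
  ad <- dat$y > 0
  n_ad <- sum(ad)
  if (n_ad < K) stop("fewer AD subjects than experts", call. = FALSE)
  if (!any(ad) || all(ad)) stop("both classes must be present", call. = FALSE)

  # membership-weighted cost of the shrunken-centroid gating; used to
  # break near-ties between restarts whose expert objectives are within
  # a few percent (the summed SVM objective barely distinguishes
  # partitions once every cluster is separable from CN, and can even
  # slightly prefer splitting an easy cluster while merging two hard
  # ones)
  gate_cost <- function(fit) {
    if (gating == "distance") return(NA_real_)
    M <- fit$membership
    Cent <- matrix(fit$gating_centroids, nrow = K)
    X_ad <- dat$X[ad, , drop = FALSE]
    D2 <- outer(rowSums(X_ad^2), rep(1, K)) - 2 * X_ad %*% t(Cent) +
      outer(rep(1, nrow(X_ad)), rowSums(Cent^2))
    sum(M * D2)
  }
  run <- function() {
    best <- NULL
    n_collapsed <- 0
    for (r in seq_len(n_restarts)) {
      M0 <- init_membership(n_ad, K, scheme = init,
                            X_ad = dat$X[ad, , drop = FALSE])
      fit <- .moe_fit_cpp(dat$X, dat$y, M0, C, t, max_iter, tol,
                          eps_svm, 1e-8, 1e-6,
                          gating = if (gating == "distance") 1L else 0L,
                          shrink = shrink)
      if (isTRUE(fit$collapsed)) {
        n_collapsed <- n_collapsed + 1
        next
      }
      obj <- utils::tail(fit$objective_trace, 1)
      cand <- list(fit = fit, obj = obj, cost = gate_cost(fit), restart = r)
      take <- if (is.null(best)) {
        TRUE
      } else if (gating == "distance") {
        obj < best$obj
      } else if (abs(obj - best$obj) <= 0.05 * max(abs(best$obj), 1e-12)) {
        cand$cost < best$cost   # near-tie on the objective
      } else {
        obj < best$obj
      }
      if (take) best <- cand
    }
    if (n_collapsed > 0) {
      message(n_collapsed, " restart(s) discarded after expert collapse")
    }
    if (is.null(best)) {
      stop("every restart collapsed an expert; try a smaller K", call. = FALSE)
    }
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  fit <- best$fit
  membership <- fit$membership
  rownames(membership) <- dat$ids[ad]
  experts <- lapply(seq_len(K), function(k) {
    structure(list(w = as.numeric(fit$W[k, ]), b = fit$b[k], C = C),
              class = "expert_svm")
  })
  structure(
    list(
      experts = experts,
      membership = membership,
      subtype = assign_hard(membership),
      K = K, C = C, t = t, seed = seed,
      gating = gating, shrink = shrink,
      gating_centroids = if (gating == "shrunken_centroid") {
        matrix(fit$gating_centroids, nrow = K)
      },
      n_iter = fit$n_iter, converged = fit$converged,
      objective_trace = as.numeric(fit$objective_trace),
      restart = best$restart,
      feature_names = colnames(dat$X),
      ad_subject_id = dat$ids[ad]
    ),
    class = "moe_model"
  )
}

#' Predict subtype membership and diagnosis-side decisions
#'
#' Pushes new residualized rows through the fitted hyperplanes. The
#' whole-model diagnosis rule is max-expert: a subject is called AD when
#' the largest signed distance over experts is positive.
#'
#' @param object A `moe_model`.
#' @param newdata Residual tibble or matrix.
#' @param type `"subtype"` (hard label), `"membership"`,
#'   `"decision"` (matrix of signed distances), or `"diagnosis"`
#'   (+1 = AD side, -1 = CN side).
#' @param ... Unused.
#' @export
predict.moe_model <- function(object, newdata,
                              type = c("subtype", "membership",
                                       "decision", "diagnosis"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) roi_matrix(newdata) else as.matrix(newdata)
  D <- vapply(object$experts, function(e) signed_distance(e, X),
              numeric(nrow(X)))
  D <- matrix(D, nrow = nrow(X))
  switch(type,
    decision = D,
    diagnosis = ifelse(apply(D, 1, max) > 0, 1, -1),
    membership = .model_membership(object, X),
    subtype = assign_hard(.model_membership(object, X))
  )
}

# memberships of new rows under the model's own gating rule
.model_membership <- function(object, X) {
  if (identical(object$gating, "distance") ||
      is.null(object$gating_centroids)) {
    return(update_membership(object$experts, X, object$t))
  }
  Cent <- object$gating_centroids
  D2 <- outer(rowSums(X^2), rep(1, nrow(Cent))) -
    2 * X %*% t(Cent) +
    outer(rep(1, nrow(X)), rowSums(Cent^2))
  Z <- -object$t / 2 * D2
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' @export
print.moe_model <- function(x, ...) {
  cat("<moe_model> K =", x$K, " C =", format(x$C), " t =", format(x$t), "\n")
  cat("  AD subjects:", nrow(x$membership),
      " iterations:", x$n_iter,
      " converged:", x$converged, "\n")
  cat("  subtype sizes:", paste(tabulate(x$subtype, x$K), collapse = "/"), "\n")
  invisible(x)
}

#' Tidy a fitted mixture-of-experts model
#'
#' @param x A `moe_model`.
#' @param what `"membership"`: one row per AD subject x expert with the
#'   fuzzy weight and hard label; `"experts"`: one row per expert x
#'   feature with the hyperplane coefficient.
#' @param ... Unused.
#' @export
tidy.moe_model <- function(x, what = c("membership", "experts"), ...) {
  what <- match.arg(what)
  if (what == "membership") {
    m <- x$membership
    tibble::tibble(
      subject_id = rep(rownames(m), times = ncol(m)),
      expert = rep(seq_len(ncol(m)), each = nrow(m)),
      membership = as.vector(m),
      subtype = rep(x$subtype, times = ncol(m))
    )
  } else {
    tibble::tibble(
      expert = rep(seq_len(x$K), each = length(x$feature_names)),
      term = rep(x$feature_names, times = x$K),
      estimate = unlist(lapply(x$experts, `[[`, "w"), use.names = FALSE)
    )
  }
}

#' One-row summary of a mixture-of-experts fit
#'
#' @param x A `moe_model`.
#' @param ... Unused.
#' @export
glance.moe_model <- function(x, ...) {
  tibble::tibble(
    K = x$K, C = x$C, t = x$t,
    n_ad = nrow(x$membership),
    n_iter = x$n_iter,
    converged = x$converged,
    objective = utils::tail(x$objective_trace, 1),
    bpc = bpc(x$membership),
    max_inner_product = if (x$K >= 2) max_pairwise_inner_product(x) else NA_real_
  )
}
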