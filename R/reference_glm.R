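# Covariate residualization against a cognitively-normal reference model.
# Per ROI, thickness is regressed on (1, age, sex, education, ICV) using
# CN baseline rows only; the fitted coefficients are then used to remove
# covariate effects from every subject, CN and AD alike, so that AD rows
# never influence the normative model.

#' Fit the CN-only reference regression per ROI
#'
#' Ordinary least squares of each of the 68 ROI thickness values on an
#' intercept plus the extraneous covariates (by default age, sex, years of
#' education and intracranial volume), using cognitively-normal baseline
#' rows only. The result is the normative model that [residualize()]
#' subtracts from all subjects.
#'
#' Subjects with a missing covariate are excluded with a warning. The
#' design matrix must be full column rank; collinear covariates are
#' reported by name.
#'
#' @param cohort A cohort tibble (see [as_cohort()]). Only CN baseline
#'   rows are used; other rows are ignored.
#' @param covariates Character vector of covariate column names, in the
#'   order they enter the design matrix.
#' @return An object of class `reference_glm`: per-ROI coefficients
#'   (`beta`, 68 x (1 + covariates)), CN covariate means
#'   (`covariate_centering`), per-ROI CN residual standard deviation
#'   (`residual_scale`), and bookkeeping fields.
#' @examples
#' spec <- default_spec(n_cn = 60, n_ad = 20)
#' cohort <- generate_cohort(spec, seed = 1)$cohort
#' fit <- fit_reference_glm(cohort)
#' glance(fit)
#' @export
fit_reference_glm <- function(cohort,
                              covariates = c("age", "sex", "education", "icv")) {
  cn <- dplyr::filter(baseline(cohort), .data$diagnosis == "CN")
  keep <- stats::complete.cases(cn[, covariates])
  if (any(!keep)) {
    warning(sum(!keep), " CN subject(s) dropped from reference fit for ",
            "missing covariates: ",
            paste(head(cn$subject_id[!keep], 5), collapse = ", "),
            call. = FALSE)
    cn <- cn[keep, ]
  }
  p <- length(covariates) + 1L
  if (nrow(cn) < 10) stop("need at least 10 CN baseline subjects", call. = FALSE)
  if (nrow(cn) < p) stop("fewer CN subjects than model parameters", call. = FALSE)

  X <- cbind(`(Intercept)` = 1, as.matrix(cn[, covariates]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Y <- roi_matrix(cn)
  beta <- qr.coef(qrX, Y)               # p x 68
  resid <- Y - X %*% beta
  structure(
    list(
      beta = t(beta),                   # 68 x p, rows in canonical ROI order
      covariates = covariates,
      covariate_centering = colMeans(as.matrix(cn[, covariates])),
      residual_scale = apply(resid, 2, sd),
      roi_names = dk_roi_names(),
      n_cn = nrow(cn)
    ),
    class = "reference_glm"
  )
}

#' Residualize thickness against the reference model
#'
#' Subtracts the reference-model prediction (from each subject's own
#' covariate values) from the observed thickness of every row, CN and AD,
#' at any visit. With `standardize = TRUE` (default) each ROI residual is
#' further divided by the CN residual standard deviation, putting all 68
#' features on a common scale so no single high-variance region dominates
#' the max-margin experts.
#'
#' @param fit A `reference_glm` from [fit_reference_glm()].
#' @param cohort A cohort tibble; rows with a missing covariate are
#'   dropped with a warning.
#' @param standardize Divide per-ROI residuals by the CN residual SD.
#' @return A residual tibble: `subject_id`, `diagnosis`, `visit_month`,
#'   then the 68 ROI columns holding residuals (mm, or CN-SD units if
#'   standardized). Attribute `standardized` records the flag.
#' @examples
#' spec <- default_spec(n_cn = 60, n_ad = 20)
#' cohort <- generate_cohort(spec, seed = 1)$cohort
#' res <- residualize(fit_reference_glm(cohort), cohort)
#' @export
residualize <- function(fit, cohort, standardize = TRUE) {
  stopifnot(inherits(fit, "reference_glm"))
  keep <- stats::complete.cases(cohort[, fit$covariates])
  if (any(!keep)) {
    warning(sum(!keep), " row(s) dropped from residualization for missing ",
            "covariates: ",
            paste(head(unique(cohort$subject_id[!keep]), 5), collapse = ", "),
            call. = FALSE)
    cohort <- cohort[keep, ]
  }
  X <- cbind(1, as.matrix(cohort[, fit$covariates]))
  pred <- X %*% t(fit$beta)             # n x 68
  resid <- roi_matrix(cohort) - pred
  if (standardize) resid <- sweep(resid, 2, fit$residual_scale, "/")
  out <- dplyr::bind_cols(
    cohort[, c("subject_id", "diagnosis", "visit_month")],
    tibble::as_tibble(resid, .name_repair = "minimal")
  )
  attr(out, "standardized") <- standardize
  out
}

#' @export
print.reference_glm <- function(x, ...) {
  cat("<reference_glm> CN normative model\n")
  cat("  ROIs:      ", length(x$roi_names), "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  n CN:      ", x$n_cn, "\n")
  invisible(x)
}

#' Tidy the per-ROI reference coefficients
#'
#' @param x A `reference_glm`.
#' @param ... Unused.
#' @return A tibble with one row per ROI x term.
#' @export
tidy.reference_glm <- function(x, ...) {
  beta <- x$beta
  tibble::tibble(
    roi = rep(x$roi_names, times = ncol(beta)),
    term = rep(colnames(beta), each = nrow(beta)),
    estimate = as.vector(beta)
  )
}

#' One-row summary of a reference fit
#'
#' @param x A `reference_glm`.
#' @param ... Unused.
#' @export
glance.reference_glm <- function(x, ...) {
  tibble::tibble(
    n_cn = x$n_cn,
    n_roi = length(x$roi_names),
    n_covariates = length(x$covariates),
    mean_residual_sd = mean(x$residual_scale)
  )
}
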