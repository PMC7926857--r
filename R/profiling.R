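# Cross-sectional subtype characterization: omnibus ANOVA, many-to-one
# (Dunnett) and all-pairs (Tukey) adjusted comparisons, chi-square tests
# for categorical traits, CSF abnormality proportions with missing-data
# exclusion, and per-ROI effect-size maps with FDR control.

#' One-way fixed-effects ANOVA across subtype groups
#'
#' @param values Numeric outcome per subject; missing values dropped.
#' @param labels Group label per subject.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `n`. With two groups F equals the square of the pooled two-sample t
#'   statistic.
#' @examples
#' anova_groups(c(rnorm(20), rnorm(20, 1)), rep(c("a", "b"), each = 20))
#' @export
anova_groups <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- factor(labels[keep])
  if (nlevels(labels) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(labels) < 2)) stop("each group needs at least two subjects", call. = FALSE)
  if (stats::var(values) == 0) {
    stop("outcome has zero variance; F statistic undefined", call. = FALSE)
  }
  fit <- stats::aov(values ~ labels)
  s <- summary(fit)[[1]]
  tibble::tibble(
    statistic = s[["F value"]][1],
    df1 = s[["Df"]][1],
    df2 = s[["Df"]][2],
    p.value = s[["Pr(>F)"]][1],
    n = length(values)
  )
}

# shared driver for single-step multiple comparisons via the
# multivariate-t acceptance region (multcomp/mvtnorm)
.glht_pairwise <- function(values, labels, type, control = NULL,
                           maxpts = 1e5, seed = 1) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- factor(labels[keep])
  if (!is.null(control)) {
    if (!control %in% levels(labels)) {
      stop("control group '", control, "' not present", call. = FALSE)
    }
    labels <- stats::relevel(labels, ref = control)
  }
  dat <- data.frame(y = values, g = labels)
  fit <- stats::aov(y ~ g, data = dat)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = type))
  adj <- withr::with_seed(seed, {
    summary(gl, test = multcomp::adjusted(
      "single-step", maxpts = as.integer(maxpts), abseps = 1e-4))
  })
  raw <- summary(gl, test = multcomp::adjusted("none"))
  tibble::tibble(
    comparison = names(adj$test$coefficients),
    estimate = unname(adj$test$coefficients),
    statistic = unname(adj$test$tstat),
    p.raw = as.numeric(raw$test$pvalues),
    p.adj = as.numeric(pmax(adj$test$pvalues, raw$test$pvalues))
  )
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Single-step Dunnett procedure: every group is compared with the named
#' control and the family-wise adjusted p-values are obtained from the
#' multivariate-t acceptance region (Monte-Carlo integration with a fixed
#' seed and at least 1e5 integrand evaluations). Adjusted p-values are
#' never below the raw ones. With a single comparison the procedure
#' reduces to the two-sample pooled t-test.
#'
#' @param values Numeric outcome per subject.
#' @param labels Group label per subject.
#' @param control Name of the control group (e.g. `"CN"` or a subtype).
#' @param maxpts Monte-Carlo integrand evaluations for the multivariate-t
#'   probabilities.
#' @param seed Seed for the integration, making p-values reproducible.
#' @return A tibble with one row per comparison: `estimate`,
#'   `statistic`, `p.raw`, `p.adj`.
#' @export
dunnett_pairwise <- function(values, labels, control, maxpts = 1e5,
                             seed = 1) {
  .glht_pairwise(values, labels, type = "Dunnett", control = control,
                 maxpts = maxpts, seed = seed)
}

#' Tukey all-pairs comparisons
#'
#' Single-step Tukey honest-significant-difference procedure over every
#' unordered pair of groups, adjusted through the same multivariate-t
#' machinery as [dunnett_pairwise()]. This is the default for all-pairs
#' subtype contrasts, since the many-to-one Dunnett procedure is only
#' defined relative to one control group.
#'
#' @inheritParams dunnett_pairwise
#' @export
tukey_pairwise <- function(values, labels, maxpts = 1e5, seed = 1) {
  .glht_pairwise(values, labels, type = "Tukey", maxpts = maxpts,
                 seed = seed)
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; `df = (r - 1)(c - 1)`.
#'
#' @param contingency An r x c matrix or table of counts.
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @examples
#' chisq_categorical(matrix(c(10, 20, 20, 10), 2))
#' @export
chisq_categorical <- function(contingency) {
  contingency <- as.matrix(contingency)
  ht <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = as.integer(unname(ht$parameter)),
    p.value = ht$p.value
  )
}

#' Default CSF biomarker cutpoints
#'
#' Standard ADNI cerebrospinal-fluid abnormality cutpoints (ng/L):
#' amyloid-beta 1-42 abnormal below 192, total tau abnormal above 93,
#' phosphorylated tau abnormal above 23. These are configuration, not
#' constants: pass modified values to [abnormal_proportion()].
#'
#' @return A named list of `list(threshold, direction)` entries.
#' @export
csf_thresholds <- function() {
  list(
    abeta42 = list(threshold = 192, direction = "below"),
    ttau = list(threshold = 93, direction = "above"),
    ptau = list(threshold = 23, direction = "above")
  )
}

#' Abnormality proportion with missing-data exclusion
#'
#' Missing values are excluded from the denominator before the proportion
#' is formed. A value exactly at the threshold counts as normal (strict
#' inequality).
#'
#' @param values Numeric biomarker values, may contain `NA`.
#' @param threshold Cutpoint.
#' @param direction `"below"`: abnormal when strictly below the
#'   threshold; `"above"`: strictly above.
#' @return A one-row tibble: `n_abnormal`, `n_observed`, `fraction`.
#' @examples
#' abnormal_proportion(c(150, 200, NA), 192, "below")
#' @export
abnormal_proportion <- function(values, threshold,
                                direction = c("below", "above")) {
  direction <- match.arg(direction)
  obs <- values[!is.na(values)]
  if (length(obs) == 0) stop("no observed values", call. = FALSE)
  ab <- if (direction == "below") sum(obs < threshold) else sum(obs > threshold)
  tibble::tibble(n_abnormal = ab, n_observed = length(obs),
                 fraction = ab / length(obs))
}

#' Per-ROI effect-size map of each subtype versus CN
#'
#' For every subtype and ROI, the pooled-SD Cohen's d and pooled
#' two-sample t-test p-value of the subtype's residuals against the CN
#' residuals, with Benjamini-Hochberg adjustment across the 68 ROIs
#' within each subtype. The default flag level mirrors the stringent
#' q < 0.0005 threshold commonly used for cortical effect-size maps.
#'
#' @param residuals Residual tibble from [residualize()] containing both
#'   CN and AD rows (baseline visit).
#' @param subtype_labels Integer subtype per AD subject: a vector in the
#'   order of the AD rows, a named vector, or a tibble with `subject_id`
#'   and `subtype`.
#' @param q_flag FDR-adjusted significance threshold for the `flag`
#'   column.
#' @return A tibble, one row per subtype x ROI: `cohens_d`, `p.value`,
#'   `p.adj`, `flag`. Negative d = thinner than CN.
#' @export
effect_size_map <- function(residuals, subtype_labels, q_flag = 5e-4) {
  cn <- dplyr::filter(residuals, .data$diagnosis == "CN")
  ad <- dplyr::filter(residuals, .data$diagnosis == "AD")
  if (is.data.frame(subtype_labels)) {
    subtype_labels <- setNames(subtype_labels$subtype,
                               subtype_labels$subject_id)
  }
  labels <- if (!is.null(names(subtype_labels))) {
    unname(subtype_labels[ad$subject_id])
  } else {
    stopifnot(length(subtype_labels) == nrow(ad))
    subtype_labels
  }
  Xcn <- roi_matrix(cn)
  Xad <- roi_matrix(ad)
  roi <- dk_roi_names()
  purrr::map_dfr(sort(unique(labels)), function(k) {
    Xk <- Xad[labels == k, , drop = FALSE]
    n1 <- nrow(Xk); n0 <- nrow(Xcn)
    m1 <- colMeans(Xk); m0 <- colMeans(Xcn)
    v1 <- apply(Xk, 2, var); v0 <- apply(Xcn, 2, var)
    sp <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
    d <- (m1 - m0) / sp
    tstat <- (m1 - m0) / (sp * sqrt(1 / n1 + 1 / n0))
    p <- 2 * stats::pt(-abs(tstat), df = n1 + n0 - 2)
    padj <- stats::p.adjust(p, method = "BH")
    tibble::tibble(
      subtype = k, roi = roi, n_subtype = n1,
      cohens_d = unname(d), p.value = unname(p), p.adj = unname(padj),
      flag = unname(padj < q_flag)
    )
  })
}
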