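# Longitudinal analyses: annual thinning rates, time-varying subtype
# attribution through the baseline-fitted hyperplanes, and subtype
# transition tables between visit pairs.

#' Annual rate of cortical-thickness change
#'
#' Per subject and ROI, `(thickness_m - thickness_0) / (m / 12)` in
#' mm/year, where month `m` is chosen from the available follow-up visits
#' (by default the latest of 12 and 24 months, the longer interval being
#' less noise-sensitive; set `use = "earliest"` to prefer 12 months).
#' Subjects without a baseline or any follow-up visit are excluded.
#'
#' @param cohort A cohort tibble with baseline and follow-up rows.
#' @param visits Follow-up months considered.
#' @param use `"latest"` or `"earliest"` available visit per subject.
#' @return A long tibble: `subject_id`, `months`, `roi`, `baseline`,
#'   `followup`, `rate` (mm/year).
#' @examples
#' spec <- default_spec(n_cn = 30, n_ad = 20)
#' gen <- generate_cohort(spec, seed = 1)
#' long <- generate_longitudinal(spec, gen$cohort, gen$truth, seed = 2)
#' rates <- annual_rate_of_change(long)
#' @export
annual_rate_of_change <- function(cohort, visits = c(12, 24),
                                  use = c("latest", "earliest")) {
  use <- match.arg(use)
  roi <- dk_roi_names()
  fup <- dplyr::filter(cohort, .data$visit_month %in% visits)
  pick <- dplyr::group_by(fup, .data$subject_id)
  pick <- dplyr::slice(pick, if (use == "latest") {
    which.max(.data$visit_month)
  } else {
    which.min(.data$visit_month)
  })
  pick <- dplyr::ungroup(pick)
  base <- baseline(cohort)
  both <- intersect(base$subject_id, pick$subject_id)
  base <- base[match(both, base$subject_id), ]
  pick <- pick[match(both, pick$subject_id), ]
  if (length(both) == 0) {
    return(tibble::tibble(subject_id = character(), months = numeric(),
                          roi = character(), baseline = numeric(),
                          followup = numeric(), rate = numeric()))
  }
  years <- pick$visit_month / 12
  b_mat <- roi_matrix(base)
  f_mat <- roi_matrix(pick)
  tibble::tibble(
    subject_id = rep(both, each = length(roi)),
    months = rep(pick$visit_month, each = length(roi)),
    roi = rep(roi, times = length(both)),
    baseline = as.vector(t(b_mat)),
    followup = as.vector(t(f_mat)),
    rate = as.vector(t((f_mat - b_mat) / years))
  )
}

#' Time-varying subtype attribution of follow-up visits
#'
#' Residualizes follow-up rows with the baseline-fitted reference model
#' (each row's own covariate values, so age advances with the visit
#' unless `freeze_age = TRUE`), pushes them through the baseline-fitted
#' model, recomputes fuzzy memberships under the fitted gating at the
#' fitted sharpness `t`, and hard-assigns a subtype per visit. Applied to the
#' unmodified baseline rows this exactly reproduces the baseline labels.
#'
#' @param model A baseline-fitted `moe_model`.
#' @param fit The baseline `reference_glm`.
#' @param cohort Cohort rows to attribute (any visits); rows with missing
#'   ROI values are skipped with a warning.
#' @param standardize Must match the residualization used at fit time.
#' @param freeze_age Replace each follow-up age with the subject's
#'   baseline age before residualizing.
#' @return A tibble: `subject_id`, `visit_month`, `subtype`, and the `K`
#'   membership columns `m1..mK` (rows sum to 1).
#' @export
attribute_followup <- function(model, fit, cohort, standardize = TRUE,
                               freeze_age = FALSE) {
  stopifnot(inherits(model, "moe_model"), inherits(fit, "reference_glm"))
  roi <- dk_roi_names()
  ok <- stats::complete.cases(cohort[, roi])
  if (any(!ok)) {
    warning(sum(!ok), " row(s) skipped for missing ROI values", call. = FALSE)
    cohort <- cohort[ok, ]
  }
  if (freeze_age) {
    base_age <- setNames(baseline(cohort)$age, baseline(cohort)$subject_id)
    cohort$age <- unname(base_age[cohort$subject_id])
  }
  res <- residualize(fit, cohort, standardize = standardize)
  m <- predict(model, res, type = "membership")
  out <- tibble::tibble(
    subject_id = res$subject_id,
    visit_month = res$visit_month,
    subtype = assign_hard(m)
  )
  colnames(m) <- paste0("m", seq_len(ncol(m)))
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

#' Subtype transition table between two visits
#'
#' Cross-tabulates baseline against follow-up subtype labels. Only
#' subjects present in both label sets enter the table; the number left
#' out is recorded in the `excluded` attribute (attrition line).
#'
#' @param baseline_labels Named vector (names = subject ids) or tibble
#'   with `subject_id` and `subtype` columns, for the baseline visit.
#' @param followup_labels Same, for the follow-up visit.
#' @param K Number of subtypes (defaults to the largest label seen).
#' @return A `transition_table`: K x K integer matrix, rows = baseline
#'   subtype, columns = follow-up subtype, with attributes `excluded`
#'   and `n`.
#' @export
transition_table <- function(baseline_labels, followup_labels, K = NULL) {
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(x$subtype, x$subject_id) else x
  }
  b <- as_named(baseline_labels)
  f <- as_named(followup_labels)
  if (is.null(names(b)) || is.null(names(f))) {
    stop("labels must be named by subject id", call. = FALSE)
  }
  both <- intersect(names(b), names(f))
  if (is.null(K)) K <- max(c(b, f))
  counts <- matrix(0L, K, K,
                   dimnames = list(baseline = seq_len(K),
                                   followup = seq_len(K)))
  for (s in both) {
    counts[b[[s]], f[[s]]] <- counts[b[[s]], f[[s]]] + 1L
  }
  structure(counts, class = c("transition_table", "matrix"),
            excluded = length(b) - length(both), n = length(both))
}

#' @export
print.transition_table <- function(x, ...) {
  cat("<transition_table>", attr(x, "n"), "subjects with both visits,",
      attr(x, "excluded"), "excluded\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' @describeIn transition_table Tidy to one row per (baseline, followup)
#'   cell.
#' @param x A `transition_table`.
#' @param ... Unused.
#' @export
tidy.transition_table <- function(x, ...) {
  K <- nrow(x)
  tibble::tibble(
    baseline = rep(seq_len(K), times = K),
    followup = rep(seq_len(K), each = K),
    n = as.vector(unclass(x))
  )
}
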