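# Cohort tables: one row per subject-visit, 68 ROI thickness columns in
# canonical order, covariates (age, sex, education, icv) and free-form
# phenotype columns. Kept as plain tibbles so the usual dplyr verbs apply.

.cohort_required <- c("subject_id", "diagnosis", "visit_month",
                      "age", "sex", "education", "icv")

#' Read and validate a cohort table
#'
#' Reads a delimited subject-by-visit table of regional cortical thickness
#' plus covariates, applies an optional column-name mapping, validates it
#' with [as_cohort()] and reorders the 68 ROI columns to the canonical
#' Desikan-Killiany order of [dk_roi_names()].
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension unless `delim` is given). Header row required; missing cells
#'   empty or `NA`; `.` decimal separator.
#' @param schema Optional named character vector mapping canonical column
#'   names (`subject_id`, `diagnosis`, `visit_month`, `age`, `sex`,
#'   `education`, `icv`, and ROI names) to the names used in the file,
#'   e.g. `c(subject_id = "PTID", icv = "EstimatedTotalIntraCranialVol")`.
#' @param delim Field delimiter; overrides the extension-based guess.
#' @return A validated cohort tibble. Columns not recognised as required
#'   or ROI columns are preserved untouched as phenotypes.
#' @seealso [as_cohort()], [dk_roi_names()]
#' @examples
#' path <- system.file("extdata", "example_cohort.csv",
#'                     package = "moesubtype")
#' cohort <- read_cohort(path)
#' dplyr::count(cohort, diagnosis)
#' @export
read_cohort <- function(path, schema = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  # read everything as character and convert with R's (correctly
  # rounded) parser, so written cohorts round-trip bit-exactly
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           na = c("", "NA"), progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  raw[] <- lapply(raw, function(v) {
    utils::type.convert(v, as.is = TRUE, na.strings = c("", "NA"))
  })
  as_cohort(raw, schema = schema)
}

#' Validate a data frame as a cohort table
#'
#' Checks the invariants every downstream step relies on: required columns
#' present, all 68 ROI columns present, numeric and positive where
#' observed, `(subject_id, visit_month)` pairs unique, and diagnosis
#' constant within subject. ROI columns are reordered to the canonical
#' order so permuting them in the input can never change a result.
#'
#' @param x A data frame, one row per subject-visit.
#' @inheritParams read_cohort
#' @return A cohort tibble with columns `subject_id`, `diagnosis`
#'   (factor CN/AD), `visit_month`, covariates, the 68 ROI columns in
#'   canonical order, then any phenotype columns.
#' @export
as_cohort <- function(x, schema = NULL) {
  x <- tibble::as_tibble(x)
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(x))
    if (length(miss) > 0) {
      stop("schema maps to column(s) absent from the file: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    names(x)[match(unname(schema), names(x))] <- names(schema)
  }
  roi <- dk_roi_names()
  miss <- setdiff(c(.cohort_required, roi), names(x))
  if (length(miss) > 0) {
    stop("required column(s) missing: ",
         paste(head(miss, 8), collapse = ", "),
         if (length(miss) > 8) sprintf(" (and %d more)", length(miss) - 8),
         call. = FALSE)
  }
  for (col in c(roi, "visit_month", "age", "sex", "education", "icv")) {
    if (!is.numeric(x[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(x[[col]])))) &
                     !is.na(x[[col]]))
      stop("column '", col, "' is not numeric (first offending row: ",
           if (length(bad)) bad[1] else 1, ")", call. = FALSE)
    }
  }
  for (col in c(roi, "visit_month", "age", "sex", "education", "icv")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  x$subject_id <- as.character(x$subject_id)
  if (!all(x$diagnosis %in% c("CN", "AD"))) {
    stop("diagnosis must be 'CN' or 'AD'", call. = FALSE)
  }
  x$diagnosis <- factor(as.character(x$diagnosis), levels = c("CN", "AD"))
  if (any(x$visit_month < 0, na.rm = TRUE)) {
    stop("visit_month must be >= 0", call. = FALSE)
  }
  dup <- duplicated(x[c("subject_id", "visit_month")])
  if (any(dup)) {
    stop("duplicated (subject_id, visit_month) pair(s): ",
         paste(unique(x$subject_id[dup]), collapse = ", "), call. = FALSE)
  }
  ndx <- tapply(x$diagnosis, x$subject_id, function(d) length(unique(d)))
  if (any(ndx > 1)) {
    stop("diagnosis changes within subject(s): ",
         paste(names(ndx)[ndx > 1], collapse = ", "), call. = FALSE)
  }
  neg <- vapply(roi, function(r) any(x[[r]] <= 0, na.rm = TRUE), logical(1))
  if (any(neg)) {
    stop("non-positive thickness in ROI column(s): ",
         paste(roi[neg], collapse = ", "), call. = FALSE)
  }
  other <- setdiff(names(x), c(.cohort_required, roi))
  x[, c(.cohort_required, roi, other)]
}

#' Write a cohort table to CSV
#'
#' Full-precision round-trip: every numeric cell survives
#' `read_cohort(write_cohort(x))` exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$diagnosis <- as.character(out$diagnosis)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  })
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Baseline rows of a cohort
#'
#' @param cohort A cohort tibble.
#' @return Rows with `visit_month == 0`.
#' @export
baseline <- function(cohort) {
  dplyr::filter(cohort, .data$visit_month == 0)
}

# extract the n x 68 ROI matrix (canonical order) from a cohort or
# residual tibble
roi_matrix <- function(x) {
  m <- as.matrix(x[, dk_roi_names()])
  rownames(m) <- x$subject_id
  m
}
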