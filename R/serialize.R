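# Single-file JSON serialization of fitted artifacts. Doubles are
# written as decimal strings with 17 significant digits (flattened
# column-major for matrices), which restores every IEEE-754 value
# bit-exactly on read while the artifact stays a plain text file that
# can be inspected and diffed.

.model_schema_version <- "1"

.chr17 <- function(x) {
  if (is.null(x)) NULL else sprintf("%.17g", as.vector(x))
}
.num17 <- function(x) {
  if (is.null(x)) NULL else as.numeric(unlist(x))
}

#' Serialize a fitted model to JSON
#'
#' Stores the mixture-of-experts model (expert hyperplanes, memberships,
#' gating parameters, hyperparameters, seed) and optionally the
#' reference regression in one schema-versioned JSON file. Round trip is
#' lossless: `read_model(write_model(m))` reproduces all numeric fields
#' bit-exactly.
#'
#' @param model A `moe_model`.
#' @param path Output path.
#' @param reference Optional `reference_glm` stored alongside.
#' @return `path`, invisibly.
#' @examples
#' spec <- default_spec(n_cn = 40, n_ad = 20)
#' gen <- generate_cohort(spec, seed = 1)
#' ref <- fit_reference_glm(gen$cohort)
#' fit <- fit_moe(residualize(ref, gen$cohort), K = 2, seed = 1,
#'                n_restarts = 2)
#' f <- tempfile(fileext = ".json")
#' write_model(fit, f, reference = ref)
#' rt <- read_model(f)
#' @export
write_model <- function(model, path, reference = NULL) {
  stopifnot(inherits(model, "moe_model"))
  payload <- list(
    schema_version = .model_schema_version,
    package_version = as.character(utils::packageVersion("moesubtype")),
    model = list(
      K = model$K, seed = model$seed,
      C = .chr17(model$C), t = .chr17(model$t),
      gating = model$gating, shrink = .chr17(model$shrink),
      gating_centroids = .chr17(model$gating_centroids),
      n_iter = model$n_iter, converged = model$converged,
      restart = model$restart,
      objective_trace = .chr17(model$objective_trace),
      feature_names = model$feature_names,
      ad_subject_id = model$ad_subject_id,
      subtype = model$subtype,
      membership = .chr17(model$membership),
      w = .chr17(t(do.call(rbind, lapply(model$experts, `[[`, "w")))),
      b = .chr17(vapply(model$experts, `[[`, numeric(1), "b"))
    )
  )
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "reference_glm"))
    payload$reference <- list(
      beta = .chr17(reference$beta),
      covariates = reference$covariates,
      covariate_centering = .chr17(reference$covariate_centering),
      residual_scale = .chr17(reference$residual_scale),
      roi_names = reference$roi_names,
      n_cn = reference$n_cn
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_model
#' @param path Path to a file written by [write_model()].
#' @return `read_model()` returns a list with elements `model`
#'   (`moe_model`) and `reference` (`reference_glm` or `NULL`).
#' @export
read_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop("cannot parse model file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(payload$schema_version) || is.null(payload$model)) {
    stop("not a moesubtype model file: ", path, call. = FALSE)
  }
  if (!identical(as.character(payload$schema_version),
                 .model_schema_version)) {
    stop("model schema version ", payload$schema_version,
         " not supported (expected ", .model_schema_version, ")",
         call. = FALSE)
  }
  m <- payload$model
  K <- as.integer(m$K)
  n_ad <- length(m$ad_subject_id)
  membership <- matrix(.num17(m$membership), nrow = n_ad)
  rownames(membership) <- m$ad_subject_id
  W <- matrix(.num17(m$w), ncol = K)   # stored column-major, d x K
  C <- .num17(m$C)
  experts <- lapply(seq_len(K), function(k) {
    structure(list(w = W[, k], b = .num17(m$b)[k], C = C),
              class = "expert_svm")
  })
  cent <- if (!is.null(m$gating_centroids)) {
    matrix(.num17(m$gating_centroids), nrow = K)
  }
  model <- structure(
    list(experts = experts, membership = membership,
         subtype = as.integer(m$subtype), K = K,
         C = C, t = .num17(m$t), seed = .num17(m$seed),
         gating = m$gating, shrink = .num17(m$shrink),
         gating_centroids = cent,
         n_iter = as.integer(m$n_iter), converged = m$converged,
         objective_trace = .num17(m$objective_trace),
         restart = m$restart, feature_names = m$feature_names,
         ad_subject_id = m$ad_subject_id),
    class = "moe_model"
  )
  reference <- NULL
  if (!is.null(payload$reference)) {
    r <- payload$reference
    beta <- matrix(.num17(r$beta), nrow = length(r$roi_names))
    rownames(beta) <- r$roi_names
    colnames(beta) <- c("(Intercept)", r$covariates)
    reference <- structure(
      list(beta = beta, covariates = r$covariates,
           covariate_centering = setNames(.num17(r$covariate_centering),
                                          r$covariates),
           residual_scale = setNames(.num17(r$residual_scale),
                                     r$roi_names),
           roi_names = r$roi_names, n_cn = as.integer(r$n_cn)),
      class = "reference_glm"
    )
  }
  list(model = model, reference = reference)
}
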