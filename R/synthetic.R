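# Synthetic ADNI-like cohorts with planted atrophy subtypes. The
# generator exists so that every pipeline stage - residualization, MOE
# fitting, selection, profiling, longitudinal attribution - can be
# validated end-to-end against known ground truth without access-
# controlled data. It emulates the structure of an ADNI-1-style baseline
# sample: CN norms with covariate effects, four planted atrophy patterns
# at fixed proportions, and 12/24-month follow-up decline.

#' Planted atrophy patterns of the four AD subtypes
#'
#' Per-pattern nonnegative effect sizes over the 68 ROIs, in CN-residual
#' SD units (0 = spared region), together with the fraction of AD
#' subjects drawn from each pattern:
#'
#' * `osad` - occipital-sparing: bilateral lateral parietal (inferior and
#'   superior parietal, supramarginal), precuneus, superior and rostral
#'   middle frontal, and middle/inferior temporal regions.
#' * `ltad` - left-temporal-dominant: the left lateral temporal-parietal
#'   cortex (lateral parietal, lateral temporal, fusiform).
#' * `mad` - minimal atrophy: sporadic mild loss in the inferior
#'   temporal regions.
#' * `dad` - diffuse: every region except bilateral postcentral,
#'   paracentral, lingual and pericalcarine.
#'
#' Affected regions default to `effect` SD of thinning (1.0) except the
#' minimal-atrophy pattern, which uses `mad_effect` (0.3).
#'
#' Each pattern also carries a `decline` 68-vector (SD/year) used for
#' follow-up visits: diffuse atrophy declines fastest, minimal atrophy
#' barely changes, and the left-temporal pattern additionally spreads
#' into bilateral occipital and right temporal cortex over time.
#'
#' @param effect Effect size (SD) of affected regions.
#' @param mad_effect Effect size of the minimal-atrophy pattern.
#' @param rates Named decline rates (SD/year) per pattern.
#' @return Named list of patterns, each with `name`, `atrophy`,
#'   `decline`, `proportion`.
#' @export
subtype_patterns <- function(effect = 1.0, mad_effect = 0.3,
                             rates = c(osad = 0.15, ltad = 0.12,
                                       mad = 0.02, dad = 0.20)) {
  # OSAD: bilateral lateral parietal + precuneus, superior/rostral-middle
  # frontal, middle/inferior temporal
  osad_rois <- c("inferiorparietal", "superiorparietal", "supramarginal",
                 "precuneus", "superiorfrontal", "rostralmiddlefrontal",
                 "middletemporal", "inferiortemporal")
  # LTAD: the left lateral temporal-parietal cortex
  ltad_rois <- c("inferiorparietal", "superiorparietal", "supramarginal",
                 "middletemporal", "inferiortemporal", "superiortemporal",
                 "bankssts", "fusiform")
  spared_dad <- c("postcentral", "paracentral", "lingual", "pericalcarine")

  vec <- function(idx, size) {
    v <- numeric(68)
    v[idx] <- size
    v
  }
  osad_idx <- .roi_index(osad_rois, "both")
  ltad_idx <- .roi_index(ltad_rois, "lh")
  mad_idx <- .roi_index("inferiortemporal", "both")
  dad_idx <- setdiff(seq_len(68), .roi_index(spared_dad, "both"))
  ltad_spread <- union(ltad_idx,
                       c(.roi_index("lateraloccipital", "both"),
                         .roi_index(c("middletemporal", "inferiortemporal"),
                                    "rh")))
  list(
    osad = list(name = "osad", atrophy = vec(osad_idx, effect),
                decline = vec(osad_idx, rates[["osad"]]),
                proportion = 0.292),
    ltad = list(name = "ltad", atrophy = vec(ltad_idx, effect),
                decline = vec(ltad_spread, rates[["ltad"]]),
                proportion = 0.224),
    mad = list(name = "mad", atrophy = vec(mad_idx, mad_effect),
               decline = vec(mad_idx, rates[["mad"]]),
               proportion = 0.161),
    dad = list(name = "dad", atrophy = vec(dad_idx, effect),
               decline = vec(dad_idx, rates[["dad"]]),
               proportion = 0.323)
  )
}

#' Default synthetic-cohort specification
#'
#' The study conditions the generator emulates: 228 CN and 192 AD
#' subjects; CN age 75.9 +/- 5.0 and AD age 75.4 +/- 7.4 years; the four
#' planted patterns of [subtype_patterns()] at proportions
#' 0.292/0.224/0.161/0.323 (which at 192 AD subjects apportion to
#' 56/43/31/62); covariate effects on thickness (age, sex, education,
#' ICV) at literature-plausible small values; per-ROI baseline mean
#' 2.5 mm with residual noise SD 0.15 mm.
#'
#' @param n_cn,n_ad Group sizes.
#' @param effect,mad_effect,rates Passed to [subtype_patterns()].
#' @param noise_sd Per-ROI residual SD (mm).
#' @param exchangeable_rho Optional exchangeable correlation between ROI
#'   noise terms (0 = independent).
#' @return A `synthetic_spec` list; see fields in the source. Serializes
#'   losslessly with [write_spec()] / [read_spec()].
#' @examples
#' spec <- default_spec()
#' sum(vapply(spec$patterns, `[[`, 1, "proportion"))
#' @export
default_spec <- function(n_cn = 228, n_ad = 192, effect = 1.0,
                         mad_effect = 0.3,
                         rates = c(osad = 0.15, ltad = 0.12,
                                   mad = 0.02, dad = 0.20),
                         noise_sd = 0.15, exchangeable_rho = 0) {
  structure(
    list(
      n_cn = n_cn, n_ad = n_ad,
      age = list(cn = c(mean = 75.9, sd = 5.0),
                 ad = c(mean = 75.4, sd = 7.4)),
      female_fraction = c(cn = 0.478, ad = 0.474),
      education = list(cn = c(mean = 16.1, sd = 2.9),
                       ad = c(mean = 14.7, sd = 3.1)),
      icv = c(mean = 1.5e6, sd = 1.5e5),
      # thickness change per unit covariate (mm/yr, mm, mm/yr, mm/mm^3)
      covariate_effects = c(age = -0.01, sex = 0.02,
                            education = 0.002, icv = 5e-8),
      covariate_centers = c(age = 75.9, sex = 0.478,
                            education = 16.1, icv = 1.5e6),
      roi_mean = rep(2.5, 68),
      noise_sd = noise_sd,
      exchangeable_rho = exchangeable_rho,
      patterns = subtype_patterns(effect = effect, mad_effect = mad_effect,
                                  rates = rates),
      followup_noise_sd = 0.02,
      attrition = c(`12` = 0.10, `24` = 0.25)
    ),
    class = "synthetic_spec"
  )
}

# largest-remainder apportionment of n subjects to pattern proportions
.apportion <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# draw the per-subject noise matrix, optionally exchangeably correlated
.noise <- function(n, sd, rho) {
  e <- matrix(rnorm(n * 68, sd = sd), n, 68)
  if (rho > 0) {
    shared <- rnorm(n, sd = sd)
    e <- sqrt(1 - rho) * e + sqrt(rho) * shared
  }
  e
}

#' Generate a synthetic baseline cohort
#'
#' CN thickness is baseline mean plus centered covariate effects plus
#' Gaussian noise; AD thickness additionally subtracts the subject's
#' planted pattern (`atrophy * noise_sd`, i.e. effect sizes are in noise-
#' SD units). Planted subtype labels are returned separately and never
#' written into the cohort.
#'
#' @param spec A `synthetic_spec` from [default_spec()].
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list: `cohort` (cohort tibble, baseline rows only) and
#'   `truth` (tibble `subject_id`, `subtype` name, `subtype_index`).
#' @examples
#' gen <- generate_cohort(default_spec(n_cn = 40, n_ad = 30), seed = 7)
#' table(gen$truth$subtype)
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_ad < length(spec$patterns)) {
    stop("n_ad smaller than the number of patterns", call. = FALSE)
  }
  withr::with_seed(seed, {
    n <- spec$n_cn + spec$n_ad
    diagnosis <- rep(c("CN", "AD"), c(spec$n_cn, spec$n_ad))
    grp <- ifelse(diagnosis == "CN", "cn", "ad")
    id <- sprintf("S%04d", seq_len(n))

    age <- rnorm(n, spec$age$cn["mean"], spec$age$cn["sd"])
    age[grp == "ad"] <- rnorm(spec$n_ad, spec$age$ad["mean"],
                              spec$age$ad["sd"])
    sex <- stats::rbinom(n, 1, spec$female_fraction[grp])
    edu <- rnorm(n, spec$education$cn["mean"], spec$education$cn["sd"])
    edu[grp == "ad"] <- rnorm(spec$n_ad, spec$education$ad["mean"],
                              spec$education$ad["sd"])
    icv <- rnorm(n, spec$icv["mean"], spec$icv["sd"])

    be <- spec$covariate_effects
    ce <- spec$covariate_centers
    cov_term <- be[["age"]] * (age - ce[["age"]]) +
      be[["sex"]] * (sex - ce[["sex"]]) +
      be[["education"]] * (edu - ce[["education"]]) +
      be[["icv"]] * (icv - ce[["icv"]])

    thick <- matrix(rep(spec$roi_mean, each = n), n, 68) + cov_term +
      .noise(n, spec$noise_sd, spec$exchangeable_rho)

    counts <- .apportion(spec$n_ad,
                         vapply(spec$patterns, `[[`, 1, "proportion"))
    subtype_index <- sample(rep(seq_along(spec$patterns), counts))
    ad_rows <- which(grp == "ad")
    for (j in seq_along(spec$patterns)) {
      rows <- ad_rows[subtype_index == j]
      shift <- spec$patterns[[j]]$atrophy * spec$noise_sd
      thick[rows, ] <- sweep(thick[rows, , drop = FALSE], 2, shift, "-")
    }
    thick <- pmax(thick, 0.1)   # thickness stays physically positive

    colnames(thick) <- dk_roi_names()
    cohort <- dplyr::bind_cols(
      tibble::tibble(subject_id = id, diagnosis = diagnosis,
                     visit_month = 0, age = age, sex = sex,
                     education = edu, icv = icv),
      tibble::as_tibble(thick)
    )
    truth <- tibble::tibble(
      subject_id = id[ad_rows],
      subtype = names(spec$patterns)[subtype_index],
      subtype_index = subtype_index
    )
    list(cohort = as_cohort(cohort), truth = truth)
  })
}

#' Generate 12/24-month follow-up visits
#'
#' Per AD subject and follow-up month m, thickness is the baseline value
#' plus continued normal aging (`age` covariate effect over m/12 years),
#' minus the pattern's decline (`decline * noise_sd * m/12`), plus
#' measurement noise. The age column advances with the visit. A fraction
#' of follow-ups is removed at random per visit (attrition); set
#' `attrition = c(\`12\` = 0, \`24\` = 0)` (or in the spec) to keep all.
#'
#' @param spec The `synthetic_spec` used at baseline.
#' @param cohort Baseline cohort tibble from [generate_cohort()].
#' @param truth Matching truth tibble.
#' @param seed Integer seed.
#' @param visits Follow-up months to generate.
#' @param attrition Named per-visit dropout fractions; defaults to the
#'   spec's.
#' @return A cohort tibble containing the baseline rows plus the
#'   surviving follow-up rows.
#' @export
generate_longitudinal <- function(spec, cohort, truth, seed,
                                  visits = c(12, 24), attrition = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(attrition)) attrition <- spec$attrition
  base_ad <- dplyr::filter(baseline(cohort), .data$diagnosis == "AD")
  base_ad <- base_ad[match(truth$subject_id, base_ad$subject_id), ]
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(visits, function(m) {
      keep <- runif(nrow(base_ad)) >= attrition[[as.character(m)]]
      sub <- base_ad[keep, ]
      idx <- truth$subtype_index[keep]
      years <- m / 12
      thick <- roi_matrix(sub) +
        spec$covariate_effects[["age"]] * years
      decl <- do.call(rbind, lapply(spec$patterns, `[[`, "decline"))
      thick <- thick - decl[idx, , drop = FALSE] * spec$noise_sd * years
      thick <- thick + matrix(rnorm(length(thick),
                                    sd = spec$followup_noise_sd),
                              nrow(thick), 68)
      thick <- pmax(thick, 0.1)
      out <- sub
      out$visit_month <- m
      out$age <- sub$age + years
      out[, dk_roi_names()] <- tibble::as_tibble(thick)
      out
    })
    as_cohort(dplyr::bind_rows(cohort, rows))
  })
}

#' Planted-K specification with disjoint pattern supports
#'
#' A clean planted-partition variant of [default_spec()] used to
#' validate expert-number selection: `K` patterns with disjoint,
#' equal-sized ROI supports (mutually orthogonal atrophy directions) at
#' a common effect size and equal mixing proportions. Unlike the
#' ADNI-like default patterns, whose supports nest (diffuse atrophy
#' contains the focal patterns, so coarser models remain genuinely
#' competitive and the number of clusters is only weakly identified),
#' orthogonal supports make both under- and over-fitting of `K` visible
#' to the selection indices.
#'
#' @param K Number of planted patterns (`K * support <= 68`).
#' @param effect Effect size (CN-residual SD) on each affected ROI.
#' @param support Number of ROIs affected per pattern.
#' @param n_cn,n_ad Group sizes.
#' @param decline_rate Follow-up decline (SD/year) on each pattern's
#'   support.
#' @return A `synthetic_spec`.
#' @examples
#' gen <- generate_cohort(planted_k_spec(3), seed = 1)
#' @export
planted_k_spec <- function(K, effect = 1.5, support = 10,
                           n_cn = 100, n_ad = 96, decline_rate = 0.1) {
  stopifnot(K >= 1, K * support <= 68)
  spec <- default_spec(n_cn = n_cn, n_ad = n_ad)
  pats <- lapply(seq_len(K), function(k) {
    v <- numeric(68)
    v[((k - 1) * support + 1):(k * support)] <- effect
    list(name = paste0("p", k), atrophy = v,
         decline = v / effect * decline_rate, proportion = 1 / K)
  })
  names(pats) <- paste0("p", seq_len(K))
  spec$patterns <- pats
  spec
}

#' Write / read a synthetic specification (YAML)
#'
#' @param spec A `synthetic_spec`.
#' @param path File path.
#' @return `read_spec()` returns the `synthetic_spec`; numeric fields
#'   round-trip exactly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  yaml::write_yaml(unclass(spec), path,
                   precision = 17, indent.mapping.sequence = TRUE)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml serializes named vectors as plain sequences; restore names and
  # atomic shape from the default-spec template, positionally
  fix <- function(x, template) {
    if (is.list(template)) {
      out <- purrr::map2(x, template[names(x)], fix)
      names(out) <- names(x)
      out
    } else {
      setNames(as.vector(unlist(x), mode = mode(template)),
               names(template))
    }
  }
  template <- unclass(default_spec())
  template$patterns <- setNames(rep(template$patterns[1],
                                    length(raw$patterns)),
                                names(raw$patterns))
  out <- fix(raw, template)
  structure(out, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>", x$n_cn, "CN +", x$n_ad, "AD;",
      length(x$patterns), "patterns (",
      paste(names(x$patterns), collapse = ", "), ")\n")
  invisible(x)
}
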