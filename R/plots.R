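# ggplot2 views of the main result types.

#' Membership heatmap of a fitted model
#'
#' AD subjects (ordered by hard subtype, then by membership strength)
#' against experts, tile-filled by fuzzy membership.
#'
#' @param object A `moe_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moe_model <- function(object, ...) {
  d <- tidy(object, what = "membership")
  strength <- vapply(split(d$membership, d$subject_id), max, numeric(1))
  ord <- order(object$subtype, -strength[object$ad_subject_id])
  d$subject_id <- factor(d$subject_id,
                         levels = object$ad_subject_id[ord])
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$expert),
                                  y = .data$subject_id,
                                  fill = .data$membership)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "expert", y = "AD subject", fill = "membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Selection indices across candidate configurations
#'
#' Held-out accuracy, maximum pairwise inner product and BPC against the
#' number of experts, one line per (C, t) cell.
#'
#' @param object A `moe_selection` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moe_selection <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object$metrics, "K", "C", "t", "acc_mean",
                  "max_inner_product", "bpc"),
    c("acc_mean", "max_inner_product", "bpc"),
    names_to = "index", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$K, y = .data$value,
                                  group = interaction(.data$C, .data$t))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "number of experts K", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-ROI effect-size map
#'
#' Tiles of Cohen's d (subtype vs CN) per ROI, FDR-flagged cells dotted.
#'
#' @param es Output of [effect_size_map()].
#' @return A ggplot.
#' @export
plot_effect_size_map <- function(es) {
  es$roi <- factor(es$roi, levels = rev(dk_roi_names()))
  ggplot2::ggplot(es, ggplot2::aes(x = factor(.data$subtype),
                                   y = .data$roi,
                                   fill = .data$cohens_d)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(es, .data$flag),
                        size = 0.4) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "subtype", y = NULL, fill = "Cohen's d") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Transition counts between baseline and follow-up subtypes
#'
#' @param object A `transition_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transition_table <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$followup),
                                  y = factor(.data$baseline),
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::labs(x = "follow-up subtype", y = "baseline subtype",
                  fill = "subjects") +
    ggplot2::theme_minimal()
}
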