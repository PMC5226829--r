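#' Plot the four cone sensitivities of a visual model
#'
#' @param model A [visual_model()].
#' @param wl Working wavelength grid.
#' @return A ggplot object.
#' @export
plot_receptor_sensitivities <- function(model, wl = spectral_grid()) {
  receptor_sensitivities(model, wl) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$wavelength, y = .data$sensitivity, colour = .data$channel
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "wavelength (nm)", y = "relative sensitivity",
      title = sprintf("%s eye, T50 %g nm", model$eye_type, model$t50),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of species scores or ranks under two conditions
#'
#' Mirrors the standard presentation of a condition comparison: species mean
#' dichromatism scores (or ranks) under one parameterization against the
#' other, with the 1:1 reference line; the focal species with the largest
#' score change is highlighted.
#'
#' @param object A [compare_conditions()] result.
#' @param what `"score"` or `"rank"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot condition_comparison
#' @export
autoplot.condition_comparison <- function(object, what = c("score", "rank"),
                                          ...) {
  what <- rlang::arg_match(what)
  per <- object$species
  cols <- if (what == "score") c("score_a", "score_b") else c("rank_a", "rank_b")
  focal <- per$species[which.max(abs(per$score_change))]
  ggplot2::ggplot(per, ggplot2::aes(
    x = .data[[cols[1]]], y = .data[[cols[2]]]
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = per[per$species == focal, ],
      shape = 17, size = 3
    ) +
    ggplot2::labs(
      x = sprintf("%s (%s)", what, object$labels[1]),
      y = sprintf("%s (%s)", what, object$labels[2])
    ) +
    ggplot2::theme_minimal()
}

#' Distributions of permutation scores for the two eye types
#'
#' Histograms of the mean dichromatism scores (and optionally the number of
#' patches above threshold) across all parameter combinations, split by eye
#' type.
#'
#' @param result_uvs,result_vs Tibbles from [permute_space()].
#' @param what `"mean_score"` or `"n_patches_above"`.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_permutation_distributions <- function(result_uvs, result_vs,
                                           what = c("mean_score", "n_patches_above"),
                                           bins = 60) {
  what <- rlang::arg_match(what)
  both <- dplyr::bind_rows(
    dplyr::mutate(result_uvs, eye_type = "UVS"),
    dplyr::mutate(result_vs, eye_type = "VS")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data[[what]], fill = .data$eye_type)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species)) +
    ggplot2::labs(
      x = if (what == "mean_score") "mean dichromatism score (JND)" else
        "patches above 1 JND",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
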