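#' Plot reconstruction success across a branch-length grid
#'
#' Success fraction against the elongated branch length, one line per
#' alignment length, faceted by short-internal-branch value and analysis
#' model.
#'
#' @param summaries A summary tibble from [summarize_replicates()].
#' @return A ggplot object.
#' @export
plot_success <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$long_branch, y = .data$success,
                               colour = factor(.data$n_sites))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$model),
      cols = ggplot2::vars(.data$topology, .data$sib),
      labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "elongated branch length (subst/site)",
                  y = "reconstruction success",
                  colour = "sites") +
    ggplot2::theme_minimal()
}

#' Plot the error-class composition of grid cells
#'
#' Stacked per-class replicate fractions against the elongated branch
#' length.
#'
#' @param summaries A summary tibble from [summarize_replicates()].
#' @return A ggplot object.
#' @export
plot_error_classes <- function(summaries) {
  long <- summaries |>
    tidyr::pivot_longer(
      dplyr::all_of(c("n_correct", "n_class_I", "n_class_II",
                      "n_class_III", "n_other")),
      names_to = "class", values_to = "count") |>
    dplyr::mutate(class = factor(sub("^n_", "", .data$class),
                                 levels = error_classes()),
                  fraction = .data$count / .data$n)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$long_branch),
                               y = .data$fraction, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$model, .data$n_sites),
      cols = ggplot2::vars(.data$topology, .data$sib),
      labeller = ggplot2::label_both) +
    ggplot2::labs(x = "elongated branch length (subst/site)",
                  y = "fraction of replicates", fill = "class") +
    ggplot2::theme_minimal()
}

#' @rdname plot_success
#' @param object An `lba_summary` tibble.
#' @param ... Unused.
#' @export
autoplot.lba_summary <- function(object, ...) plot_success(object)
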