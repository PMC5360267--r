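# ggplot2 presentation of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a SIFt profile
#'
#' Bar chart of the any-contact frequency per position with the retention
#' cutoff and hotspot threshold drawn as horizontal lines; hotspot
#' positions are highlighted.
#'
#' @param object A `sift_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sift_profile
#' @export
autoplot.sift_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  cutoff <- attr(object, "cutoff")
  hs <- attr(object, "hotspot_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$freq,
    fill = .data$hotspot)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = hs, linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
      `TRUE` = "#c23b22"), guide = "none") +
    ggplot2::labs(
      x = "generic position", y = "any-contact frequency",
      title = attr(object, "profile_id"),
      subtitle = sprintf("retained > %.2f (dashed), hotspot ≥ %.2f (dotted)",
        cutoff, hs)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot the cluster-count penalty profile of a clustering
#'
#' @param object A `ligand_clustering` with a Kelley penalty profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ligand_clustering
#' @export
autoplot.ligand_clustering <- function(object, ...) {
  if (is.null(object$profile)) {
    stop("clustering has no penalty profile (k was fixed)", call. = FALSE)
  }
  best <- object$profile$k[which.min(object$profile$penalty)]
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$k,
    y = .data$penalty)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k",
      y = "Kelley-Gardner-Sutcliffe penalty") +
    ggplot2::theme_minimal()
}

#' Plot per-model BEDROC scores
#'
#' @param results Tibble from [bedroc_table()] (or [shortlist_models()]).
#' @param floor Optional BEDROC floor drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_bedroc <- function(results, floor = 0.5) {
  ggplot2::ggplot(results, ggplot2::aes(
    x = stats::reorder(.data$model_id, .data$bedroc), y = .data$bedroc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = floor, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "BEDROC") +
    ggplot2::theme_minimal()
}
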