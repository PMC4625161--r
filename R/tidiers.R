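#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy eigenvector scores of a PC model
#'
#' @param x A `pc_model` from [pca_fit()].
#' @param ... Unused.
#' @return For `tidy()`, a tibble with one row per sample: `sample`,
#'   `group`, then `EV1..EVk`. For `glance()`, one row per eigenvector with
#'   its eigenvalue and variance fraction.
#' @method tidy pc_model
#' @export
tidy.pc_model <- function(x, ...) {
  ev <- tibble::as_tibble(x$evec, .name_repair = ~ paste0("EV", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(sample = rownames(x$evec),
                                  group = x$samples$group), ev)
}

#' @rdname tidy.pc_model
#' @method glance pc_model
#' @export
glance.pc_model <- function(x, ...) {
  tibble::tibble(eigenvector = seq_along(x$eval), eigenvalue = x$eval,
                 variance_fraction = x$eval / sum(pmax(x$eval, 0)))
}

#' Eigenvector scatter of a PC model
#'
#' @param object A `pc_model`.
#' @param dims Two eigenvector indices to plot (default 1:2).
#' @param labels Optional group label per sample (defaults to the labels
#'   stored at fit time).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pc_model
#' @export
autoplot.pc_model <- function(object, dims = c(1L, 2L), labels = NULL, ...) {
  d <- tidy(object)
  if (!is.null(labels)) d$group <- labels
  xs <- paste0("EV", dims[1L]); ys <- paste0("EV", dims[2L])
  ggplot2::ggplot(d, ggplot2::aes(.data[[xs]], .data[[ys]],
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (eigenvalue %.3f)", xs, object$eval[dims[1L]]),
      y = sprintf("%s (eigenvalue %.3f)", ys, object$eval[dims[2L]]),
      colour = "group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Association scan overview plot
#'
#' Plots -log10 theoretical p by marker index, faceted by comparison, with
#' the significance ceiling drawn as a horizontal line.
#'
#' @param records Association records from [assoc_scan()].
#' @param p_ceiling Ceiling to draw (default 1e-5).
#' @return A ggplot.
#' @export
plot_association <- function(records, p_ceiling = 1e-5) {
  d <- dplyr::mutate(
    dplyr::group_by(records, .data$comparison),
    index = dplyr::row_number(),
    neglogp = -log10(.data$p_theoretical))
  ggplot2::ggplot(d, ggplot2::aes(.data$index, .data$neglogp)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(p_ceiling), linetype = 2,
                        colour = "red") +
    ggplot2::facet_wrap(~comparison, ncol = 1L) +
    ggplot2::labs(x = "marker index", y = "-log10 p (theoretical)") +
    ggplot2::theme_minimal()
}

#' Classification score plot
#'
#' Scatter of the two score differences that decide each sample's dominant
#' type, coloured by call.
#'
#' @param calls A [classify_samples()] result.
#' @return A ggplot.
#' @export
plot_classification <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(.data$d_VP, .data$d_KP,
                                      colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = expression(Delta[VP]), y = expression(Delta[KP]),
                  colour = "call") +
    ggplot2::theme_minimal()
}
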