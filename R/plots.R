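#' Plot a simulated vascular network
#'
#' @param object An [simulate_vessels()] result.
#' @param ... Unused.
#' @return A ggplot: trail points coloured by lineage.
#' @exportS3Method ggplot2::autoplot
autoplot.angio_sim <- function(object, ...) {
  ggplot2::ggplot(object$trail,
                  ggplot2::aes(.data$x, .data$y,
                               colour = factor(.data$lineage))) +
    ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
    ggplot2::coord_fixed(xlim = c(0, object$config$side_length),
                         ylim = c(0, object$config$side_length)) +
    ggplot2::labs(title = sprintf("%s model, seed %d", toupper(object$model),
                                  object$seed),
                  x = "x", y = "y (towards tumour)") +
    ggplot2::theme_minimal()
}

#' Plot an extended persistence diagram
#'
#' @param diagram An [extended_persistence()] tibble.
#' @return A ggplot of (birth, death) points by class and dimension.
#' @export
plot_diagram <- function(diagram) {
  ggplot2::ggplot(diagram,
                  ggplot2::aes(.data$birth, .data$death,
                               colour = .data$cls,
                               shape = factor(.data$dim))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "class", shape = "dimension") +
    ggplot2::theme_minimal()
}

#' Pairwise-marginal plot of an ABC-SMC posterior
#'
#' @param object An [abc_smc()] fit.
#' @param params Two parameter names (default: the first two).
#' @param truth Optional named true parameter vector to mark.
#' @param ... Unused.
#' @return A ggplot of the final-population particles, weighted, for one
#'   parameter pair.
#' @exportS3Method ggplot2::autoplot
autoplot.abc_smc <- function(object, params = NULL, truth = NULL, ...) {
  pop <- object$populations[[length(object$populations)]]
  params <- params %||% object$prior$param[1:2]
  p <- ggplot2::ggplot(pop,
                       ggplot2::aes(.data[[params[1]]], .data[[params[2]]],
                                    size = .data$weight)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue",
                        show.legend = FALSE) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::annotate("point", x = truth[[params[1]]],
                               y = truth[[params[2]]], colour = "red",
                               shape = 4, size = 3)
  }
  p
}
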