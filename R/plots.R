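#' Plot a particle size spectrum
#'
#' Bin-width-normalized abundance against the upper bin edge, on log10 axes.
#'
#' @param object A `size_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot size_spectrum
#' @export
autoplot.size_spectrum <- function(object, ...) {
  if (!"a_n" %in% names(object)) object <- normalize_to_bin_width(object)
  dat <- dplyr::filter(tibble::as_tibble(object), .data$count > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_upper, y = .data$a_n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Upper bin edge (mm)",
                  y = expression(A[n] ~ "(particles" ~ mm^-1 * ")")) +
    ggplot2::theme_bw()
}

#' Plot a power-law fit over its size spectrum
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  dat <- dplyr::filter(object$data, .data$count > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$midpoint, y = .data$a_n)) +
    ggplot2::geom_point() +
    ggplot2::geom_function(
      fun = function(d) 10^(object$intercept - object$exponent * log10(d)),
      colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Bin midpoint (mm)",
      y = expression(A[n] ~ "(particles" ~ mm^-1 * ")"),
      subtitle = sprintf("exponent = %.2f (%s fit above %g mm)",
                         object$exponent, object$method,
                         object$fit_min_diameter)) +
    ggplot2::theme_bw()
}

#' Plot NMDS sample coordinates
#'
#' @param object An `nmds_ordination`.
#' @param groups Optional sample-to-group mapping (data frame or named
#'   vector) used to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmds_ordination
#' @export
autoplot.nmds_ordination <- function(object, groups = NULL, ...) {
  pts <- object$points
  if (!is.null(groups)) {
    pts$group <- resolve_groups(groups, pts$sample)
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2,
                                           colour = .data$group))
  } else {
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(subtitle = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_bw()
}

#' Plot metabolic rates with error bars
#'
#' NCP, R and GPP per experiment with +/- one standard error.
#'
#' @param object A `rate_estimate` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rate_estimate
#' @export
autoplot.rate_estimate <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$.exp <- if ("experiment_id" %in% names(dat)) dat$experiment_id else
    as.character(seq_len(nrow(dat)))
  long <- tidyr::pivot_longer(
    dat, dplyr::all_of(c("ncp", "r", "gpp")),
    names_to = "component", values_to = "rate")
  ses <- tidyr::pivot_longer(
    dat, dplyr::all_of(c("se_ncp", "se_r", "se_gpp")),
    names_to = "component", values_to = "se")
  long$se <- ses$se
  long$component <- factor(toupper(long$component),
                           levels = c("NCP", "R", "GPP"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.exp, y = .data$rate,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate - .data$se, ymax = .data$rate + .data$se),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::labs(x = NULL, y = attr(object, "units") %||% "rate") +
    ggplot2::theme_bw()
}
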