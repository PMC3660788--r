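#' Plot a plate map
#'
#' False-colour map of per-well mean lifetimes on the plate grid; wells
#' where no cells were found are drawn white, excluded wells grey.
#'
#' @param object A [plate_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot plate_map
autoplot.plate_map <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value), colour = "grey40") +
    ggplot2::geom_tile(data = dplyr::filter(d, .data$missing),
                       fill = "white", colour = "grey40") +
    ggplot2::geom_tile(data = dplyr::filter(d, .data$excluded),
                       fill = "grey80", colour = "grey40") +
    ggplot2::scale_y_reverse(breaks = seq_len(max(d$row)),
                             labels = LETTERS[seq_len(max(d$row))]) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(d$col)),
                                position = "top") +
    ggplot2::scale_fill_viridis_c(option = "turbo", na.value = "white",
                                  name = "tau (ps)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response table
#'
#' Mean +/- SD per dose on a log-dose axis, with the fitted Hill curve
#' overlaid when available.
#'
#' @param object A [dose_response_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot dose_response
autoplot.dose_response <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_uM, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.05) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (uM)", y = "mean lifetime (ps)") +
    ggplot2::theme_minimal()
  hf <- attr(object, "hill_fit")
  if (!is.null(hf) && !isTRUE(hf$unidentifiable)) {
    grid <- exp(seq(log(min(d$dose_uM)), log(max(d$dose_uM)),
                    length.out = 100))
    curve <- tibble(dose_uM = grid,
                    mean = hf$bottom + (hf$top - hf$bottom) /
                      (1 + (hf$ec50_uM / grid)^hf$hill))
    p <- p + ggplot2::geom_line(data = curve, colour = "steelblue")
  }
  p
}

#' Plot a lifetime image
#'
#' @param object A `lifetime_image` from [fit_pixelwise()].
#' @param ... Unused.
#' @return A ggplot raster of the per-pixel lifetimes.
#' @export
#' @method autoplot lifetime_image
autoplot.lifetime_image <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$tau_ps)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "turbo", name = "tau (ps)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a mono-exponential fit against its data
#'
#' Counts per gate with the reconvolved model overlaid, on a log count
#' scale.
#'
#' @param object A [fit_monoexp()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot monoexp_fit
autoplot.monoexp_fit <- function(object, ...) {
  d <- tibble(delay = object$gate_delays_ps, counts = object$counts,
              fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delay)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$counts)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gate delay (ps)", y = "photon counts") +
    ggplot2::theme_minimal()
}
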