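## ggplot2 visualisation methods.

#' Tidy a parameter map into a long tibble
#'
#' @param x A `param_map`.
#' @param ... Unused.
#' @return A tibble with `x`, `y`, `value`, `quality`, `mask`.
#' @method tidy param_map
#' @export
tidy.param_map <- function(x, ...) {
  d <- dim(x$values)
  tibble(x = rep(seq_len(d[1]), d[2]),
         y = rep(seq_len(d[2]), each = d[1]),
         value = as.vector(x$values),
         quality = as.vector(x$quality),
         mask = as.vector(x$mask))
}

#' Plot a parameter map
#'
#' @param object A `param_map`.
#' @param ... Unused.
#' @return A ggplot raster of the fitted values (masked voxels only).
#' @method autoplot param_map
#' @export
autoplot.param_map <- function(object, ...) {
  df <- tidy.param_map(object)
  df$value[!df$mask] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black", name = object$kind) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a phantom label map
#'
#' @param object A `kidney_phantom`.
#' @param ... Unused.
#' @return A ggplot raster of the compartment labels.
#' @method autoplot kidney_phantom
#' @export
autoplot.kidney_phantom <- function(object, ...) {
  lab <- unclass(object$label_map)
  d <- dim(lab)
  df <- tibble(x = rep(seq_len(d[1]), d[2]),
               y = rep(seq_len(d[2]), each = d[1]),
               compartment = factor(as.vector(lab), levels = 0:3,
                                    labels = names(compartment_codes())))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$compartment)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot an ADC histogram (kernel density estimate)
#'
#' @param object An `adc_histogram`.
#' @param ... Unused.
#' @return A ggplot of the KDE curve.
#' @method autoplot adc_histogram
#' @export
autoplot.adc_histogram <- function(object, ...) {
  kde <- attr(object, "kde")
  df <- tibble(adc = kde$grid, density = kde$density)
  ggplot2::ggplot(df, ggplot2::aes(.data$adc, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ADC (1e-3 mm²/s)", y = "probability density")
}

#' Plot group means with SEM error bars
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot point-range of group means +/- SEM.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(y = object$metric, x = NULL)
}
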