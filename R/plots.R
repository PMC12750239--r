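# ggplot2 autoplot methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.bl_zprofile <- function(object, ...) {
  units <- c(number = "number density (nm^-3)",
             charge = "charge density (e nm^-3)",
             potential = "potential (V)")
  ggplot2::ggplot(tibble::tibble(z = bin_centers(object),
                                 value = object$values),
                  ggplot2::aes(x = .data$z, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = units[[object$quantity]]) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bl_order_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$carbon_index,
                                       y = .data$s_cd,
                                       colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$s_cd - .data$stderr,
                                          ymax = .data$s_cd + .data$stderr)) +
    ggplot2::labs(x = "carbon index", y = expression(S[CD])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bl_msd <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(lag = object$lag_ps, msd = object$msd_nm2),
                  ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ps)", y = expression(MSD ~ (nm^2))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bl_rdf <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(r = object$r, g = object$g),
                  ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "r (nm)", y = "g(r)") +
    ggplot2::theme_minimal()
}
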