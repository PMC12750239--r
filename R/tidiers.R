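# broom-style tidiers for fitted/derived result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bl_report <- function(x, ...) x$values

#' @export
glance.bl_report <- function(x, ...) {
  wide <- x$values |>
    dplyr::select("observable", "value") |>
    tidyr::pivot_wider(names_from = "observable", values_from = "value")
  dplyr::bind_cols(tibble::tibble(system = x$system,
                                  n_errors = length(x$errors)), wide)
}

#' @export
tidy.bl_thickness <- function(x, ...) {
  tibble::tibble(term = "thickness", estimate = x$thickness,
                 std.error = x$uncertainty, unit = "nm", method = x$method)
}

#' @export
tidy.bl_packing <- function(x, ...) {
  tibble::tibble(term = c("area_per_lipid", "packing_density"),
                 estimate = c(x$apl, x$packing_density),
                 std.error = c(NA_real_, x$uncertainty),
                 unit = c("nm^2", "nm^-2"))
}

#' @export
tidy.bl_diffusion <- function(x, ...) {
  tibble::tibble(term = "diffusion_coefficient", estimate = x$d_cm2_s,
                 std.error = x$uncertainty, unit = "cm^2/s")
}

#' @export
glance.bl_diffusion <- function(x, ...) {
  tibble::tibble(d_cm2_s = x$d_cm2_s, r.squared = x$r_squared,
                 fit_lo_ps = x$fit_window_ps[1], fit_hi_ps = x$fit_window_ps[2])
}

#' @export
tidy.bl_msd <- function(x, ...) {
  tibble::tibble(lag_ps = x$lag_ps, msd_nm2 = x$msd_nm2,
                 n_origins = x$n_origins)
}

#' @export
tidy.bl_rdf <- function(x, ...) {
  tibble::tibble(r = x$r, g = x$g, mode = x$mode)
}

#' @export
tidy.bl_zprofile <- function(x, ...) {
  tibble::tibble(z = bin_centers(x), value = x$values, quantity = x$quantity)
}
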