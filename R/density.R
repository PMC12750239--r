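# z-binned density profiles along the membrane normal, headgroup-peak
# bilayer thickness, and the transmembrane electrostatic potential from
# double integration of the one-dimensional Poisson equation.

# physical constants (SI)
EPSILON0 <- 8.8541878128e-12   # F/m
E_CHARGE <- 1.602176634e-19    # C

#' Construct a z-profile from binned values
#'
#' Builds a `bl_zprofile` directly from bin edges and per-bin values —
#' e.g. a charge-density profile assembled from an external tool or an
#' analytic construction — so it can flow into
#' [electrostatic_potential()] and the plotting/tidying methods.
#'
#' @param bin_edges Monotone bin edges along z, nm (length n+1).
#' @param values Per-bin values (length n): number density (nm^-3),
#'   charge density (e nm^-3) or potential (V).
#' @param quantity `"number"`, `"charge"` or `"potential"`.
#' @return A `bl_zprofile`.
#' @export
zprofile <- function(bin_edges, values,
                     quantity = c("number", "charge", "potential")) {
  quantity <- match.arg(quantity)
  if (any(diff(bin_edges) <= 0)) rlang::abort("bin_edges must be increasing")
  new_zprofile(bin_edges, values, quantity, frames_averaged = 1L)
}

new_zprofile <- function(bin_edges, values, quantity, frames_averaged,
                         area = NA_real_, centered = TRUE) {
  stopifnot(length(values) == length(bin_edges) - 1)
  structure(list(bin_edges = bin_edges, values = values, quantity = quantity,
                 frames_averaged = frames_averaged, area = area,
                 centered = centered),
            class = "bl_zprofile")
}

#' Bin centers of a z-profile
#' @param profile A `bl_zprofile`.
#' @return Numeric vector of bin-center positions (nm).
#' @export
bin_centers <- function(profile) {
  e <- profile$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' @export
print.bl_zprofile <- function(x, ...) {
  cat("<bl_zprofile> ", x$quantity, ", ", length(x$values), " bins over [",
      round(x$bin_edges[1], 3), ", ", round(max(x$bin_edges), 3),
      "] nm, averaged over ", x$frames_averaged, " frame(s)\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.bl_zprofile <- function(x, ...) {
  tibble::tibble(z = bin_centers(x), value = x$values, quantity = x$quantity)
}

#' Number or charge density profile along the membrane normal
#'
#' Slices the box into z-slabs and accumulates, per frame, either the
#' count of selected atoms (number density, nm^-3) or the sum of their
#' partial charges (charge density, e nm^-3), divided by the slab volume
#' and averaged over the analysis window. By default coordinates are
#' re-centered on the per-frame bilayer midplane (mean z of all lipid
#' atoms) so slow bilayer drift does not smear the profile; the bin grid
#' then spans `[-lz/2, lz/2)` of the mean box.
#'
#' @param traj A [bl_trajectory].
#' @param selection Atom selection, an unquoted expression over the atom
#'   table columns (e.g. `role == "head"`); `NULL` selects all atoms.
#' @param bin_width Slab thickness in nm (default 0.05).
#' @param quantity `"number"` or `"charge"`.
#' @param center Re-center each frame on the bilayer midplane (default
#'   `TRUE`); with `FALSE` the grid spans `[0, lz)` in box coordinates.
#' @return A `bl_zprofile`.
#' @export
z_profile <- function(traj, selection = NULL, bin_width = 0.05,
                      quantity = c("number", "charge"), center = TRUE) {
  z_profile_impl(traj, rlang::enquo(selection), bin_width,
                 match.arg(quantity), center)
}

z_profile_impl <- function(traj, sel_quo, bin_width, quantity, center) {
  stopifnot(bin_width > 0)
  sel <- select_atoms(traj$topology, sel_quo)
  frames <- analysis_frames(traj)
  box <- mean_box(traj)
  lz <- box[3]

  n_bins <- floor(lz / bin_width + 1e-9)
  covered <- n_bins * bin_width
  if (lz - covered > 1e-9) {
    rlang::warn(sprintf(
      "bin width %.4g does not divide lz = %.4g nm; trailing %.4g nm dropped",
      bin_width, lz, lz - covered))
  }
  lo <- if (center) -covered / 2 else 0
  edges <- lo + bin_width * (0:n_bins)
  area <- box[1] * box[2]

  if (length(sel) == 0) {
    rlang::warn("empty atom selection; returning an all-zero profile")
    return(new_zprofile(edges, numeric(n_bins), quantity, length(frames),
                        area = area, centered = center))
  }

  charges <- traj$topology$atoms$charge[sel]
  lipid_rows <- !is.na(traj$topology$atoms$lipid_id)
  acc <- numeric(n_bins)
  for (f in frames) {
    z <- f$xyz[sel, 3]
    if (center) {
      mid <- mean(f$xyz[lipid_rows, 3])
      z <- z - mid
      z <- z - covered * floor((z - lo) / covered)  # wrap into [lo, lo+covered)
    } else {
      z <- z - covered * floor(z / covered)
    }
    idx <- pmin(floor((z - lo) / bin_width) + 1, n_bins)
    if (quantity == "charge") {
      agg <- rowsum(charges, idx)
      acc[as.integer(rownames(agg))] <- acc[as.integer(rownames(agg))] + agg[, 1]
    } else {
      acc <- acc + tabulate(idx, n_bins)
    }
  }
  vals <- acc / (length(frames) * area * bin_width)
  new_zprofile(edges, vals, quantity, length(frames),
               area = area, centered = center)
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  if (window %% 2 == 0) window <- window + 1
  k <- rep(1 / window, window)
  as.numeric(stats::filter(x, k, sides = 2, circular = TRUE))
}

#' Bilayer thickness from headgroup density peaks
#'
#' The thickness is the separation of the two maxima of the (smoothed)
#' headgroup number-density profile, one on each side of the bilayer
#' midplane — the standard peak-to-peak definition. The uncertainty is a
#' block estimate: the analysis window is split into contiguous blocks,
#' the thickness recomputed per block, and [block_error()] applied.
#'
#' A profile without two clear peaks (e.g. a non-lamellar aggregate with
#' heads scattered in z) is refused: each side's peak must stand above
#' `peak_factor` times the profile mean.
#'
#' @param traj A [bl_trajectory].
#' @param head_selection Atom selection for headgroup atoms (default
#'   `role == "head"`).
#' @param bin_width Profile bin width, nm.
#' @param smooth_window Moving-average window in bins applied before peak
#'   finding (default 5).
#' @param n_blocks Blocks for the uncertainty estimate (default 5).
#' @param peak_factor Required ratio of each peak to the mean smoothed
#'   density (default 2); below it the profile is declared non-lamellar.
#' @return A `bl_thickness` object: `thickness`, `peak_lower`,
#'   `peak_upper` (nm, midplane-centered), `uncertainty`, `method`.
#' @export
bilayer_thickness <- function(traj, head_selection = role == "head",
                              bin_width = 0.05, smooth_window = 5,
                              n_blocks = 5, peak_factor = 2) {
  sel_quo <- rlang::enquo(head_selection)

  measure <- function(subtraj) {
    prof <- z_profile_impl(subtraj, sel_quo, bin_width, "number", TRUE)
    peaks_from_profile(prof, smooth_window, peak_factor)
  }

  full <- measure(traj)

  times <- frame_times(traj)
  keep <- which(times >= traj$window[1] & times <= traj$window[2])
  unc <- NA_real_
  if (length(keep) >= n_blocks && n_blocks >= 2) {
    grp <- split(keep, cut(seq_along(keep), n_blocks, labels = FALSE))
    block_vals <- vapply(grp, function(ix) {
      sub <- traj
      sub$frames <- traj$frames[ix]
      sub$window <- range(times[ix])
      tryCatch(measure(sub)$thickness, error = function(e) NA_real_)
    }, numeric(1))
    block_vals <- block_vals[!is.na(block_vals)]
    if (length(block_vals) >= 2) {
      unc <- block_error(block_vals, n_blocks = length(block_vals))$stderr
    }
  }

  structure(list(thickness = full$thickness, peak_lower = full$peak_lower,
                 peak_upper = full$peak_upper, uncertainty = unc,
                 method = "peak_to_peak", bin_width = bin_width),
            class = "bl_thickness")
}

peaks_from_profile <- function(prof, smooth_window, peak_factor) {
  z <- bin_centers(prof)
  s <- moving_average(prof$values, smooth_window)
  lower <- which(z < 0)
  upper <- which(z > 0)
  if (length(lower) == 0 || length(upper) == 0 || all(s == 0)) {
    rlang::abort("no bilayer peaks: headgroup density lacks two maxima")
  }
  i_lo <- lower[which.max(s[lower])]
  i_up <- upper[which.max(s[upper])]
  if (s[i_lo] < peak_factor * mean(s) || s[i_up] < peak_factor * mean(s)) {
    rlang::abort("no bilayer peaks: headgroup density lacks two maxima")
  }
  bw <- z[2] - z[1]
  if (z[i_up] - z[i_lo] <= smooth_window * bw) {
    # both maxima inside one smoothing kernel: a single layer, not two
    rlang::abort("no bilayer peaks: headgroup density lacks two maxima")
  }
  list(peak_lower = z[i_lo], peak_upper = z[i_up],
       thickness = z[i_up] - z[i_lo])
}

#' @export
print.bl_thickness <- function(x, ...) {
  cat(sprintf("<bl_thickness> %.3f +/- %s nm (peaks at %.3f / %.3f nm, %s)\n",
              x$thickness,
              if (is.na(x$uncertainty)) "NA" else sprintf("%.3f", x$uncertainty),
              x$peak_lower, x$peak_upper, x$method))
  invisible(x)
}

#' Electrostatic potential from a charge-density profile
#'
#' Solves the one-dimensional Poisson equation by two successive
#' cumulative trapezoidal integrations of the laterally averaged charge
#' density over the bin centers:
#' \deqn{V(z) = -\frac{1}{\varepsilon_0}\int_0^z dz' \int_0^{z'} \rho(z'')\,dz''}
#' with the boundary convention V = 0 at the profile origin (the start of
#' the box). Input charge density in e nm^-3 is converted to SI so the
#' output is in volts.
#'
#' @param charge_profile A `bl_zprofile` with `quantity == "charge"`.
#' @return A `bl_potential` object with fields `profile` (a volt-valued
#'   `bl_zprofile` on the same grid), `delta_v` (default-convention
#'   magnitude, see [potential_difference()]), `epsilon0`.
#' @export
electrostatic_potential <- function(charge_profile) {
  if (!inherits(charge_profile, "bl_zprofile") ||
      charge_profile$quantity != "charge") {
    rlang::abort("electrostatic_potential() needs a charge-density profile")
  }
  z_m <- bin_centers(charge_profile) * 1e-9
  rho_si <- charge_profile$values * E_CHARGE * 1e27   # e nm^-3 -> C m^-3
  cum1 <- pracma::cumtrapz(z_m, rho_si)               # C m^-2
  v <- -as.numeric(pracma::cumtrapz(z_m, as.numeric(cum1))) / EPSILON0
  prof <- new_zprofile(charge_profile$bin_edges, v, "potential",
                       charge_profile$frames_averaged,
                       area = charge_profile$area,
                       centered = charge_profile$centered)
  res <- structure(list(profile = prof, epsilon0 = EPSILON0,
                        convention = "center_vs_bulk"), class = "bl_potential")
  res$delta_v <- potential_difference(res, "center_vs_bulk")
  res
}

#' @export
print.bl_potential <- function(x, ...) {
  cat(sprintf("<bl_potential> |dV| = %.4f V (%s), %d bins\n",
              x$delta_v, x$convention, length(x$profile$values)))
  invisible(x)
}

#' Potential difference across the bilayer
#'
#' Two conventions are provided. `"center_vs_bulk"` (default): potential
#' at the profile center minus the mean potential over the outermost
#' `bulk_width` nm of each side (averaged over both sides) — the membrane
#' interior relative to bulk water. `"max_minus_min"`: the full range of
#' the profile. Both are reported as magnitudes.
#'
#' @param pot A `bl_potential`.
#' @param convention `"center_vs_bulk"` or `"max_minus_min"`.
#' @param bulk_width Width (nm) of the bulk region at each end (default 1).
#' @return Potential difference in volts (magnitude).
#' @export
potential_difference <- function(pot,
                                 convention = c("center_vs_bulk",
                                                "max_minus_min"),
                                 bulk_width = 1) {
  convention <- match.arg(convention)
  v <- pot$profile$values
  z <- bin_centers(pot$profile)
  if (convention == "max_minus_min") return(abs(max(v) - min(v)))
  z_mid <- (min(pot$profile$bin_edges) + max(pot$profile$bin_edges)) / 2
  v_center <- v[which.min(abs(z - z_mid))]
  lo_bulk <- z <= min(z) + bulk_width
  hi_bulk <- z >= max(z) - bulk_width
  v_bulk <- (mean(v[lo_bulk]) + mean(v[hi_bulk])) / 2
  abs(v_center - v_bulk)
}

#' Export a z-profile as two-column TSV
#'
#' @param profile A `bl_zprofile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  units <- c(number = "nm^-3", charge = "e nm^-3", potential = "V")
  df <- data.frame(z_center_nm = bin_centers(profile), value = profile$values)
  names(df)[2] <- paste0(profile$quantity, "_", units[[profile$quantity]])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
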