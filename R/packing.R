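# Area per lipid / packing density, lateral diffusion via the Einstein
# relation, and the shared block-averaging error estimator.

#' Block-averaging mean and standard error
#'
#' Splits a series of correlated per-frame values into `n_blocks`
#' contiguous blocks and estimates the standard error as the spread of
#' the block means: `stderr = sd_pop(block means) / sqrt(n_blocks)`,
#' with the population standard deviation. Replicate runs can be passed
#' as pre-averaged values with `n_blocks = length(series)`, treating each
#' replicate as one block.
#'
#' @param series Numeric vector (per-frame or per-replicate values).
#' @param n_blocks Number of contiguous blocks (>= 2).
#' @return List with `mean` and `stderr`.
#' @export
block_error <- function(series, n_blocks = 5) {
  if (n_blocks < 2) rlang::abort("n_blocks must be >= 2")
  if (length(series) < n_blocks) {
    rlang::abort("series has fewer values than blocks")
  }
  grp <- cut(seq_along(series), n_blocks, labels = FALSE)
  bm <- tapply(series, grp, mean)
  sd_pop <- sqrt(mean((bm - mean(bm))^2))
  list(mean = mean(series), stderr = sd_pop / sqrt(n_blocks))
}

#' Packing density and area per lipid
#'
#' The area per lipid (APL) is the lateral box area divided by the number
#' of lipids per leaflet, averaged over the analysis window; the packing
#' density is its reciprocal, `n_leaflet / <lx ly>`. The identity
#' `packing x APL = 1` holds exactly by construction.
#'
#' @param traj A [bl_trajectory].
#' @param n_leaflet Lipids per leaflet; default half the lipid count (or
#'   the upper-leaflet count when leaflets are assigned).
#' @param n_blocks Blocks for the uncertainty (default 5).
#' @return A `bl_packing` object: `apl` (mean nm^2), `apl_series`,
#'   `packing_density` (nm^-2), `uncertainty` (on the packing density),
#'   `n_leaflet`.
#' @export
packing_density <- function(traj, n_leaflet = NULL, n_blocks = 5) {
  if (is.null(n_leaflet)) {
    lf <- traj$topology$lipids$leaflet
    n_leaflet <- if (any(lf == "upper")) sum(lf == "upper")
                 else nrow(traj$topology$lipids) / 2
  }
  if (n_leaflet <= 0) rlang::abort("n_leaflet must be positive")
  frames <- analysis_frames(traj)
  areas <- vapply(frames, function(f) f$box[1] * f$box[2], numeric(1))
  if (any(areas <= 0)) rlang::abort("zero lateral box area")
  apl_series <- areas / n_leaflet
  apl <- mean(apl_series)
  dens <- 1 / apl
  unc <- NA_real_
  if (length(apl_series) >= n_blocks && n_blocks >= 2) {
    be <- block_error(1 / apl_series, n_blocks)
    unc <- be$stderr
  }
  structure(list(apl = apl, apl_series = apl_series,
                 packing_density = dens, uncertainty = unc,
                 n_leaflet = n_leaflet),
            class = "bl_packing")
}

#' @export
print.bl_packing <- function(x, ...) {
  cat(sprintf("<bl_packing> APL = %.4f nm^2, packing = %.4f +/- %s nm^-2 (n_leaflet = %g)\n",
              x$apl, x$packing_density,
              if (is.na(x$uncertainty)) "NA" else sprintf("%.4f", x$uncertainty),
              x$n_leaflet))
  invisible(x)
}

#' Unwrap lateral lipid center-of-mass tracks
#'
#' Builds continuous (unwrapped) xy tracks of per-lipid centers of mass
#' across the analysis window: each frame-to-frame displacement is
#' minimum-image corrected and accumulated, undoing the periodic
#' wrapping that coordinate files apply. Requires that no lipid moves
#' more than half a box edge between consecutive frames.
#'
#' @param traj A [bl_trajectory] (leaflets should be assigned for drift
#'   removal downstream).
#' @param selection Optional atom selection restricting which atoms enter
#'   each lipid's center of mass (default: all atoms of the lipid).
#' @return A `bl_tracks` object: `time` (ps), `x`, `y` (frames x lipids
#'   matrices, nm, continuous), `lipid_id`, `leaflet`.
#' @export
unwrap_lateral <- function(traj, selection = NULL) {
  sel_quo <- rlang::enquo(selection)
  atoms <- traj$topology$atoms
  sel <- select_atoms(traj$topology, sel_quo)
  sel <- sel[!is.na(atoms$lipid_id[sel])]
  if (length(sel) == 0) rlang::abort("selection contains no lipid atoms")

  lip <- factor(atoms$lipid_id[sel])
  w <- atoms$mass[sel]
  wsum <- as.numeric(tapply(w, lip, sum))
  frames <- analysis_frames(traj)

  # reference atom per lipid: intra-lipid offsets are unwrapped relative
  # to it so a molecule straddling the box edge gets a proper center
  ref_row <- sel[match(levels(lip), as.character(atoms$lipid_id[sel]))]
  ref_of_atom <- ref_row[as.integer(lip)]

  com_xy <- function(f) {
    out <- matrix(NA_real_, nlevels(lip), 2)
    for (d in 1:2) {
      rx <- f$xyz[ref_of_atom, d]
      dx <- f$xyz[sel, d] - rx
      dx <- dx - f$box[d] * round(dx / f$box[d])
      out[, d] <- f$xyz[ref_row, d] +
        as.numeric(tapply(w * dx, lip, sum)) / wsum
    }
    out
  }

  n_lip <- nlevels(lip)
  n_fr <- length(frames)
  x <- matrix(NA_real_, n_fr, n_lip)
  y <- matrix(NA_real_, n_fr, n_lip)
  prev <- com_xy(frames[[1]])
  x[1, ] <- prev[, 1]; y[1, ] <- prev[, 2]
  for (fi in seq_len(n_fr)[-1]) {
    cur <- com_xy(frames[[fi]])
    box <- frames[[fi]]$box
    d <- cur - prev
    wrapped <- cbind(d[, 1] - box[1] * round(d[, 1] / box[1]),
                     d[, 2] - box[2] * round(d[, 2] / box[2]))
    if (any(abs(wrapped) >= pmin(box[1], box[2]) / 2 - 1e-12)) {
      rlang::abort("frame spacing too coarse: displacement >= half box edge")
    }
    x[fi, ] <- x[fi - 1, ] + wrapped[, 1]
    y[fi, ] <- y[fi - 1, ] + wrapped[, 2]
    prev <- cur
  }

  ids <- as.integer(levels(lip))
  lf <- traj$topology$lipids$leaflet[match(ids, traj$topology$lipids$lipid_id)]
  structure(list(time = vapply(frames, function(f) f$time, numeric(1)),
                 x = x, y = y, lipid_id = ids, leaflet = lf),
            class = "bl_tracks")
}

#' Lateral mean-square displacement
#'
#' Einstein-relation MSD estimator over per-lipid xy tracks:
#' `msd(tau) = <|r(t + tau) - r(t)|^2>` averaged over lipids and sliding
#' time origins. With `remove_drift = TRUE` (default) the per-leaflet
#' center-of-mass position is subtracted per frame first, removing
#' collective drift that would otherwise inflate the apparent diffusion.
#'
#' @param tracks A `bl_tracks` from [unwrap_lateral()].
#' @param max_lag Largest lag in ps; default half the track length.
#' @param origin_stride Use every `origin_stride`-th frame as a time
#'   origin (default 1: all origins).
#' @param remove_drift Subtract per-leaflet COM drift (default `TRUE`).
#' @return A `bl_msd` object: tibble columns `lag_ps`, `msd_nm2`,
#'   `n_origins`.
#' @export
lateral_msd <- function(tracks, max_lag = NULL, origin_stride = 1,
                        remove_drift = TRUE) {
  t <- tracks$time
  n_fr <- length(t)
  if (n_fr < 2) rlang::abort("need at least 2 frames for an MSD")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    rlang::warn("frame times not equally spaced; lags use the mean spacing")
  }
  step <- mean(dt)
  span <- t[n_fr] - t[1]
  if (is.null(max_lag)) max_lag <- span / 2
  if (max_lag >= span + 1e-9) rlang::abort("max_lag exceeds the track length")

  x <- tracks$x; y <- tracks$y
  if (remove_drift) {
    for (lf in unique(tracks$leaflet)) {
      cols <- which(tracks$leaflet == lf)
      x[, cols] <- x[, cols] - rowMeans(x[, cols, drop = FALSE])
      y[, cols] <- y[, cols] - rowMeans(y[, cols, drop = FALSE])
    }
  }

  max_k <- min(n_fr - 1, floor(max_lag / step + 1e-9))
  lags <- seq_len(max_k)
  msd <- numeric(max_k)
  n_origins <- integer(max_k)
  for (k in lags) {
    origins <- seq(1, n_fr - k, by = origin_stride)
    dx <- x[origins + k, , drop = FALSE] - x[origins, , drop = FALSE]
    dy <- y[origins + k, , drop = FALSE] - y[origins, , drop = FALSE]
    msd[k] <- mean(dx^2 + dy^2)
    n_origins[k] <- length(origins)
  }

  structure(list(lag_ps = c(0, lags * step), msd_nm2 = c(0, msd),
                 n_origins = c(length(seq(1, n_fr, by = origin_stride)),
                               n_origins)),
            class = "bl_msd")
}

#' @export
print.bl_msd <- function(x, ...) {
  cat("<bl_msd> ", length(x$lag_ps), " lags up to ",
      max(x$lag_ps), " ps\n", sep = "")
  invisible(x)
}

#' Lateral diffusion coefficient from an MSD curve
#'
#' Least-squares fit of msd(tau) over a central lag window (default the
#' 10-50% span of available lags, avoiding short-time cage effects and
#' the noisy long-lag tail); for two lateral dimensions D = slope / 4.
#' Reported in cm^2/s (1 nm^2/ps = 1e-2 cm^2/s).
#'
#' @param msd A `bl_msd`.
#' @param fit_window Fractions `c(lo, hi)` of the maximum lag to fit over.
#' @return A `bl_diffusion` object: `d_cm2_s`, `fit_window_ps`,
#'   `r_squared`, `uncertainty` (slope standard error propagated to D).
#' @export
diffusion_coefficient <- function(msd, fit_window = c(0.1, 0.5)) {
  lag <- msd$lag_ps
  m <- msd$msd_nm2
  lo <- fit_window[1] * max(lag)
  hi <- fit_window[2] * max(lag)
  keep <- lag >= lo & lag <= hi
  if (sum(keep) < 2) rlang::abort("fit window contains fewer than 2 lags")
  fit <- stats::lm(m[keep] ~ lag[keep])
  slope <- unname(stats::coef(fit)[2])          # nm^2 / ps
  sm <- suppressWarnings(summary(fit))          # exact lines are fine here
  se <- sm$coefficients[2, 2]
  r2 <- sm$r.squared
  d <- slope / 4 * 1e-2                          # cm^2/s
  if (d < 0) {
    rlang::warn(sprintf("negative MSD slope (D = %.3g cm^2/s); reporting as-is", d))
  }
  structure(list(d_cm2_s = d, fit_window_ps = c(lo, hi),
                 r_squared = r2, uncertainty = se / 4 * 1e-2),
            class = "bl_diffusion")
}

#' @export
print.bl_diffusion <- function(x, ...) {
  cat(sprintf("<bl_diffusion> D = %.4f x 10^-7 cm^2/s (fit %g-%g ps, r^2 = %.4f)\n",
              x$d_cm2_s / 1e-7, x$fit_window_ps[1], x$fit_window_ps[2],
              x$r_squared))
  invisible(x)
}

#' Export an MSD curve as TSV
#' @param msd A `bl_msd`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msd_tsv <- function(msd, path) {
  utils::write.table(data.frame(lag_ps = msd$lag_ps, msd_nm2 = msd$msd_nm2),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
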