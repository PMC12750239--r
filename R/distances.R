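# Intramolecular atom-pair distances, radial distribution functions with
# minimum-image periodic boundaries, first-shell (nearest-neighbor)
# distances, and single-conformation end-to-end lengths.

#' Resolve a within-lipid atom selector
#'
#' A selector is either a label string (matched against the atom `label`
#' column, then against `name`) or a list `list(role =, carbon =)`. It
#' must resolve to exactly one atom per lipid.
#' @noRd
resolve_selector <- function(atoms, lipid_rows, sel, lipid_id) {
  if (is.character(sel)) {
    hit <- lipid_rows[atoms$label[lipid_rows] == sel]
    if (length(hit) == 0) hit <- lipid_rows[atoms$name[lipid_rows] == sel]
  } else {
    hit <- lipid_rows[atoms$role[lipid_rows] == sel$role]
    if (!is.null(sel$carbon)) {
      hit <- hit[atoms$carbon[hit] %in% sel$carbon]
    }
  }
  if (length(hit) != 1) {
    rlang::abort(sprintf(
      "selector '%s' resolves to %d atoms in lipid %d (must be exactly 1)",
      if (is.character(sel)) sel else paste0(sel$role, "[", sel$carbon, "]"),
      length(hit), lipid_id))
  }
  hit
}

#' Average intramolecular atom-pair distances
#'
#' For each named pair of selectors, measures the minimum-image distance
#' between the two atoms within every lipid in every analysis frame and
#' averages; the uncertainty is a block estimate over per-frame means.
#' Minimum image is applied even within a molecule since wrapped
#' coordinates can split a lipid across the box.
#'
#' @param traj A [bl_trajectory].
#' @param pairs Named list; each element is a list/vector of two
#'   selectors, e.g. `list(N1_N2 = c("N1", "N2"))`.
#' @param species Optional species restriction.
#' @param n_blocks Blocks for uncertainties (default 5).
#' @return A tibble: `pair`, `mean_nm`, `stderr_nm`, `n_lipids`.
#' @export
intramolecular_distances <- function(traj, pairs, species = NULL,
                                     n_blocks = 5) {
  atoms <- traj$topology$atoms
  lipids <- traj$topology$lipids
  if (!is.null(species)) lipids <- lipids[lipids$species == species, ]
  frames <- analysis_frames(traj)

  rows_by_lipid <- split(seq_len(nrow(atoms)), atoms$lipid_id)

  purrr::imap_dfr(pairs, function(p, nm) {
    ia <- ib <- integer(nrow(lipids))
    for (j in seq_len(nrow(lipids))) {
      lr <- rows_by_lipid[[as.character(lipids$lipid_id[j])]]
      ia[j] <- resolve_selector(atoms, lr, p[[1]], lipids$lipid_id[j])
      ib[j] <- resolve_selector(atoms, lr, p[[2]], lipids$lipid_id[j])
    }
    per_frame <- vapply(frames, function(f) {
      mean(min_image_distance(f$xyz[ia, , drop = FALSE],
                              f$xyz[ib, , drop = FALSE], f$box))
    }, numeric(1))
    nb <- min(n_blocks, length(per_frame))
    est <- if (nb >= 2) block_error(per_frame, nb)
           else list(mean = mean(per_frame), stderr = NA_real_)
    tibble::tibble(pair = nm, mean_nm = est$mean, stderr_nm = est$stderr,
                   n_lipids = nrow(lipids))
  })
}

#' Radial distribution function under periodic boundaries
#'
#' Intermolecular pair correlation between two atom selections: pairs
#' within the same lipid are excluded, distances use the minimum-image
#' convention, and the histogram is normalized by the exact shell volume
#' (`4/3 pi (r2^3 - r1^3)` in 3d; annulus area times slab height in
#' lateral mode) and the ideal-gas density of the second selection, so
#' g -> 1 at large r for a homogeneous system.
#'
#' @param traj A [bl_trajectory].
#' @param sel_a,sel_b Atom selections (unquoted expressions).
#' @param r_max Maximum distance, nm; must not exceed half the smallest
#'   box edge in 3d mode.
#' @param dr Bin width, nm (default 0.002).
#' @param mode `"3d"` or `"lateral"` (in-plane xy distances).
#' @return A `bl_rdf` object: `r` (bin centers), `g`, `mode`, plus the
#'   raw mean pair counts per bin (`counts`).
#' @export
rdf <- function(traj, sel_a, sel_b, r_max = NULL, dr = 0.002,
                mode = c("3d", "lateral")) {
  mode <- match.arg(mode)
  atoms <- traj$topology$atoms
  a <- select_atoms(traj$topology, rlang::enquo(sel_a))
  b <- select_atoms(traj$topology, rlang::enquo(sel_b))
  if (length(a) == 0 || length(b) == 0) rlang::abort("empty RDF selection")
  box <- mean_box(traj)
  if (is.null(r_max)) r_max <- min(box[1:2], if (mode == "3d") box[3]) / 2
  if (mode == "3d" && r_max > min(box) / 2 + 1e-9) {
    rlang::abort("r_max exceeds half the smallest box edge")
  }

  n_bins <- ceiling(r_max / dr - 1e-9)
  edges <- dr * (0:n_bins)
  frames <- analysis_frames(traj)

  lip_a <- atoms$lipid_id[a]
  lip_b <- atoms$lipid_id[b]
  # same-molecule pairs excluded: intermolecular by definition
  excl <- outer(lip_a, lip_b, function(p, q) !is.na(p) & !is.na(q) & p == q)
  self <- outer(a, b, "==")
  valid <- !(excl | self)
  if (mode == "lateral") {
    # in-plane correlations are per leaflet: cross-leaflet pairs sit at
    # small xy separations that say nothing about lateral packing
    lf <- traj$topology$lipids
    lf_of <- function(ids) lf$leaflet[match(ids, lf$lipid_id)]
    la <- lf_of(lip_a); lb <- lf_of(lip_b)
    if (any(c(la, lb) %in% c("upper", "lower"))) {
      same <- outer(la, lb, function(p, q) !is.na(p) & !is.na(q) &
                      p == q & p %in% c("upper", "lower"))
      valid <- valid & same
    }
  }
  if (!any(valid)) rlang::abort("no intermolecular pairs in RDF selections")

  counts <- numeric(n_bins)
  for (f in frames) {
    pa <- f$xyz[a, , drop = FALSE]
    pb <- f$xyz[b, , drop = FALSE]
    for (d in 1:(if (mode == "3d") 3 else 2)) {
      dd <- outer(pa[, d], pb[, d], "-")
      dd <- dd - f$box[d] * round(dd / f$box[d])
      if (d == 1) acc <- dd^2 else acc <- acc + dd^2
    }
    r <- sqrt(acc[valid])
    r <- r[r < r_max]
    if (length(r) > 0) {
      counts <- counts + tabulate(pmin(floor(r / dr) + 1, n_bins), n_bins)
    }
  }
  counts <- counts / length(frames)

  # ideal-gas reference: the expected bin count for the same valid pair
  # set placed uniformly (shell volume over box volume in 3d, annulus
  # area over box area in lateral mode)
  n_valid <- sum(valid)
  if (mode == "3d") {
    shell_frac <- 4 / 3 * pi * (edges[-1]^3 - edges[-(n_bins + 1)]^3) /
      (box[1] * box[2] * box[3])
  } else {
    shell_frac <- pi * (edges[-1]^2 - edges[-(n_bins + 1)]^2) /
      (box[1] * box[2])
  }
  g <- counts / (n_valid * shell_frac)

  structure(list(r = (edges[-1] + edges[-(n_bins + 1)]) / 2, g = g,
                 counts = counts, mode = mode, dr = dr, r_max = r_max,
                 n_a = length(a), n_valid_pairs = n_valid),
            class = "bl_rdf")
}

#' @export
print.bl_rdf <- function(x, ...) {
  cat("<bl_rdf> ", x$mode, " mode, ", length(x$r), " bins to r_max = ",
      x$r_max, " nm\n", sep = "")
  invisible(x)
}

#' First-peak position of an RDF
#'
#' The position of the first local maximum of the smoothed g(r) with
#' g > 1 — the nearest-neighbor shell distance, the standard reading of
#' an "average intermolecular distance from the RDF". Ties between equal
#' neighboring bins break to the lower bin.
#'
#' @param rdf_result A `bl_rdf`.
#' @param smooth_window Moving-average window in bins (default 5).
#' @return First-peak distance in nm.
#' @export
first_peak_distance <- function(rdf_result, smooth_window = 5) {
  g <- moving_average(rdf_result$g, smooth_window)
  n <- length(g)
  for (i in 2:(n - 1)) {
    if (g[i] > 1 && g[i] > g[i - 1] && g[i] >= g[i + 1]) {
      return(rdf_result$r[i])
    }
  }
  rlang::abort("structureless RDF: no local maximum above g = 1")
}

#' First-shell weighted mean distance (alternative reading)
#'
#' Mean distance over the first coordination shell, weighting each bin by
#' its pair count, integrating from the first g > 1 crossing to the first
#' minimum after the peak.
#'
#' @inheritParams first_peak_distance
#' @return Weighted mean first-shell distance in nm.
#' @export
first_shell_mean_distance <- function(rdf_result, smooth_window = 5) {
  g <- moving_average(rdf_result$g, smooth_window)
  peak_r <- first_peak_distance(rdf_result, smooth_window)
  i_peak <- which.min(abs(rdf_result$r - peak_r))
  i_start <- which(g > 1)[1]
  i_end <- i_peak
  while (i_end < length(g) - 1 && g[i_end + 1] < g[i_end]) i_end <- i_end + 1
  w <- rdf_result$counts[i_start:i_end]
  if (sum(w) == 0) return(peak_r)
  sum(rdf_result$r[i_start:i_end] * w) / sum(w)
}

#' End-to-end distance in a single conformation
#'
#' Straight-line (minimum-image) distance between two selected atoms of
#' one lipid in a single structure — e.g. headgroup to terminal carbon of
#' a straightened lipid, whose double is comparable to the bilayer
#' thickness.
#'
#' @param topology A [bl_topology].
#' @param frame A single frame (list with `xyz`, `box`).
#' @param lipid_id Which lipid to measure.
#' @param a,b Selectors (label strings or `list(role=, carbon=)`).
#' @return Distance in nm.
#' @export
end_to_end_length <- function(topology, frame, lipid_id, a, b) {
  atoms <- topology$atoms
  lr <- which(atoms$lipid_id == lipid_id)
  if (length(lr) == 0) rlang::abort(paste0("no lipid with id ", lipid_id))
  ia <- resolve_selector(atoms, lr, a, lipid_id)
  ib <- resolve_selector(atoms, lr, b, lipid_id)
  min_image_distance(frame$xyz[ia, ], frame$xyz[ib, ], frame$box)
}
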