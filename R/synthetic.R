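# Synthetic two-leaflet bilayer trajectories with analytically known
# ground truth for every observable the package measures. Lipids are
# rigid bodies on a jittered lattice: headgroup layers at +/- d/2, two
# bead tails descending toward the midplane with a prescribed per-carbon
# tilt schedule, lateral Brownian motion at a prescribed diffusion
# coefficient, and a z-layered dipole charge distribution. Because no
# force field acts, every observable is exactly determined by the
# construction parameters.

#' Specify a synthetic bilayer
#'
#' Defaults emulate a 150-lipid bilayer (75 per leaflet) in a
#' 6.1 x 6.1 x 24.1 nm box with a 6.3 nm headgroup-peak separation,
#' 12-carbon tails with tilt increasing from 10 to 50 degrees along the
#' chain (so the order parameter decays toward the tail ends), lateral
#' diffusion of 0.1e-7 cm^2/s, and a headgroup dipole (charge -q at the
#' head bead, +q/2 on each first chain carbon 0.2 nm further in) sized to
#' give a transmembrane potential difference of about 0.5 V.
#'
#' @param n_per_leaflet Lipids per leaflet (default 75).
#' @param box Box lengths `c(lx, ly, lz)` nm (default 6.1, 6.1, 24.1).
#' @param head_sep Headgroup layer separation d, nm (default 6.3); the
#'   ground-truth bilayer thickness.
#' @param n_carbons Carbons per tail m >= 3 (default 12).
#' @param bond_length Chain bead spacing, nm (default 0.153).
#' @param tilt_deg Tilt schedule: scalar (fixed tilt) or length-m vector
#'   theta(k), degrees (default `seq(10, 50, length.out = n_carbons)`).
#' @param lateral_D Lateral diffusion coefficient, cm^2/s (default
#'   0.1e-7).
#' @param jitter_sigma Positional jitter sigma, nm: lattice xy jitter at
#'   construction and per-frame whole-lipid z excursions (default 0.1).
#' @param head_offset Vertical head-to-first-carbon offset, nm (default
#'   0.2); sets the dipole arm.
#' @param charge_q Head charge magnitude q, e (default 0.07).
#' @param tail_split_deg Azimuth offset between the two tails, degrees
#'   (default 25).
#' @param tail_xy_offset Lateral offset of each tail base from the head
#'   axis, nm (default 0.05).
#' @param unsat_carbon Carbon index labelled "unsaturated" (default 9).
#' @param lattice_spacing Optional explicit lattice spacing, nm; default
#'   derived from the box and lipid count.
#' @param n_water Zero-charge solvent filler atoms (default 0).
#' @param n_frames Number of frames (default 200).
#' @param dt Frame spacing, ps (default 50).
#' @param seed RNG seed (default 1).
#' @return A `bl_synth_spec` list.
#' @export
synthetic_spec <- function(n_per_leaflet = 75, box = c(6.1, 6.1, 24.1),
                           head_sep = 6.3, n_carbons = 12,
                           bond_length = 0.153, tilt_deg = NULL,
                           lateral_D = 0.1e-7, jitter_sigma = 0.1,
                           head_offset = 0.2, charge_q = 0.07,
                           tail_split_deg = 25, tail_xy_offset = 0.05,
                           unsat_carbon = 9, lattice_spacing = NULL,
                           n_water = 0, n_frames = 200, dt = 50, seed = 1) {
  if (is.null(tilt_deg)) tilt_deg <- seq(10, 50, length.out = n_carbons)
  if (length(tilt_deg) == 1) tilt_deg <- rep(tilt_deg, n_carbons)
  stopifnot(length(tilt_deg) == n_carbons)
  if (n_carbons < 3) rlang::abort("n_carbons must be >= 3")
  if (head_sep >= box[3] - 2) {
    rlang::abort("head separation must leave a water slab: d < lz - 2 nm")
  }
  unsat_carbon <- max(2, min(unsat_carbon, n_carbons - 1))
  structure(list(n_per_leaflet = n_per_leaflet, box = box,
                 head_sep = head_sep, n_carbons = n_carbons,
                 bond_length = bond_length, tilt_deg = tilt_deg,
                 lateral_D = lateral_D, jitter_sigma = jitter_sigma,
                 head_offset = head_offset, charge_q = charge_q,
                 tail_split_deg = tail_split_deg,
                 tail_xy_offset = tail_xy_offset,
                 unsat_carbon = unsat_carbon,
                 lattice_spacing = lattice_spacing, n_water = n_water,
                 n_frames = n_frames, dt = dt, seed = seed),
            class = "bl_synth_spec")
}

#' Read a synthetic spec from YAML
#' @param path YAML file whose keys are [synthetic_spec()] arguments.
#' @return A `bl_synth_spec`.
#' @export
read_synthetic_spec <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$box)) args$box <- as.numeric(args$box)
  do.call(synthetic_spec, args)
}

# one tail as an m x 3 matrix of positions relative to the head bead;
# the vector C(k-1) -> C(k+1) has tilt theta(k) by construction, which
# is what makes the order-parameter ground truth exact
build_tail <- function(spec, phi, zdir) {
  m <- spec$n_carbons
  th <- spec$tilt_deg * pi / 180
  b <- spec$bond_length
  u <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), zdir * cos(th))
  p <- matrix(0, m, 3)
  p[1, ] <- c(spec$tail_xy_offset * cos(phi), spec$tail_xy_offset * sin(phi),
              zdir * spec$head_offset)
  p[2, ] <- p[1, ] + b * u[2, ]
  if (m >= 3) {
    for (k in 2:(m - 1)) p[k + 1, ] <- p[k - 1, ] + 2 * b * u[k, ]
  }
  p
}

lipid_template <- function(spec, phi, zdir) {
  rbind(c(0, 0, 0),
        build_tail(spec, phi, zdir),
        build_tail(spec, phi + spec$tail_split_deg * pi / 180, zdir))
}

lattice_sites <- function(spec) {
  n <- spec$n_per_leaflet
  lx <- spec$box[1]; ly <- spec$box[2]
  if (is.null(spec$lattice_spacing)) {
    nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
  } else {
    nx <- floor(lx / spec$lattice_spacing)
    ny <- floor(ly / spec$lattice_spacing)
    if (nx * ny < n) {
      rlang::abort("lattice cannot host n_per_leaflet lipids in this box")
    }
  }
  sx <- lx / nx; sy <- ly / ny
  g <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))[seq_len(n), ]
  list(xy = cbind((g$i + 0.5) * sx, (g$j + 0.5) * sy),
       spacing = min(sx, sy))
}

#' Generate a synthetic bilayer trajectory with ground truth
#'
#' Builds the trajectory described by the spec and the exact value every
#' analysis should recover from it. Deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `trajectory` (a [bl_trajectory]) and
#'   `ground_truth` (list: `thickness` nm, `packing` nm^-2, `apl` nm^2,
#'   `s_cd` tibble, `d_cm2_s`, `delta_v` V, `neighbor_spacing` nm,
#'   `intra` tibble of constructed pair distances, `chain_extension` nm,
#'   `tracks_x`/`tracks_y` true unwrapped head tracks).
#' @export
generate_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bl_synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_leaflet
  m <- spec$n_carbons
  apl_atoms <- 1 + 2 * m
  n_lip <- 2 * n
  box <- spec$box

  sites <- lattice_sites(spec)
  phi <- stats::runif(n_lip, 0, 2 * pi)
  jit_xy <- matrix(stats::rnorm(2 * n_lip, 0, spec$jitter_sigma), ncol = 2)

  # base coordinates, bilayer-centered (midplane z = 0)
  base <- matrix(NA_real_, n_lip * apl_atoms, 3)
  head_xy <- matrix(NA_real_, n_lip, 2)
  for (l in seq_len(n_lip)) {
    upper <- l <= n
    site <- sites$xy[if (upper) l else l - n, ]
    zdir <- if (upper) -1 else 1
    tmpl <- lipid_template(spec, phi[l], zdir)
    origin <- c(site + jit_xy[l, ], if (upper) spec$head_sep / 2
                                    else -spec$head_sep / 2)
    rows <- (l - 1) * apl_atoms + seq_len(apl_atoms)
    base[rows, ] <- sweep(tmpl, 2, origin, "+")
    head_xy[l, ] <- origin[1:2]
  }

  topology <- synthetic_topology(spec)

  # lateral Brownian walks (per lipid, rigid body) and per-frame z bob
  d_nm2_ps <- spec$lateral_D * 100   # cm^2/s -> nm^2/ps
  step_sd <- sqrt(2 * d_nm2_ps * spec$dt)
  n_fr <- spec$n_frames
  steps_x <- matrix(stats::rnorm((n_fr - 1) * n_lip, 0, step_sd), n_fr - 1)
  steps_y <- matrix(stats::rnorm((n_fr - 1) * n_lip, 0, step_sd), n_fr - 1)
  walk_x <- rbind(0, apply(steps_x, 2, cumsum))
  walk_y <- rbind(0, apply(steps_y, 2, cumsum))
  if (n_fr == 1) walk_x <- walk_y <- matrix(0, 1, n_lip)
  bob <- matrix(stats::rnorm(n_fr * n_lip, 0, spec$jitter_sigma), n_fr)

  water <- NULL
  if (spec$n_water > 0) {
    water <- cbind(stats::runif(spec$n_water, 0, box[1]),
                   stats::runif(spec$n_water, 0, box[2]),
                   stats::runif(spec$n_water, 0, box[3]) - box[3] / 2)
  }

  lip_of_atom <- rep(seq_len(n_lip), each = apl_atoms)
  frames <- vector("list", n_fr)
  for (fi in seq_len(n_fr)) {
    xyz <- base
    xyz[, 1] <- xyz[, 1] + walk_x[fi, lip_of_atom]
    xyz[, 2] <- xyz[, 2] + walk_y[fi, lip_of_atom]
    xyz[, 3] <- xyz[, 3] + bob[fi, lip_of_atom]
    if (!is.null(water)) xyz <- rbind(xyz, water)
    # shift midplane to lz/2 and wrap into the primary box
    xyz[, 3] <- xyz[, 3] + box[3] / 2
    xyz[, 1] <- xyz[, 1] %% box[1]
    xyz[, 2] <- xyz[, 2] %% box[2]
    xyz[, 3] <- xyz[, 3] %% box[3]
    frames[[fi]] <- list(time = (fi - 1) * spec$dt, xyz = xyz, box = box)
  }
  traj <- bl_trajectory(topology, frames)

  ground_truth <- synthetic_ground_truth(spec, sites$spacing,
                                         head_xy, walk_x, walk_y)
  list(trajectory = traj, ground_truth = ground_truth)
}

synthetic_topology <- function(spec) {
  m <- spec$n_carbons
  q <- spec$charge_q
  one_lipid <- function(lid) {
    tail_names <- function(suffix) sprintf("C%02d%s", seq_len(m), suffix)
    nm <- c("HEAD", tail_names("A"), tail_names("B"))
    role <- c("head", rep("sn1", m), rep("sn2", m))
    carbon <- c(NA_integer_, seq_len(m), seq_len(m))
    charge <- c(-q, q / 2, rep(0, m - 1), q / 2, rep(0, m - 1))
    label <- nm
    label[1] <- "N1"
    label[carbon %in% spec$unsat_carbon & role != "head"] <- "unsaturated"
    label[carbon %in% m & role != "head"] <- "terminal"
    tibble::tibble(name = nm, lipid_id = lid, species = "SYNL",
                   role = role, carbon = carbon, charge = charge,
                   label = label, mass = 1)
  }
  atoms <- dplyr::bind_rows(lapply(seq_len(2 * spec$n_per_leaflet), one_lipid))
  if (spec$n_water > 0) {
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      name = "OW", lipid_id = NA_integer_, species = "SOL", role = "other",
      carbon = NA_integer_, charge = 0, label = "OW", mass = 1,
      .rows = spec$n_water))
  }
  atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  bl_topology(atoms)
}

synthetic_ground_truth <- function(spec, spacing, head_xy, walk_x, walk_y) {
  m <- spec$n_carbons
  th <- spec$tilt_deg * pi / 180
  interior <- 2:(m - 1)
  s_cd <- tibble::tibble(carbon_index = interior,
                         s_cd = 0.5 * (3 * cos(th[interior])^2 - 1))

  # template pair distances (invariant to the per-lipid azimuth)
  tmpl <- lipid_template(spec, 0, -1)
  idx_head <- 1
  idx_sn1 <- 1 + seq_len(m)
  idx_sn2 <- 1 + m + seq_len(m)
  dist3 <- function(i, j) sqrt(sum((tmpl[i, ] - tmpl[j, ])^2))
  intra <- tibble::tibble(
    pair = c("head_terminal_sn1", "terminal_terminal", "unsat_unsat"),
    value_nm = c(dist3(idx_head, idx_sn1[m]),
                 dist3(idx_sn1[m], idx_sn2[m]),
                 dist3(idx_sn1[spec$unsat_carbon], idx_sn2[spec$unsat_carbon])))

  packing <- spec$n_per_leaflet / (spec$box[1] * spec$box[2])
  # dipole-layer plateau: surface dipole density over epsilon_0
  delta_v <- packing * 1e18 * spec$charge_q * E_CHARGE *
    (spec$head_offset * 1e-9) / EPSILON0

  list(thickness = spec$head_sep,
       packing = packing,
       apl = 1 / packing,
       s_cd = s_cd,
       d_cm2_s = spec$lateral_D,
       delta_v = delta_v,
       neighbor_spacing = spacing,
       intra = intra,
       chain_extension = abs(tmpl[idx_sn1[m], 3]),
       tracks_x = sweep(walk_x, 2, head_xy[, 1], "+"),
       tracks_y = sweep(walk_y, 2, head_xy[, 2], "+"))
}

#' Non-lamellar control variant
#'
#' Generates the same lipids as [generate_bilayer()] but scatters each
#' lipid's z position uniformly through the box every frame — a
#' disordered, non-lamellar aggregate with no headgroup layering. Used to
#' verify that [bilayer_thickness()] refuses non-bilayer structures.
#'
#' @param spec A [synthetic_spec()].
#' @return A [bl_trajectory].
#' @export
nonlamellar_variant <- function(spec) {
  set.seed(spec$seed + 1)
  gen <- generate_bilayer(spec)
  traj <- gen$trajectory
  n_lip <- 2 * spec$n_per_leaflet
  apl_atoms <- 1 + 2 * spec$n_carbons
  lip_of_atom <- rep(seq_len(n_lip), each = apl_atoms)
  lz <- spec$box[3]
  for (fi in seq_along(traj$frames)) {
    z_new <- stats::runif(n_lip, 1, lz - 1)
    f <- traj$frames[[fi]]
    head_rows <- (seq_len(n_lip) - 1) * apl_atoms + 1
    shift <- z_new - f$xyz[head_rows, 3]
    nl <- length(lip_of_atom)
    f$xyz[seq_len(nl), 3] <-
      (f$xyz[seq_len(nl), 3] + shift[lip_of_atom]) %% lz
    traj$frames[[fi]] <- f
  }
  traj
}

#' Write a synthetic trajectory as a self-contained fixture
#'
#' Emits `structure.gro` (first frame), `trajectory.gro` (all frames) and
#' `species_map.yaml` (roles, charges, labels derived from the topology),
#' so the files round-trip through [read_structure()] and
#' [load_trajectory()] with no extra configuration.
#'
#' @param traj A [bl_trajectory].
#' @param dir Output directory (created if needed).
#' @return Named list of the three paths, invisibly.
#' @export
write_fixture <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  structure_path <- file.path(dir, "structure.gro")
  traj_path <- file.path(dir, "trajectory.gro")
  map_path <- file.path(dir, "species_map.yaml")

  write_gro(traj, structure_path, frames_only = 1)
  write_gro(traj, traj_path)

  atoms <- traj$topology$atoms
  residues <- list()
  solvent <- character(0)
  for (sp in unique(atoms$species)) {
    sub <- atoms[atoms$species == sp, ]
    if (all(is.na(sub$lipid_id))) {
      solvent <- c(solvent, sp)
      next
    }
    first_lip <- sub[sub$lipid_id == sub$lipid_id[1], ]
    entries <- list()
    for (i in seq_len(nrow(first_lip))) {
      e <- list(role = first_lip$role[i], charge = first_lip$charge[i],
                label = first_lip$label[i])
      if (!is.na(first_lip$carbon[i])) e$carbon <- first_lip$carbon[i]
      entries[[first_lip$name[i]]] <- e
    }
    residues[[sp]] <- entries
  }
  yaml::write_yaml(list(solvent = as.list(solvent), residues = residues),
                   map_path)
  invisible(list(structure = structure_path, trajectory = traj_path,
                 species_map = map_path))
}
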