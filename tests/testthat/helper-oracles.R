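# Brute-force oracles and tiny in-code fixtures shared across tests.

# minimum-image distance by explicit search over the 27 neighbor images
# (points are wrapped into the primary box first, the convention's domain)
oracle_min_image <- function(a, b, box) {
  a <- a %% box
  b <- b %% box
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    img <- b + c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((a - img)^2)))
  }
  best
}

# pair-distance histogram by the 27-image search (same binning as rdf)
oracle_pair_counts <- function(xyz_a, xyz_b, same_pair, box, r_max, dr,
                               lateral = FALSE) {
  n_bins <- ceiling(r_max / dr - 1e-9)
  counts <- numeric(n_bins)
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      if (same_pair[i, j]) next
      if (lateral) {
        a <- c(xyz_a[i, 1:2], 0); b <- c(xyz_b[j, 1:2], 0)
        r <- oracle_min_image(a, b, c(box[1], box[2], 1e9))
      } else {
        r <- oracle_min_image(xyz_a[i, ], xyz_b[j, ], box)
      }
      if (r < r_max) {
        k <- min(floor(r / dr) + 1, n_bins)
        counts[k] <- counts[k] + 1
      }
    }
  }
  counts
}

# MSD by an explicit double loop over origins and lags
oracle_msd <- function(x, y, origin_stride = 1) {
  n_fr <- nrow(x)
  out <- numeric(n_fr - 1)
  for (k in seq_len(n_fr - 1)) {
    vals <- c()
    for (t0 in seq(1, n_fr - k, by = origin_stride)) {
      vals <- c(vals, (x[t0 + k, ] - x[t0, ])^2 + (y[t0 + k, ] - y[t0, ])^2)
    }
    out[k] <- mean(vals)
  }
  out
}

# minimal topology: one head bead per lipid at given positions, optional
# extra "other" atoms; all charges zero
head_only_topology <- function(n_lipids, extra_other = 0) {
  atoms <- tibble::tibble(
    atom_id = seq_len(n_lipids + extra_other) - 1L,
    name = c(rep("HEAD", n_lipids), rep("X", extra_other)),
    lipid_id = c(seq_len(n_lipids), rep(NA_integer_, extra_other)),
    species = c(rep("LIP", n_lipids), rep("SOL", extra_other)),
    role = c(rep("head", n_lipids), rep("other", extra_other)),
    carbon = NA_integer_, charge = 0, label = "H", mass = 1)
  bl_topology(atoms)
}

one_frame_traj <- function(topology, xyz, box, time = 0) {
  bl_trajectory(topology, list(list(time = time, xyz = xyz, box = box)))
}

# n_lipids single-bead "lipids" with prescribed per-frame xy tracks and a
# fixed z; used for MSD tests with exactly known displacement histories
tracks_trajectory <- function(x, y, box, dt = 1, z = 1) {
  n_fr <- nrow(x); n_lip <- ncol(x)
  topo <- head_only_topology(n_lip)
  frames <- lapply(seq_len(n_fr), function(fi) {
    list(time = (fi - 1) * dt,
         xyz = cbind(x[fi, ] %% box[1], y[fi, ] %% box[2], rep(z, n_lip)),
         box = box)
  })
  bl_trajectory(topo, frames)
}
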