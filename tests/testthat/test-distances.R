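# Intramolecular distances, RDFs, first peaks, end-to-end lengths.

two_bead_lipids <- function(xyz, box, sep_labels = c("N1", "N2")) {
  n_lip <- nrow(xyz) / 2
  atoms <- tibble::tibble(
    atom_id = seq_len(2 * n_lip) - 1L,
    name = rep(sep_labels, n_lip),
    lipid_id = rep(seq_len(n_lip), each = 2),
    species = "LIP", role = "other", carbon = NA_integer_,
    charge = 0, label = rep(sep_labels, n_lip), mass = 1)
  one_frame_traj(bl_topology(atoms), xyz, box)
}

test_that("a rigid constructed pair is measured exactly", {
  traj <- two_bead_lipids(rbind(c(1, 1, 1), c(1, 1, 1.66)),
                          box = c(6, 6, 10))
  res <- intramolecular_distances(traj, list(n1_n2 = c("N1", "N2")))
  expect_equal(res$mean_nm, 0.66, tolerance = 1e-12)
})

test_that("pairs straddling the periodic boundary use the minimum image", {
  traj <- two_bead_lipids(rbind(c(0.05, 1, 1), c(5.95, 1, 1)),
                          box = c(6, 6, 10))
  res <- intramolecular_distances(traj, list(p = c("N1", "N2")))
  expect_equal(res$mean_nm, 0.1, tolerance = 1e-12)
})

test_that("jittered pairs average to the construction distance", {
  set.seed(15)
  n <- 400; d0 <- 0.9; sigma <- 0.05
  a <- cbind(stats::runif(n, 1, 5), stats::runif(n, 1, 5), 2)
  b <- a + cbind(d0 + stats::rnorm(n, 0, sigma), 0, 0)
  xyz <- matrix(NA_real_, 2 * n, 3)
  xyz[seq(1, 2 * n, by = 2), ] <- a
  xyz[seq(2, 2 * n, by = 2), ] <- b
  traj <- two_bead_lipids(xyz, box = c(30, 30, 10))
  res <- intramolecular_distances(traj, list(p = c("N1", "N2")))
  expect_lt(abs(res$mean_nm - d0), 3 * sigma / sqrt(n) + 1e-3)
})

test_that("ambiguous selectors fail with a named error", {
  gen <- generate_bilayer(synthetic_spec(n_per_leaflet = 2, n_carbons = 4,
                                         n_frames = 1, seed = 1))
  expect_error(
    intramolecular_distances(gen$trajectory,
                             list(bad = c("terminal", "N1"))),
    "terminal")
})

test_that("two isolated atoms give a single-bin RDF spike", {
  atoms <- tibble::tibble(
    atom_id = 0:1, name = "X", lipid_id = 1:2, species = "LIP",
    role = "other", carbon = NA_integer_, charge = 0, label = "X", mass = 1)
  traj <- one_frame_traj(bl_topology(atoms),
                         rbind(c(1, 1, 1), c(1.4, 1, 1)), box = c(4, 4, 4))
  r <- rdf(traj, name == "X", name == "X", r_max = 1.9, dr = 0.01)
  expect_equal(sum(r$counts > 0), 1)
  expect_lt(abs(r$r[which(r$counts > 0)] - 0.4), 0.005 + 1e-9)
})

test_that("an ideal gas has g(r) = 1 beyond the noise floor", {
  set.seed(44)
  n <- 1000
  atoms <- tibble::tibble(
    atom_id = seq_len(n) - 1L, name = "X", lipid_id = seq_len(n),
    species = "LIP", role = "other", carbon = NA_integer_, charge = 0,
    label = "X", mass = 1)
  xyz <- cbind(stats::runif(n, 0, 5), stats::runif(n, 0, 5),
               stats::runif(n, 0, 5))
  traj <- one_frame_traj(bl_topology(atoms), xyz, box = c(5, 5, 5))
  r <- rdf(traj, name == "X", name == "X", r_max = 2.4, dr = 0.05)
  far <- r$r > 0.5
  expect_true(all(abs(r$g[far] - 1) < 0.1))
})

test_that("RDF histograms match the 27-image brute-force oracle", {
  set.seed(3)
  n <- 18
  atoms <- tibble::tibble(
    atom_id = seq_len(n) - 1L, name = "X",
    lipid_id = rep(seq_len(n / 2), each = 2),   # two atoms per molecule
    species = "LIP", role = "other", carbon = NA_integer_, charge = 0,
    label = "X", mass = 1)
  xyz <- cbind(stats::runif(n, 0, 4), stats::runif(n, 0, 4),
               stats::runif(n, 0, 4))
  traj <- one_frame_traj(bl_topology(atoms), xyz, box = c(4, 4, 4))
  r <- rdf(traj, name == "X", name == "X", r_max = 1.9, dr = 0.05)
  same <- outer(atoms$lipid_id, atoms$lipid_id, "==")
  expect_equal(r$counts,
               oracle_pair_counts(xyz, xyz, same, c(4, 4, 4), 1.9, 0.05))
  expect_error(rdf(traj, name == "X", name == "X", r_max = 3), "half")

  # counting identity: sum of counts / n_a = mean partners within r_max
  expect_equal(sum(r$counts) / r$n_a,
               sum(oracle_pair_counts(xyz, xyz, same, c(4, 4, 4), 1.9, 0.05)) / n)
})

test_that("first-peak extraction honours the tie-break and guards", {
  gen <- generate_bilayer(synthetic_spec(
    n_per_leaflet = 25, box = c(2.05, 2.05, 24.1), lattice_spacing = 0.41,
    n_frames = 10, seed = 3, lateral_D = 0, jitter_sigma = 0))
  traj <- assign_leaflets(gen$trajectory)
  r <- rdf(traj, role == "head", role == "head", r_max = 1, dr = 0.002,
           mode = "lateral")
  # frozen lattice: peak lands in the bin containing the 0.41 nm spacing
  expect_lt(abs(first_peak_distance(r, smooth_window = 1) - 0.41),
            0.002 + 1e-9)

  # jittered construction still recovers the spacing
  genj <- generate_bilayer(synthetic_spec(
    n_per_leaflet = 25, box = c(2.05, 2.05, 24.1), lattice_spacing = 0.41,
    n_frames = 10, seed = 3, lateral_D = 0, jitter_sigma = 0.008))
  rj <- rdf(assign_leaflets(genj$trajectory), role == "head", role == "head",
            r_max = 1, dr = 0.002, mode = "lateral")
  expect_lt(abs(first_peak_distance(rj, smooth_window = 9) - 0.41), 0.01)

  # monotone decreasing g has no first shell
  fake <- structure(list(r = seq(0.05, 1, by = 0.05),
                         g = 2 * exp(-seq(0.05, 1, by = 0.05)),
                         counts = rep(1, 20), mode = "3d"),
                    class = "bl_rdf")
  fake$g <- cummin(fake$g)
  expect_error(first_peak_distance(fake, smooth_window = 1), "structureless")
})

test_that("end-to-end length measures straight constructions exactly", {
  # linear 10-bead chain at 0.15 nm spacing: 1.35 nm end to end
  m <- 10
  atoms <- tibble::tibble(
    atom_id = seq_len(m) - 1L, name = sprintf("C%02d", 1:m),
    lipid_id = 1L, species = "LIP", role = "sn1", carbon = 1:m,
    charge = 0, label = sprintf("C%02d", 1:m), mass = 1)
  topo <- bl_topology(atoms)
  frame <- list(time = 0, xyz = cbind(1, 1, 1 + 0.15 * (0:(m - 1))),
                box = c(6, 6, 10))
  expect_equal(end_to_end_length(topo, frame, 1, list(role = "sn1", carbon = 1),
                                 list(role = "sn1", carbon = m)), 1.35)
  expect_equal(end_to_end_length(topo, frame, 1, "C03", "C03"), 0)

  # straight synthetic lipid: half the reference bilayer span, doubled
  b <- (3.67 - 0.2) / 23
  spec <- synthetic_spec(n_per_leaflet = 4, n_carbons = 24, bond_length = b,
                         tilt_deg = 0, tail_xy_offset = 0, head_sep = 7.34,
                         jitter_sigma = 0, n_frames = 1, seed = 5)
  gen <- generate_bilayer(spec)
  len <- end_to_end_length(gen$trajectory$topology,
                           gen$trajectory$frames[[1]], 1,
                           "N1", list(role = "sn1", carbon = 24))
  expect_equal(len, 3.67, tolerance = 1e-9)
  expect_equal(2 * len, 7.34, tolerance = 1e-9)
  expect_equal(gen$ground_truth$thickness, 2 * len, tolerance = 1e-9)
})

test_that("inter- vs intramolecular ordering is reproduced by construction", {
  spec <- synthetic_spec(n_frames = 10, seed = 10, lateral_D = 0,
                         jitter_sigma = 0.05)
  gen <- generate_bilayer(spec)
  traj <- assign_leaflets(gen$trajectory)
  r <- rdf(traj, role == "head", role == "head", r_max = 1.5, dr = 0.01,
           mode = "lateral")
  inter <- first_peak_distance(r)
  intra <- intramolecular_distances(
    traj, list(ht = list("N1", list(role = "sn1", carbon = 12))))
  expect_lt(inter, intra$mean_nm)
  expect_equal(intra$mean_nm,
               gen$ground_truth$intra$value_nm[
                 gen$ground_truth$intra$pair == "head_terminal_sn1"],
               tolerance = 0.02)
})
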