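# Trajectory model: structure I/O, windows, leaflets, periodic geometry.

test_that("GRO structure reading recovers box, coordinates and roles", {
  gro <- c("two atoms",
           "    2",
           sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "LIP", "HEAD", 1,
                   1, 2, 3),
           sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "LIP", "C01A", 2,
                   1.1, 2.1, 3.1),
           "   6.10000   6.10000  24.10000")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  map <- list(residues = list(LIP = list(
    HEAD = list(role = "head", charge = -0.1),
    C01A = list(role = "sn1", carbon = 1, charge = 0.1))))
  st <- read_structure(path, read_species_map(map))
  expect_equal(st$frame$box, c(6.1, 6.1, 24.1))
  expect_equal(st$frame$xyz[1, ], c(1, 2, 3))
  expect_equal(st$topology$atoms$role, c("head", "sn1"))
  expect_equal(st$topology$atoms$charge, c(-0.1, 0.1))
})

test_that("unknown residue or atom names are explicit errors", {
  line <- function(res, at) sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                    1, res, at, 1, 1, 2, 3)
  gro <- c("x", "    1", line("XXX", "HEAD"),
           "   6.10000   6.10000  24.10000")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  map <- read_species_map(list(residues = list(LIP = list(
    HEAD = list(role = "head", charge = 0)))))
  expect_error(read_structure(path, map), "XXX")
  gro[3] <- line("LIP", "HUH")
  writeLines(gro, path)
  expect_error(read_structure(path, map), "HUH")
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  skip_if_not_installed("bio3d")
  pdb <- c(
    "CRYST1   61.000   61.000  241.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1 HEAD LIP A   1      10.000   0.000   5.000  1.00  0.00",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  map <- read_species_map(list(residues = list(LIP = list(
    HEAD = list(role = "head", charge = 0)))))
  st <- read_structure(path, map)
  expect_equal(st$frame$xyz[1, ], c(1, 0, 0.5))
  expect_equal(st$frame$box, c(6.1, 6.1, 24.1))
})

test_that("trajectory loading enforces time order and applies windows", {
  topo <- head_only_topology(2)
  mk_frame <- function(t) list(time = t, xyz = cbind(c(1, 2), 1, c(3, -3)),
                               box = c(6, 6, 10))
  traj <- bl_trajectory(topo, lapply(c(0, 50, 100), mk_frame))
  expect_equal(frame_times(traj), c(0, 50, 100))

  traj <- set_window(traj, 50, 100)
  expect_length(analysis_frames(traj), 2)

  expect_error(bl_trajectory(topo, lapply(c(0, 50, 50), mk_frame)),
               "strictly increasing")
  bad <- mk_frame(0); bad$xyz <- bad$xyz[1, , drop = FALSE]
  expect_error(bl_trajectory(topo, list(bad)), "atom count")
})

test_that("leaflet assignment splits heads around the midplane", {
  topo <- head_only_topology(2)
  traj <- one_frame_traj(topo, cbind(c(1, 1), c(1, 1), c(3, -3)),
                         box = c(6, 6, 10))
  traj <- assign_leaflets(traj)
  expect_equal(traj$topology$lipids$leaflet, c("upper", "lower"))
})

test_that("leaflet assignment is invariant to a global z-translation", {
  gen <- generate_bilayer(synthetic_spec(n_per_leaflet = 10, n_carbons = 3,
                                         n_frames = 2, seed = 4))
  t1 <- assign_leaflets(gen$trajectory)
  t2 <- gen$trajectory
  for (i in seq_along(t2$frames)) {
    t2$frames[[i]]$xyz[, 3] <- t2$frames[[i]]$xyz[, 3] + 1.37
  }
  t2 <- assign_leaflets(t2)
  expect_identical(t1$topology$lipids$leaflet, t2$topology$lipids$leaflet)
})

test_that("degenerate one-sided structures are flagged", {
  gen <- generate_bilayer(synthetic_spec(n_per_leaflet = 4, n_carbons = 3,
                                         n_frames = 1, jitter_sigma = 0,
                                         seed = 2))
  traj <- gen$trajectory
  atoms <- traj$topology$atoms
  upper_rows <- atoms$lipid_id %in% 1:4   # keep only the upper leaflet
  traj$topology$atoms <- atoms[upper_rows, ]
  traj$topology$atoms$atom_id <- seq_len(nrow(traj$topology$atoms)) - 1L
  traj$topology$lipids <- traj$topology$lipids[1:4, ]
  traj$frames[[1]]$xyz <- traj$frames[[1]]$xyz[upper_rows, ]
  expect_warning(assign_leaflets(traj), "may not be a bilayer")
})

test_that("minimum-image distance wraps and matches the 27-image oracle", {
  box <- c(6.1, 6.1, 24.1)
  expect_equal(min_image_distance(c(0, 0, 0), c(6.0, 0, 0), box), 0.1)
  expect_equal(min_image_distance(c(1, 2, 3), c(1, 2, 3), box), 0)

  set.seed(42)
  for (i in 1:1000) {
    a <- stats::runif(3, -5, 30)
    b <- stats::runif(3, -5, 30)
    expect_equal(min_image_distance(a, b, box), oracle_min_image(a, b, box),
                 tolerance = 1e-12)
  }
  # symmetry and the half-diagonal bound
  set.seed(7)
  a <- matrix(stats::runif(300, 0, 25), ncol = 3)
  b <- matrix(stats::runif(300, 0, 25), ncol = 3)
  d_ab <- min_image_distance(a, b, box)
  d_ba <- min_image_distance(b, a, box)
  expect_equal(d_ab, d_ba)
  expect_true(all(d_ab <= sqrt(sum(box^2)) / 2 + 1e-12))
})

test_that("GRO write/read round-trips coordinates within format precision", {
  gen <- generate_bilayer(synthetic_spec(n_per_leaflet = 6, n_carbons = 4,
                                         n_frames = 3, seed = 9))
  dir <- withr::local_tempdir()
  fx <- write_fixture(gen$trajectory, dir)
  st <- read_structure(fx$structure, fx$species_map)
  traj <- load_trajectory(st$topology, fx$trajectory)
  expect_length(traj$frames, 3)
  for (i in 1:3) {
    expect_lt(max(abs(traj$frames[[i]]$xyz - gen$trajectory$frames[[i]]$xyz)),
              1e-3 + 1e-9)
  }
  expect_identical(st$topology$atoms$role, gen$trajectory$topology$atoms$role)
  expect_equal(st$topology$atoms$charge, gen$trajectory$topology$atoms$charge)
})
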