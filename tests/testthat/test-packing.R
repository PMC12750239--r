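# Packing density, track unwrapping, MSD, diffusion, block errors.

test_that("block error reproduces hand-computed and limiting cases", {
  expect_equal(block_error(rep(3.2, 10), 2), list(mean = 3.2, stderr = 0))
  be <- block_error(c(1, 1, 2, 2), 2)
  expect_equal(be$mean, 1.5)
  expect_equal(be$stderr, 0.5 / sqrt(2), tolerance = 1e-12)
  expect_error(block_error(1:3, 5), "fewer")
  expect_error(block_error(1:10, 1), ">= 2")
})

test_that("block stderr of i.i.d. noise approximates sigma over sqrt(n)", {
  set.seed(20)
  x <- stats::rnorm(1e4, sd = 2)
  be <- block_error(x, 5)
  expect_lt(abs(be$stderr - 2 / sqrt(1e4)) / (2 / sqrt(1e4)), 0.3)
})

test_that("packing density is lipids per leaflet over lateral area", {
  gen <- generate_bilayer(synthetic_spec(n_frames = 3, seed = 2))
  traj <- assign_leaflets(gen$trajectory)
  pk <- packing_density(traj)
  expect_identical(pk$packing_density, 75 / (6.1 * 6.1))
  expect_lt(abs(pk$packing_density * pk$apl - 1), 1e-12)

  # doubling both lateral edges quarters the density
  big <- traj
  for (i in seq_along(big$frames)) {
    big$frames[[i]]$box[1:2] <- big$frames[[i]]$box[1:2] * 2
  }
  expect_equal(packing_density(big, n_leaflet = 75)$packing_density,
               pk$packing_density / 4)
  # z-box changes do not touch it
  tall <- traj
  for (i in seq_along(tall$frames)) tall$frames[[i]]$box[3] <- 40
  expect_equal(packing_density(tall, n_leaflet = 75)$packing_density,
               pk$packing_density)
  expect_error(packing_density(traj, n_leaflet = 0), "positive")
})

test_that("unwrapping corrects boundary crossings and preserves tracks", {
  # particle crossing the +x boundary: 5.9 -> 0.1 with lx = 6
  x <- matrix(c(5.9, 0.1), ncol = 1)
  y <- matrix(c(1, 1), ncol = 1)
  traj <- tracks_trajectory(x, y, box = c(6, 6, 10))
  tr <- unwrap_lateral(traj)
  expect_equal(tr$x[2, 1] - tr$x[1, 1], 0.2, tolerance = 1e-12)

  # stationary particle: constant track
  traj2 <- tracks_trajectory(matrix(2, 5, 1), matrix(3, 5, 1),
                             box = c(6, 6, 10))
  tr2 <- unwrap_lateral(traj2)
  expect_true(all(tr2$x == tr2$x[1, 1]) && all(tr2$y == tr2$y[1, 1]))

  # confined random walk: unwrapped track equals the true cumulative steps
  set.seed(4)
  steps <- matrix(stats::rnorm(200, sd = 0.4), 100, 2)
  truth_x <- cbind(cumsum(c(1, steps[-100, 1])))
  truth_y <- cbind(cumsum(c(1, steps[-100, 2])))
  traj3 <- tracks_trajectory(truth_x, truth_y, box = c(6, 6, 10))
  tr3 <- unwrap_lateral(traj3)
  expect_equal(as.numeric(tr3$x - tr3$x[1, 1]),
               as.numeric(truth_x - truth_x[1]), tolerance = 1e-9)
  expect_equal(as.numeric(tr3$y - tr3$y[1, 1]),
               as.numeric(truth_y - truth_y[1]), tolerance = 1e-9)

  # too-coarse sampling is refused
  jump <- tracks_trajectory(matrix(c(0, 3), 2, 1), matrix(1, 2, 1),
                            box = c(6, 6, 10))
  expect_error(unwrap_lateral(jump), "too coarse")
})

test_that("ground-truth generator tracks survive wrapping and unwrapping", {
  gen <- generate_bilayer(synthetic_spec(n_per_leaflet = 10, n_carbons = 3,
                                         lateral_D = 1e-7, n_frames = 50,
                                         seed = 6))
  traj <- assign_leaflets(gen$trajectory)
  tr <- unwrap_lateral(traj, selection = role == "head")
  gt_x <- gen$ground_truth$tracks_x
  # tracks agree up to a constant offset (head vs reference geometry)
  dev_x <- sweep(tr$x - gt_x, 2, tr$x[1, ] - gt_x[1, ])
  expect_lt(max(abs(dev_x)), 1e-9)
})

test_that("MSD limiting cases: static, ballistic, and Brownian slope", {
  static <- tracks_trajectory(matrix(2, 10, 3), matrix(2, 10, 3),
                              box = c(8, 8, 8))
  msd0 <- lateral_msd(unwrap_lateral(static))
  expect_true(all(msd0$msd_nm2 == 0))
  dc0 <- diffusion_coefficient(msd0)
  expect_equal(dc0$d_cm2_s, 0)

  # uniform drift v with drift removal off: msd(tau) = (v tau)^2
  v <- 0.03
  n_fr <- 21
  x <- matrix(rep(v * (0:(n_fr - 1)), 2), ncol = 2)
  drift <- tracks_trajectory(x, 0 * x + 1, box = c(8, 8, 8))
  msd_d <- lateral_msd(unwrap_lateral(drift), remove_drift = FALSE)
  expect_equal(msd_d$msd_nm2, (v * msd_d$lag_ps)^2, tolerance = 1e-10)

  # an exact Einstein line returns D exactly
  d_nm2_ps <- 0.1e-7 * 100
  msd_line <- structure(list(lag_ps = 0:100,
                             msd_nm2 = 4 * d_nm2_ps * (0:100),
                             n_origins = rep(1L, 101)), class = "bl_msd")
  dc <- diffusion_coefficient(msd_line)
  expect_equal(dc$d_cm2_s, 0.1e-7, tolerance = 1e-12)

  # a decreasing MSD warns about the negative slope
  msd_neg <- structure(list(lag_ps = 0:100, msd_nm2 = -0.01 * (0:100),
                            n_origins = rep(1L, 101)), class = "bl_msd")
  expect_warning(dneg <- diffusion_coefficient(msd_neg), "negative")
  expect_lt(dneg$d_cm2_s, 0)
})

test_that("the MSD estimator matches a brute-force double loop", {
  set.seed(9)
  n_fr <- 10; n_lip <- 4
  x <- apply(matrix(stats::rnorm(n_fr * n_lip, sd = 0.2), n_fr), 2, cumsum)
  y <- apply(matrix(stats::rnorm(n_fr * n_lip, sd = 0.2), n_fr), 2, cumsum)
  traj <- tracks_trajectory(x, y, box = c(50, 50, 10))
  tr <- unwrap_lateral(traj)
  for (stride in c(1, 2)) {
    msd <- lateral_msd(tr, max_lag = n_fr - 1, origin_stride = stride,
                       remove_drift = FALSE)
    expect_equal(msd$msd_nm2[-1], oracle_msd(tr$x, tr$y, stride),
                 tolerance = 1e-12)
  }
})

test_that("Brownian motion parameter recovery brackets the study range", {
  spec <- synthetic_spec(n_per_leaflet = 50, n_carbons = 3, n_frames = 600,
                         jitter_sigma = 0.02, lateral_D = 0.1e-7, seed = 27)
  gen <- generate_bilayer(spec)
  traj <- assign_leaflets(gen$trajectory)
  dc <- diffusion_coefficient(lateral_msd(unwrap_lateral(traj)))
  expect_lt(abs(dc$d_cm2_s - 0.1e-7) / 0.1e-7, 0.1)
})
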