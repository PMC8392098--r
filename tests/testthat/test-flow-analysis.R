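# Velocity binning, orientation statistics, KS, shear, viscosity, lift.

test_that("the published grid tiles the full domain into 5 x 5 x 40 bins", {
  tb <- synthetic_traj(function(p) cbind(0.1, 0, 0 * p[, 1]), n = 2000)
  g <- bin_velocities(tb, grid = c(16, 9, 1), box = c(80, 45, 40))
  expect_equal(nrow(g), 16 * 9)
  expect_equal(diff(sort(unique(g$x_mid)))[1], 5)
  expect_equal(diff(sort(unique(g$y_mid)))[1], 5)
  expect_equal(unique(g$z_mid), 20)
})

test_that("uniform flow bins to the same vector everywhere with theta = 0", {
  tb <- synthetic_traj(function(p) cbind(rep(0.3, nrow(p)), 0, 0))
  g <- bin_velocities(tb, grid = c(8, 5, 1), box = c(80, 45, 40))
  occ <- g[g$occupied, ]
  expect_equal(occ$vx, rep(0.3, nrow(occ)))
  expect_equal(occ$vy, rep(0, nrow(occ)))
  expect_equal(occ$theta, rep(0, nrow(occ)))
  os <- orientation_stats(g)
  expect_equal(os$circ_sd, 0)
  expect_equal(os$mean_theta, 0)
})

test_that("binning is a faithful momentum bookkeeper and recovers a Couette profile", {
  gam <- 0.02
  tb <- synthetic_traj(function(p) cbind(gam * p[, 2], 0, 0), n = 6000)
  g <- bin_velocities(tb, grid = c(1, 9, 1), box = c(80, 45, 40))
  # sum(bin mean * count) equals the particle-velocity sum
  expect_equal(sum(g$vx * g$n, na.rm = TRUE), sum(tb$vx), tolerance = 1e-9)
  # binned profile linear with slope gamma-dot
  fit <- stats::lm(vx ~ y_mid, data = g[g$occupied, ])
  expect_equal(unname(coef(fit)[2]), gam, tolerance = 0.02)

  pr <- shear_profile(tb, ny = 9, box = c(80, 45, 40), gamma = 2)
  inner <- pr[2:8, ]
  expect_equal(inner$shear_rate, rep(gam, 7), tolerance = 0.05)
  expect_equal(pr$stress, 2 * pr$shear_rate)
  # uniform flow has zero shear
  tbu <- synthetic_traj(function(p) cbind(rep(0.3, nrow(p)), 0, 0))
  pru <- shear_profile(tbu, ny = 9, box = c(80, 45, 40))
  expect_equal(max(abs(pru$shear_rate), na.rm = TRUE), 0, tolerance = 1e-12)
  expect_error(shear_profile(tb, ny = 2, box = c(80, 45, 40)), "3 y bins")
})

test_that("orientation dispersion is rotation-invariant and degenerates correctly", {
  set.seed(52)
  th <- runif(200, -pi, pi)
  v <- orientation_stats(th)
  rot <- orientation_stats(((th + 1.3 + pi) %% (2 * pi)) - pi)
  expect_equal(v$circ_sd, rot$circ_sd, tolerance = 1e-9)
  expect_lt(orientation_stats(runif(20000, -pi, pi))$resultant_length, 0.03)
  expect_error(orientation_stats(numeric()), "no occupied")
})

test_that("KS comparison equals the brute-force ECDF supremum and handles edge cases", {
  expect_equal(compare_orientations(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(compare_orientations(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(compare_orientations(c(1, 2), c(5, 6))$statistic, 1)
  set.seed(53)
  for (i in 1:50) {
    a <- rnorm(sample(10:200, 1))
    b <- rnorm(sample(10:200, 1), mean = sample(c(0, 1), 1))
    expect_equal(compare_orientations(a, b)$statistic, ks_brute(a, b),
                 tolerance = 1e-12)
  }
  expect_error(compare_orientations(1, c(1, 2)), "at least 2")
})

test_that("viscosity calibration is positive, Newtonian and reproducible", {
  v1 <- cached("visc1", calibrate_viscosity(seed = 61))
  expect_gt(v1$gamma, 0)
  # same drive, new seed: within mutual 10%
  v2 <- cached("visc2", calibrate_viscosity(seed = 62))
  expect_equal(v1$gamma, v2$gamma, tolerance = 0.1)
  # doubled body force: Newtonian within 10%
  v3 <- cached("visc3", calibrate_viscosity(seed = 61, g = 0.04))
  expect_equal(v3$gamma, v1$gamma, tolerance = 0.1)
})

test_that("lifting force recovers a constant synthetic stream exactly and errors without records", {
  fs <- list(time = 1:10, bead = 1:3,
             water = matrix(rep(c(0, 0.2, 0), each = 10), 10, 9)[, rep(1:3, 3)],
             total = matrix(0.5, 10, 9))
  # columns are (fx, fy, fz) per bead: set fy columns to 0.2
  fs$water <- matrix(0, 10, 9)
  fs$water[, c(2, 5, 8)] <- 0.2
  lf <- lifting_force(fs)
  expect_equal(lf$mean_fy, 0.2)
  expect_equal(lf$per_bead$mean_fy, rep(0.2, 3))
  lf2 <- lifting_force(fs, window = c(5, 10))
  expect_equal(lf2$n_samples, 6)
  run_norec <- list(force_stream = NULL)
  class(run_norec) <- "dpd_run"
  expect_error(lifting_force(run_norec), "no force stream")
})

test_that("quiescent solvent exerts no net vertical force on a mid-domain chain", {
  # a chain lying horizontally at mid-height is up-down symmetric, so the
  # time-averaged solvent force on its beads has no vertical component.
  # (a vertical brush chain would NOT satisfy this: its bonded neighbours
  # shadow the solvent asymmetrically along y.)
  set.seed(63)
  L <- c(10, 6, 4)
  n <- round(3 * prod(L))
  ch <- cbind(2 + 0.5 * (0:7), 3, 2)
  water <- matrix(runif(3 * (n - 8)), ncol = 3) %*% diag(L)
  sys <- dpd_system(rbind(ch, water), box = dpd_box(L),
                    species = c(rep("eg_bead", 8), rep("water", n - 8)),
                    role = c(rep("tethered", 8), rep("free", n - 8)),
                    topology = list(bonds = cbind(1:7, 2:8)), seed = 63)
  sys <- thermalise(sys)
  sys <- suppressWarnings(equilibrate(sys, time = 4))
  out <- dpd_advance(sys, 12, record_every = 0.1, record_ids = 1:8)
  fy <- colMeans(out$rec_water)[seq(2, 24, 3)]
  # noise band: per-bead solvent-force fluctuations ~ O(10) per step
  # decorrelate in ~0.1 tau; 12 tau of per-step averaging over 8 beads
  # leaves an SE well under 0.3
  expect_lt(abs(mean(fy)), 1)
  # and no systematic tilt along the chain either
  expect_lt(abs(mean(colMeans(out$rec_water)[seq(1, 24, 3)])), 1)
})
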