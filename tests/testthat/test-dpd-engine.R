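# Pair forces, bonded terms, walls, integration, thermostat.

test_that("conservative pair force matches hand evaluation and vanishes at the cutoff", {
  f <- dpd_forces(pair_system(0.5))
  # a_ww w(0.5) = 25 * 0.5, repulsive along the pair axis
  expect_equal(f$pair[1, 1], -12.5, tolerance = 1e-12)
  expect_equal(f$pair[2, 1], 12.5, tolerance = 1e-12)
  expect_equal(f$pair[1, 2:3], c(0, 0))
  # Newton's third law
  expect_equal(colSums(f$pair), c(0, 0, 0), tolerance = 1e-12)

  # beyond the cutoff all three terms are zero
  far <- pair_system(1.2)
  expect_equal(max(abs(dpd_forces(far, noise = TRUE)$force)), 0)

  # continuity: force -> 0 as r -> r_c
  near <- dpd_forces(pair_system(0.999))$pair[1, 1]
  expect_lt(abs(near), 25 * 0.0011)
})

test_that("dissipative force opposes approach with magnitude beta w^2 (e.v)", {
  f <- dpd_forces(pair_system(0.5, v_rel = 1))
  # conservative -12.5 plus dissipative -4.5 * 0.25 * 1 on bead 1
  expect_equal(f$pair[1, 1], -12.5 - 1.125, tolerance = 1e-12)
  # receding pair: dissipative flips sign
  f2 <- dpd_forces(pair_system(0.5, v_rel = -1))
  expect_equal(f2$pair[1, 1], -12.5 + 1.125, tolerance = 1e-12)
})

test_that("random force has the fluctuation-dissipation amplitude and pair symmetry", {
  z <- glycodpd:::sample_pair_noise_cpp(42L, 100000L, 0L, 1L)
  expect_lt(abs(mean(z)), 0.02)
  expect_equal(var(z), 1, tolerance = 0.02)
  # same draw regardless of index order
  expect_identical(glycodpd:::sample_pair_noise_cpp(7L, 10L, 3L, 9L),
                   glycodpd:::sample_pair_noise_cpp(7L, 10L, 9L, 3L))

  # component variance at r = 0.5: (2 beta kBT / dt) w^2 = 9000 * 0.25
  sys <- pair_system(0.5)
  fr <- vapply(1:10000, function(s) dpd_forces(sys, noise = TRUE, step = s)$pair[1, 1],
               numeric(1))
  expect_equal(var(fr), 2250, tolerance = 0.05)
  expect_equal(mean(fr), -12.5, tolerance = abs(12.5) * 0.1)
})

test_that("bond force and energy follow the printed harmonic form (no 1/2 prefactor)", {
  p0 <- dpd_params(a_ww = 0)
  sys <- pair_system(0.6, params = p0, bond = TRUE)
  f <- dpd_forces(sys)
  expect_equal(f$e_bond, 1, tolerance = 1e-12)            # 100 * 0.1^2
  expect_equal(f$bond[1, 1], 20, tolerance = 1e-12)       # 2 * 100 * 0.1, restoring
  # equilibrium: zero force, zero energy
  fe <- dpd_forces(pair_system(0.5, params = p0, bond = TRUE))
  expect_equal(fe$e_bond, 0)
  expect_equal(max(abs(fe$bond)), 0)
})

test_that("bending energy is half k_E (phi - pi)^2 with zero force/torque when straight", {
  box <- dpd_box(c(10, 10, 10), periodic = rep(TRUE, 3))
  p0 <- dpd_params(a_ww = 0, a_gw = 0, a_gg = 0)
  bent <- rbind(c(5, 5, 5), c(5.5, 5, 5),
                c(5.5 + 0.5 * cos(0.1), 5 + 0.5 * sin(0.1), 5))
  sys <- dpd_system(bent, box = box, walls = FALSE, params = p0,
                    topology = list(angles = rbind(c(1, 2, 3))))
  f <- dpd_forces(sys)
  expect_equal(f$e_bend, 0.5 * 462 * 0.01, tolerance = 1e-9)  # 2.31 kBT
  expect_equal(colSums(f$angle), c(0, 0, 0), tolerance = 1e-9)
  # zero net torque about the centre bead
  tq <- c(0, 0, 0)
  for (i in c(1, 3)) {
    r <- bent[i, ] - bent[2, ]
    tq <- tq + c(r[2] * f$angle[i, 3] - r[3] * f$angle[i, 2],
                 r[3] * f$angle[i, 1] - r[1] * f$angle[i, 3],
                 r[1] * f$angle[i, 2] - r[2] * f$angle[i, 1])
  }
  expect_equal(tq, c(0, 0, 0), tolerance = 1e-9)

  straight <- dpd_system(rbind(c(5, 5, 5), c(5.5, 5, 5), c(6, 5, 5)),
                         box = box, walls = FALSE, params = p0,
                         topology = list(angles = rbind(c(1, 2, 3))))
  fs <- dpd_forces(straight)
  expect_equal(fs$e_bend, 0)
  expect_equal(max(abs(fs$angle)), 0)
})

test_that("bonded forces equal the numerical gradient of the printed energies", {
  box <- dpd_box(c(20, 20, 20), periodic = rep(TRUE, 3))
  p0 <- dpd_params(a_ww = 0, a_gw = 0, a_gg = 0)
  pos <- rbind(c(10, 10, 10), c(10.45, 10.1, 10.05), c(10.8, 10.5, 10.2))
  sys <- dpd_system(pos, box = box, walls = FALSE, params = p0,
                    topology = list(bonds = rbind(c(1, 2), c(2, 3)),
                                    angles = rbind(c(1, 2, 3))))
  f <- dpd_forces(sys)
  h <- 1e-6
  for (i in 1:3) for (k in 1:3) {
    a <- sys; a$pos[i, k] <- a$pos[i, k] + h
    b <- sys; b$pos[i, k] <- b$pos[i, k] - h
    ea <- dpd_forces(a); eb <- dpd_forces(b)
    g <- -((ea$e_bond + ea$e_bend) - (eb$e_bond + eb$e_bend)) / (2 * h)
    expect_equal(f$bond[i, k] + f$angle[i, k], g, tolerance = 1e-5)
  }
})

test_that("wall force is perpendicular, repulsive, ranged and continuous", {
  box <- dpd_box(c(10, 6, 10))
  sys <- dpd_system(rbind(c(5, 3, 5),     # mid-domain
                          c(5, 0, 5),     # on the lower wall
                          c(5, 0.5, 5),   # inside lower range
                          c(5, 5.9, 5)),  # inside upper range
                    box = box, params = dpd_params(a_ww = 0, a_wall = 25))
  f <- dpd_forces(sys)
  expect_equal(f$wall[1, ], c(0, 0, 0))
  expect_equal(f$wall[2, ], c(0, 25, 0))           # maximal repulsion +y
  expect_equal(f$wall[3, ], c(0, 25 * 0.5, 0))
  expect_equal(f$wall[4, 2], -25 * 0.9, tolerance = 1e-9)  # 0.1 r_c from wall
  expect_equal(f$wall[4, c(1, 3)], c(0, 0))
  # continuity at the range boundary
  edge <- dpd_system(rbind(c(5, 0.9999, 5)), box = box,
                     params = dpd_params(a_ww = 0, a_wall = 25))
  expect_lt(abs(dpd_forces(edge)$wall[1, 2]), 25 * 2e-4)
})

test_that("containment: no bead leaves the walled box over a long run", {
  set.seed(4)
  L <- c(5, 4, 5)
  n <- round(3 * prod(L))
  pos <- matrix(runif(3 * n), n, 3) %*% diag(L)
  sys <- thermalise(dpd_system(pos, box = dpd_box(L), seed = 4))
  out <- dpd_advance(sys, 10)   # 10^4 steps
  expect_true(all(out$system$pos[, 2] >= 0))
  expect_true(all(out$system$pos[, 2] <= L[2]))
  # near-wall depletion: mean density in the first half r_c is depressed
  frac_low <- mean(out$system$pos[, 2] < 0.5)
  expect_lt(frac_low, 0.5 / L[2])
})

test_that("driven and tethered beads move exactly as prescribed", {
  box <- dpd_box(c(10, 6, 10))
  sys <- dpd_system(rbind(c(5, 3, 5), c(2, 3, 5)), box = box,
                    role = c("driven", "tethered"),
                    drive = rbind(c(0.05, 0, 0), c(0, 0, 0)))
  out <- dpd_advance(sys, 2)   # 2000 steps
  expect_equal(out$system$pos[1, ], c(5 + 0.05 * 2, 3, 5), tolerance = 1e-12)
  expect_equal(out$system$pos[2, ], c(2, 3, 5))
  expect_equal(out$system$vel[1, ], c(0.05, 0, 0))

  # zero forces, zero velocities, no drive: state unchanged
  still <- dpd_system(rbind(c(5, 3, 5)), box = box,
                      params = dpd_params(a_ww = 0))
  expect_equal(dpd_advance(still, 0.5, noise = FALSE)$system$pos,
               still$pos)
})

test_that("momentum is conserved in a fully periodic undriven box", {
  sys <- water_box(L = c(6, 6, 6), seed = 2)
  expect_lt(sqrt(sum(total_momentum(sys)^2)), 1e-10)
  out <- dpd_advance(sys, 1)   # 10^3 steps
  expect_lt(sqrt(sum(total_momentum(out$system)^2)), 1e-8)
})

test_that("trajectories are bit-identical for identical seed and config, and restarts resume exactly", {
  sys <- water_box(L = c(5, 5, 5), seed = 3)
  a <- dpd_advance(sys, 0.2)
  b <- dpd_advance(sys, 0.2)
  expect_identical(a$system$pos, b$system$pos)
  expect_identical(a$system$vel, b$system$vel)

  half1 <- dpd_advance(sys, 0.2)
  half2 <- dpd_advance(half1$system, 0.3)
  whole <- dpd_advance(sys, 0.5)
  expect_identical(half2$system$pos, whole$system$pos)
  expect_identical(half2$system$vel, whole$system$vel)
})

test_that("kinetic temperature estimator follows equipartition and excludes constrained beads", {
  sys <- water_box(L = c(5, 5, 5), seed = 5)
  sys$vel[] <- 0
  expect_equal(kinetic_temperature(sys), 0)
  set.seed(6)
  sys$vel <- matrix(rnorm(nrow(sys$pos) * 3), ncol = 3)
  expect_equal(kinetic_temperature(sys), 1, tolerance = 0.1)
  # constrained beads do not contribute
  sys$role[1:10] <- glycodpd:::.ROLES[["tethered"]]
  sys$vel[1:10, ] <- 100
  expect_equal(kinetic_temperature(sys), 1, tolerance = 0.1)
  sys$role[] <- glycodpd:::.ROLES[["tethered"]]
  expect_error(kinetic_temperature(sys), "free beads")
})

test_that("degenerate coincident pair is flagged, not silently mangled", {
  box <- dpd_box(c(10, 10, 10), periodic = rep(TRUE, 3))
  sys <- dpd_system(rbind(c(5, 5, 5), c(5, 5, 5)), box = box, walls = FALSE)
  expect_warning(dpd_forces(sys), "degenerate")
})
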