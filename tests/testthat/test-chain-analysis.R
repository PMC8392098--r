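# Deformation metrics: RMSD forms, deflection, splines, settling time.

test_that("RMSD follows the printed normalisation, with the conventional form behind a flag", {
  a <- matrix(0, 60, 3)
  b <- a; b[1, 1] <- 1
  expect_equal(chain_rmsd(a, a), 0)
  expect_equal(chain_rmsd(a, b), 1 / 60)
  expect_equal(chain_rmsd(a, b, form = "standard"), 1 / sqrt(60))
  # uniform translation d: printed form gives |d| / sqrt(N_b)
  d <- c(0.3, -0.4, 1.2)
  tr <- sweep(a, 2, -d)
  expect_equal(chain_rmsd(a, tr), sqrt(sum(d^2)) / sqrt(60))
  expect_equal(chain_rmsd(a, tr, form = "standard"), sqrt(sum(d^2)))
  expect_error(chain_rmsd(a, matrix(0, 59, 3)), "mismatch")
})

test_that("printed RMSD is scale-equivariant, permutation-invariant and zero iff identical", {
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    a <- matrix(rnorm(3 * n), n, 3)
    b <- a + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    r <- chain_rmsd(a, b)
    expect_gt(r, 0)
    # scaling all displacements by c scales RMSD by c
    c_ <- runif(1, 0.5, 3)
    expect_equal(chain_rmsd(a, a + c_ * (b - a)), c_ * r, tolerance = 1e-12)
    # permutation invariance under uniform weights
    p <- sample(n)
    expect_equal(chain_rmsd(a[p, ], b[p, ]), r, tolerance = 1e-12)
    # weighted form respects weights
    w <- runif(n)
    manual <- sqrt(sum(w * rowSums((a - b)^2)) / (n * sum(w)))
    expect_equal(chain_rmsd(a, b, weights = w), manual)
  }
})

test_that("tip deflection is zero against itself and exact under rigid translation", {
  run <- cached("micro_A_run31", {
    sys <- cached("micro_A_equil31", {
      s <- build_case(make_mini_case("A", "micro", seed = 31))
      suppressWarnings(equilibrate(s))
    })
    run_production(sys)
  })
  td <- tip_deflection(run)
  t0 <- min(td$time)
  expect_equal(td$dx[td$time == t0], rep(0, 4))
  expect_equal(td$dy[td$time == t0], rep(0, 4))

  # rigid translation of a synthetic two-frame trajectory
  ct <- run$trajectory$chains
  f1 <- run$trajectory$frames[[1]]
  f2 <- f1; f2[, 1] <- f2[, 1] + 2   # may wrap; unwrapping must recover +2
  traj <- new_dpd_trajectory(c(0, 1), list(f1, f2), run$trajectory$species,
                             run$trajectory$role, ct, run$trajectory$box,
                             run$trajectory$params)
  td2 <- tip_deflection(traj)
  expect_equal(td2$dx[td2$time == 1], rep(2, 4), tolerance = 1e-12)
})

test_that("relative deflection divides by contour length and averages over chains", {
  expect_equal(2.95 / 29.5, 0.1)   # the defining arithmetic
  run <- cached("micro_A_run31", run_production(
    cached("micro_A_equil31", suppressWarnings(
      equilibrate(build_case(make_mini_case("A", "micro", seed = 31)))))))
  td <- tip_deflection(run)
  rd <- relative_deflection(run)
  manual <- td |>
    dplyr::group_by(time) |>
    dplyr::summarise(v = mean(dx / 3.5))
  expect_equal(rd$rel_deflection, manual$v, tolerance = 1e-12)
  # central restriction picks the middle two chains
  rdc <- relative_deflection(run, central_only = TRUE, each = TRUE)
  expect_equal(sort(unique(rdc$chain)), c(2, 3))
})

test_that("windowed RMSD is zero for a static trajectory and averages consecutive-frame RMSD", {
  run <- cached("micro_A_run31", run_production(
    cached("micro_A_equil31", suppressWarnings(
      equilibrate(build_case(make_mini_case("A", "micro", seed = 31)))))))
  f <- run$trajectory$frames[[1]]
  static <- new_dpd_trajectory(1:8, rep(list(f), 8), run$trajectory$species,
                               run$trajectory$role, run$trajectory$chains,
                               run$trajectory$box, run$trajectory$params)
  wr <- windowed_rmsd(static, window = 4)
  expect_true(all(wr$rmsd == 0))
  expect_error(windowed_rmsd(static, window = 0.1), "frame interval")
})

test_that("interface spline interpolates the tips and rejects non-monotone layouts", {
  tips <- tibble::tibble(x = c(1, 3, 5, 7, 9), y = c(2, 2, 2, 2, 2))
  sp <- interface_spline(tips)
  expect_equal(sp$y, rep(2, nrow(sp)), tolerance = 1e-9)      # line recovered

  # tips on a parabola: interpolated exactly at the knots
  xp <- seq(0, 8, 1)
  tips2 <- tibble::tibble(x = xp, y = 0.25 * (xp - 4)^2)
  sp2 <- interface_spline(tips2, n_out = 33)
  at_knots <- sp2[sp2$x %in% xp, ]
  expect_equal(at_knots$y, 0.25 * (at_knots$x - 4)^2, tolerance = 1e-6)

  expect_error(interface_spline(tibble::tibble(x = c(1, 1, 2, 3), y = 1:4)),
               "monotone")
  expect_warning(interface_spline(tibble::tibble(x = 1:3, y = c(0, 1, 0))),
                 "fewer than 4")
})

test_that("settling time matches the closed form on synthetic series", {
  tt <- seq(0, 50, 0.1)
  # step series settles immediately
  expect_equal(settling_time(tt, rep(3, length(tt)), tol = 0.01), 0)
  # exponential approach with known time constant
  tc <- 4
  x <- 1 - exp(-tt / tc)
  tol <- 0.02
  plateau <- mean(x[tt >= 0.75 * max(tt)])
  expected <- tt[max(which(abs(x - plateau) > tol)) + 1]   # brute scan
  expect_equal(settling_time(tt, x, tol = tol), expected)
  expect_equal(expected, tc * log(1 / tol), tolerance = 0.1)
  # a ramp that never plateaus is flagged
  expect_warning(out <- settling_time(tt, tt, tol = 0.01), "not plateaued")
  expect_true(is.na(out))
})
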