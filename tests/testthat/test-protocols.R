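# Run recipe: equilibration, drive, events, mini generator.

test_that("zero-span equilibration returns the system unchanged", {
  sys <- build_case(make_mini_case("A", "micro", seed = 31))
  expect_identical(equilibrate(sys, time = 0), sys)
})

test_that("equilibration thermalises to the target temperature and keeps drives inactive", {
  sys <- cached("micro_A_equil31", {
    s <- build_case(make_mini_case("A", "micro", seed = 31))
    suppressWarnings(equilibrate(s))
  })
  expect_equal(sys$equil_temperature, 1, tolerance = 0.05)
  # anchors have not moved during equilibration
  ct <- sys$topology$chains
  cfg <- sys$config
  x0 <- (cfg$L[1] - (cfg$n_rbc - 1) * cfg$rbc_d1) / 2
  expect_equal(sort(sys$pos[ct$anchor[ct$label == "RBC"], 1]),
               x0 + (seq_len(cfg$n_rbc) - 1) * cfg$rbc_d1)
})

test_that("production drives the moving ends at exactly the prescribed speed", {
  run <- cached("micro_A_run31", {
    sys <- cached("micro_A_equil31", {
      s <- build_case(make_mini_case("A", "micro", seed = 31))
      suppressWarnings(equilibrate(s))
    })
    run_production(sys)
  })
  tb <- tibble::as_tibble(run$trajectory)
  ct <- run$trajectory$chains
  an <- ct$anchor[ct$label == "RBC"][1]
  a <- tb[tb$id == an, ]
  a <- a[order(a$time), ]
  # unwrapped displacement equals drive * time at every frame
  dx <- glycodpd:::.unwrap(a$x, run$trajectory$box$L[1]) - a$x[1]
  expect_equal(dx, 0.05 * (a$time - a$time[1]), tolerance = 1e-10)
  expect_true(all(a$vx == 0.05))
  # y, z held
  expect_equal(diff(range(a$y)), 0)
  expect_equal(diff(range(a$z)), 0)
})

test_that("slow and fast drive variants displace by their printed speeds", {
  for (cs in c("A1", "A2")) {
    cfg <- make_mini_case(cs, "micro", seed = 32)
    sys <- build_case(cfg)
    out <- dpd_advance(sys, 1)
    an <- sys$topology$chains$anchor[sys$topology$chains$label == "RBC"][1]
    moved <- out$system$pos[an, 1] - sys$pos[an, 1]
    expect_equal(moved, cfg$drive * 1, tolerance = 1e-10)
  }
})

test_that("release event frees the tether, applies the displacement, and later frames reflect it", {
  cfg <- make_mini_case("G", "micro", seed = 33)
  expect_length(cfg$events, 1)
  ev <- cfg$events[[1]]
  expect_equal(ev$kind, "release_chain")
  expect_equal(ev$time, cfg$production / 2)

  run <- cached("micro_G_run33", {
    sys <- suppressWarnings(equilibrate(build_case(cfg)))
    run_production(sys)
  })
  ct <- run$trajectory$chains
  anchor <- ct$anchor[ct$chain == ev$chain]
  # tether is gone at the end
  expect_equal(run$system$role[anchor], glycodpd:::.ROLES[["free"]])
  # anchor fixed before the event, moving after
  tb <- tibble::as_tibble(run$trajectory)
  aa <- tb[tb$id == anchor, ]
  pre <- aa[aa$time <= ev$time, ]
  post <- aa[aa$time > ev$time + 1, ]
  expect_lt(diff(range(pre$y)), 1e-9)
  expect_gt(sd(post$y), 1e-4)
})

test_that("velocity pulse drives the tips for its duration and then frees them", {
  cfg <- make_mini_case("H", "micro", seed = 34)
  expect_equal(cfg$drive, 0)
  ev <- cfg$events[[1]]
  expect_equal(ev$kind, "velocity_pulse")
  run <- cached("micro_H_run34", {
    sys <- suppressWarnings(equilibrate(build_case(cfg)))
    run_production(sys)
  })
  tb <- tibble::as_tibble(run$trajectory)
  ct <- run$trajectory$chains
  tips <- ct$tip[ct$label == "EG"]
  during <- tb[tb$id %in% tips & tb$time <= ev$duration, ]
  expect_true(all(during$vx == ev$velocity[1]))
  after <- tb[tb$id %in% tips & tb$time > ev$duration + 1, ]
  expect_gt(sd(after$vx), 1e-4)     # free and thermalised again
  expect_equal(run$system$role[tips], rep(glycodpd:::.ROLES[["free"]], 5))
})

test_that("events referencing missing chains or outside the window error", {
  sys <- build_case(make_mini_case("A", "micro", seed = 35))
  sys <- suppressWarnings(equilibrate(sys, time = 0.05))
  expect_error(run_production(sys, time = 1,
                              events = list(event_release_chain(0.5, 99))),
               "missing chain")
  expect_error(run_production(sys, time = 1,
                              events = list(event_release_chain(5, 1))),
               "outside")
})

test_that("mini and micro generators stay geometrically similar and buildable", {
  for (cs in c("A", "B", "C", "D", "F", "G", "H", "A3")) {
    for (sc in c("mini", "micro")) {
      cfg <- make_mini_case(cs, sc, seed = 1)
      expect_equal(nrow(validate_config(cfg)), 0,
                   info = paste(cs, sc))
    }
  }
  # micro-A bead budget: density 3 in 10 x 6 x 4
  cfg <- make_mini_case("A", "micro", 1)
  expect_equal(round(3 * prod(cfg$L)), 720)
  expect_error(make_mini_case("Z", "micro", 1), "unknown case")
})

test_that("an undriven, event-free production is statistically stationary", {
  cfg <- make_mini_case("A", "micro", seed = 36, drive = 0)
  sys <- suppressWarnings(equilibrate(build_case(cfg)))
  run <- run_production(sys, time = 8)
  g <- bin_velocities(run, grid = c(4, 3, 1))
  sp <- sqrt(sum(colMeans(cbind(g$vx, g$vy, g$vz)[g$occupied, ])^2))
  # the domain-mean velocity is the thermal centre-of-mass mode,
  # sd ~ sqrt(kBT/N) ~ 0.04 per component, and it relaxes slowly;
  # 5 sigma of its 3-component norm bounds an undriven run
  expect_lt(sp, 5 * sqrt(1 / sum(run$trajectory$species == 0)))
  d <- relative_deflection(run)
  # thermal tip sway of a semiflexible chain: sd(dx/l0) ~ 0.17 per chain,
  # partially averaged over 4 chains and 8 tau
  expect_lt(abs(mean(d$rel_deflection)), 0.3)
})
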