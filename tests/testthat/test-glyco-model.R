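# Chain and case construction.

test_that("chain builder produces the closed-form bead/bond/angle counts", {
  ch <- build_chain(chain_spec(n_beads = 60), c(10, 0, 20))
  expect_equal(nrow(ch$pos), 60)
  expect_equal(nrow(ch$bonds), 59)
  expect_equal(nrow(ch$angles), 58)
  expect_equal(chain_spec(n_beads = 60)$l0, 29.5)
  expect_equal(chain_spec(n_beads = 30)$l0, 14.5)   # halved chains

  mini <- build_chain(chain_spec(n_beads = 2), c(0, 0, 0))
  expect_equal(nrow(mini$bonds), 1)
  expect_equal(nrow(mini$angles), 0)

  # beads collinear at spacing b0; top-anchored chains grow downward
  up <- build_chain(chain_spec(n_beads = 5), c(1, 0, 2))
  expect_equal(up$pos[, 2], seq(0, 2, 0.5))
  dn <- build_chain(chain_spec(n_beads = 5, anchor = "top"), c(1, 32.5, 2))
  expect_equal(dn$pos[, 2], seq(32.5, 30.5, -0.5))
})

test_that("the case matrix carries the published geometry and variants", {
  tab <- glyco_cases()
  A <- tab[tab$case == "A", ]
  expect_equal(c(A$d0, A$d1, A$n_eg, A$beads, A$kE_half, A$drive),
               c(32.5, 5, 12, 60, 231, 0.05))
  expect_equal(tab$d1[tab$case == "B"], 2.5)
  expect_equal(tab$n_eg[tab$case == "B"], 24L)
  expect_equal(tab$n_eg[tab$case == "C"], 6L)
  expect_equal(tab$beads[tab$case == "D"], 30L)
  expect_equal(tab$d0[tab$case == "F"], 27.5)
  expect_equal(tab$drive[tab$case == "A1"], 0.005)
  expect_equal(tab$drive[tab$case == "A2"], 0.2)
  expect_equal(tab$n_rbc[tab$case == "A3"], 1L)
  expect_equal(tab$kE_half[tab$case %in% c("E1", "E2", "E3", "E4")],
               c(347, 115, 462, 693))
  expect_equal(tab$n_eg[tab$case == "H"], 5L)
  expect_equal(tab$n_rbc[tab$case == "H"], 3L)
})

test_that("configuration validation reports violations instead of throwing", {
  expect_equal(nrow(validate_config(case_config("H"))), 0)
  bad <- case_config("A", d1 = 10, n_eg = 12L)   # span 110 > 80
  v <- validate_config(bad)
  expect_gt(nrow(v), 0)
  expect_true(any(v$field == "d1"))
  v2 <- validate_config(case_config("A", d0 = -1))
  expect_true(any(v2$field == "d0"))
})

test_that("full-scale case A builds with density x volume beads", {
  cfg <- case_config("A", seed = 9)
  sys <- cached("full_A", build_case(cfg))
  expect_equal(nrow(sys$pos), 3 * 80 * 45 * 40)           # 432,000
  ct <- sys$topology$chains
  expect_equal(sum(ct$label == "EG"), 12)
  expect_equal(sum(ct$label == "RBC"), 12)
  expect_equal(nrow(sys$topology$bonds), 24 * 59)
  expect_equal(nrow(sys$topology$angles), 24 * 58)
  expect_equal(sum(sys$species == 0), 432000 - 24 * 60)
  # anchors: lower on the wall plane, upper on the d0 plane
  expect_equal(unique(sys$pos[ct$anchor[ct$label == "EG"], 2]), 0)
  expect_equal(unique(sys$pos[ct$anchor[ct$label == "RBC"], 2]), 32.5)
  # no initial overlap closer than 0.1 r_c between solvent and chains
  w <- sys$pos[sys$species == 0, , drop = FALSE][1:5000, ]
  chainp <- sys$pos[sys$species != 0, , drop = FALSE]
  ok <- glycodpd:::overlap_ok_cpp(w, chainp, sys$box$L, sys$box$periodic, 0.1)
  expect_true(all(ok))
})

test_that("rebuilding with the same config and seed is bit-identical", {
  cfg <- make_mini_case("A", "micro", seed = 11)
  s1 <- build_case(cfg)
  s2 <- build_case(cfg)
  expect_identical(s1$pos, s2$pos)
  expect_identical(s1$vel, s2$vel)
  s3 <- build_case(make_mini_case("A", "micro", seed = 12))
  expect_false(identical(s1$pos, s3$pos))
})

test_that("micro variants preserve the case deviations from baseline", {
  A <- make_mini_case("A", "micro", 1)
  B <- make_mini_case("B", "micro", 1)
  C <- make_mini_case("C", "micro", 1)
  D <- make_mini_case("D", "micro", 1)
  F_ <- make_mini_case("F", "micro", 1)
  expect_equal(B$d1 / A$d1, 0.5)
  expect_equal(B$n_eg / A$n_eg, 2)
  expect_equal(C$d1 / A$d1, 2)
  expect_equal(D$beads / A$beads, 0.5)
  expect_lt(F_$d0, A$d0)
  expect_equal(F_$d0 / A$d0, 27.5 / 32.5)
  expect_equal(make_mini_case("A3", "micro", 1)$n_rbc, 1L)
  # flexibility class preserved: l_p / l0 matches the full-scale brush
  expect_equal((2 * A$kE_half * A$b0) / A$l0, 462 * 0.5 / 29.5,
               tolerance = 0.05)
})

test_that("post-equilibration brush stands between half contour and the stretched contour", {
  sys <- cached("micro_A_equil", {
    s <- build_case(make_mini_case("A", "micro", seed = 21))
    suppressWarnings(equilibrate(s))
  })
  ct <- sys$topology$chains
  eg <- ct[ct$label == "EG", ]
  tips <- sys$pos[eg$tip, 2]
  l0 <- eg$l0[1]
  # bonded neighbours also feel the soft pair repulsion (no exclusions),
  # so the working contour runs ~13% over N_b b0; height must lie between
  # half the nominal contour and the stretched contour
  bonds <- sys$topology$bonds
  bl <- sys$pos[bonds[, 1], ] - sys$pos[bonds[, 2], ]
  for (k in c(1, 3)) bl[, k] <- bl[, k] - sys$box$L[k] * round(bl[, k] / sys$box$L[k])
  contour <- (eg$n_beads[1] - 1) * mean(sqrt(rowSums(bl^2)))
  expect_gt(mean(tips), 0.5 * l0)
  expect_lt(mean(tips), contour)
})
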