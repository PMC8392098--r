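#' Equipartition probe: bonded fluctuation widths in a ghost bath
#'
#' Thermal-statistics check of the bonded terms. A single harmonic dimer
#' and a single bending trimer are embedded in an ideal "ghost" bath
#' (all conservative repulsions zero, standard friction), which thermalises
#' every degree of freedom without perturbing the bonded potentials -- an
#' isolated molecule under purely central pair friction is not ergodic
#' (angular momentum is never damped), so the bath is essential.
#'
#' Two widths are returned, matching the closed-form transverse widths of
#' the printed potentials:
#' * `bond_sd`: standard deviation of the dimer bond length; Boltzmann
#'   statistics of `E = k_s (r - b0)^2` give \eqn{\sqrt{k_B T / 2 k_s}}
#'   (0.0707 r_c at the defaults, radial phase-space correction < 1%).
#' * `angle_width`: \eqn{\sqrt{\langle(\pi - \varphi)^2\rangle / 2}} of the
#'   trimer. The polar bending angle of a 3-D trimer is Rayleigh
#'   distributed, with each transverse component Gaussian of width
#'   \eqn{\sqrt{k_B T / k_E}} (0.0465 rad at the baseline stiffness); the
#'   half-mean-square estimator recovers exactly that component width.
#'
#' @param seed integer seed.
#' @param span sampling span (tau); with `n_probe = 4` molecules of each
#'   kind sampled every 0.016 tau, the default yields 1e5 samples of each
#'   observable.
#' @param k_s,k_E,b0 bonded parameters under test.
#' @param box ghost-bath box lengths (fully periodic).
#' @param n_probe number of independent dimers and trimers embedded.
#' @return One-row tibble: `bond_sd`, `bond_mean`, `angle_width`,
#'   `angle_sd`, `n_samples`, plus the closed-form `bond_sd_expected` and
#'   `angle_width_expected`.
#' @export
equipartition_probe <- function(seed = 1, span = 400, k_s = 100, k_E = 462,
                                b0 = 0.5, box = c(5, 5, 5), n_probe = 4) {
  set.seed(seed)
  L <- box
  p <- dpd_params(a_ww = 0, a_gw = 0, a_gg = 0)
  pos <- list(); bonds <- list(); angles <- list(); off <- 0L
  sites <- as.matrix(tidyr::expand_grid(x = L[1] * c(0.25, 0.75),
                                        y = L[2] * c(0.25, 0.75),
                                        z = L[3] * c(0.25, 0.75)))
  for (m in seq_len(n_probe)) {
    s <- sites[m, ]
    pos[[length(pos) + 1]] <- rbind(s, s + c(b0, 0, 0))
    bonds[[length(bonds) + 1]] <- off + rbind(c(1, 2)); off <- off + 2L
  }
  for (m in seq_len(n_probe)) {
    s <- sites[n_probe + m, ]
    pos[[length(pos) + 1]] <- rbind(s, s + c(b0, 0, 0), s + c(2 * b0, 0, 0))
    bonds[[length(bonds) + 1]] <- off + rbind(c(1, 2), c(2, 3))
    angles[[length(angles) + 1]] <- off + rbind(c(1, 2, 3)); off <- off + 3L
  }
  probe <- do.call(rbind, pos)
  bonds <- do.call(rbind, bonds)
  angles <- do.call(rbind, angles)
  nb <- round(3 * prod(L)) - nrow(probe)
  bath <- matrix(runif(3 * nb), ncol = 3) %*% diag(L)
  sys <- dpd_system(rbind(probe, bath), box = dpd_box(L, periodic = rep(TRUE, 3)),
                    walls = FALSE, params = p,
                    species = c(rep("eg_bead", nrow(probe)), rep("water", nb)),
                    topology = list(bonds = bonds, bond_ks = k_s, bond_b0 = b0,
                                    angles = angles, angle_kE = k_E),
                    seed = seed)
  sys <- thermalise(sys)
  settle <- dpd_advance(sys, 20)
  dimer_bonds <- bonds[seq_len(n_probe), , drop = FALSE]
  out <- dpd_advance(settle$system, span,
                     obs_bonds = dimer_bonds, obs_angles = angles,
                     obs_every = 0.004 * n_probe)
  r <- as.vector(out$obs_r)
  eps <- pi - as.vector(out$obs_phi)
  tibble(bond_sd = sd(r), bond_mean = mean(r),
         angle_width = sqrt(mean(eps^2) / 2), angle_sd = sd(eps),
         n_samples = length(r),
         bond_sd_expected = sqrt(1 / (2 * k_s)),
         angle_width_expected = sqrt(1 / k_E))
}

#' Thermostat check on a pure solvent box
#'
#' Equilibrates a periodic water box at the standard parameters and
#' returns the mean kinetic temperature over the sampling span; the
#' fluctuation--dissipation relation of the pair thermostat should hold it
#' at the target within a few percent.
#'
#' @param seed integer seed.
#' @param box box lengths (fully periodic).
#' @param equil,sample equilibration and sampling spans (tau).
#' @param params a [dpd_params()].
#' @return One-row tibble: `mean_kBT`, `se_kBT`, `n_beads`, `target`.
#' @export
thermostat_check <- function(seed = 1, box = c(10, 10, 10), equil = 50,
                             sample = 50, params = dpd_params()) {
  set.seed(seed)
  n <- round(3 * prod(box))
  pos <- matrix(runif(3 * n), n, 3) %*% diag(box)
  sys <- dpd_system(pos, box = dpd_box(box, periodic = rep(TRUE, 3)),
                    walls = FALSE, params = params, seed = seed)
  sys <- thermalise(sys)
  eq <- dpd_advance(sys, equil)
  out <- dpd_advance(eq$system, sample, sample_every = 0.05)
  Ts <- out$temperature
  ess <- max(4, length(Ts) / 10)   # conservative: samples are correlated
  tibble(mean_kBT = mean(Ts), se_kBT = sd(Ts) / sqrt(ess),
         n_beads = n, target = params$kBT)
}
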