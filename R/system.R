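#' Simulation box
#'
#' Orthorhombic domain with periodic x and z axes and (by default) soft
#' repulsive walls closing the y axis at `y = 0` and `y = Ly`.
#'
#' @param L box edge lengths `c(Lx, Ly, Lz)` in r_c.
#' @param periodic logical length-3; the walled y axis is non-periodic in all
#'   production geometries, but a fully periodic box is supported for
#'   momentum-conservation and pure-solvent checks.
#' @return A `dpd_box` list with elements `L` and `periodic`.
#' @export
dpd_box <- function(L, periodic = c(TRUE, FALSE, TRUE)) {
  L <- as.numeric(L)
  stopifnot(length(L) == 3, all(L > 0), length(periodic) == 3)
  structure(list(L = L, periodic = as.logical(periodic)), class = "dpd_box")
}

#' Assemble a particle system
#'
#' Low-level constructor used by [build_case()]; exposed so that small
#' hand-built systems (dimers, trimers, solvent boxes) can be driven directly.
#'
#' @param pos N x 3 positions (r_c).
#' @param vel N x 3 velocities (r_c/tau); defaults to zero.
#' @param species integer or character vector (`"water"`, `"eg_bead"`,
#'   `"rbc_bead"`).
#' @param role integer or character vector (`"free"`, `"tethered"`,
#'   `"driven"`).
#' @param box a [dpd_box()].
#' @param params a [dpd_params()].
#' @param topology list with `bonds` (m x 2, 1-based), `bond_ks`, `bond_b0`,
#'   `angles` (k x 3, centre bead second), `angle_kE`, `angle_phi0`, and an
#'   optional `chains` tibble. Missing pieces default to empty.
#' @param drive N x 3 prescribed velocities for driven beads.
#' @param mass scalar or per-bead mass (reduced; default 1).
#' @param walls logical; apply the soft y walls (ignored when y is periodic).
#' @param seed integer seed feeding the counter-based pair noise.
#'
#' @return A `dpd_system` object.
#' @export
dpd_system <- function(pos, vel = NULL, species = "water", role = "free",
                       box, params = dpd_params(), topology = list(),
                       drive = NULL, mass = 1, walls = !box$periodic[2],
                       seed = 1L) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, is.finite(pos))
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  vel <- as.matrix(vel)
  stopifnot(nrow(vel) == n, ncol(vel) == 3, is.finite(vel))
  species <- .code_vec(species, .SPECIES, n)
  role <- .code_vec(role, .ROLES, n)
  if (is.null(drive)) drive <- matrix(0, n, 3)
  topology <- .complete_topology(topology)
  if (nrow(topology$bonds) > 0)
    stopifnot(all(topology$bonds >= 1), all(topology$bonds <= n))
  if (nrow(topology$angles) > 0)
    stopifnot(all(topology$angles >= 1), all(topology$angles <= n))
  structure(list(pos = pos, vel = vel, species = species, role = role,
                 mass = mass, drive = as.matrix(drive), box = box,
                 params = params, topology = topology,
                 walls = isTRUE(walls) && !box$periodic[2],
                 seed = as.integer(seed), step = 0, time = 0,
                 force = NULL, config = NULL),
            class = "dpd_system")
}

.code_vec <- function(x, codes, n) {
  if (is.character(x)) x <- codes[x]
  x <- as.integer(x)
  if (length(x) == 1) x <- rep(x, n)
  stopifnot(length(x) == n, !anyNA(x), all(x %in% codes))
  x
}

.complete_topology <- function(top) {
  def <- list(bonds = matrix(integer(), 0, 2), bond_ks = 100, bond_b0 = 0.5,
              angles = matrix(integer(), 0, 3), angle_kE = 462,
              angle_phi0 = pi, chains = NULL)
  for (nm in names(def)) if (is.null(top[[nm]])) top[[nm]] <- def[[nm]]
  top$bonds <- matrix(as.integer(top$bonds), ncol = 2)
  top$angles <- matrix(as.integer(top$angles), ncol = 3)
  top
}

#' @export
print.dpd_system <- function(x, ...) {
  cat("<dpd_system> ", nrow(x$pos), " beads in ",
      paste(x$box$L, collapse = " x "), " r_c^3\n", sep = "")
  tab <- table(factor(names(.SPECIES)[x$species + 1L], levels = names(.SPECIES)))
  cat("  species:", paste(names(tab), tab, collapse = ", "), "\n")
  cat("  bonds:", nrow(x$topology$bonds), " angles:", nrow(x$topology$angles),
      " time:", format(x$time), "tau\n")
  invisible(x)
}

#' Evaluate forces on the current configuration
#'
#' Computes the decomposed force field (pairwise conservative + dissipative
#' \[+ random\], bonds, angles, walls) without advancing time. The random
#' term is reproducible: it is keyed by `(seed, step, pair)`.
#'
#' @param system a `dpd_system`.
#' @param noise include the random force term.
#' @param step evaluation counter used to key the pair noise.
#' @return List with N x 3 matrices `force`, `pair`, `bond`, `angle`, `wall`
#'   and scalars `e_bond`, `e_bend`, `degenerate_pairs`.
#' @export
dpd_forces <- function(system, noise = FALSE, step = system$step) {
  s <- system
  res <- dpd_forces_cpp(s$pos, s$vel, s$species, s$role,
                        as.numeric(s$mass),
                        s$box$L, s$box$periodic,
                        s$params$a, s$params$beta, s$params$kBT, s$params$dt,
                        noise, s$params$exclude_12, s$walls, s$params$a_wall,
                        s$params$body_force,
                        s$topology$bonds - 1L, as.numeric(s$topology$bond_ks),
                        as.numeric(s$topology$bond_b0),
                        s$topology$angles - 1L, as.numeric(s$topology$angle_kE),
                        as.numeric(s$topology$angle_phi0),
                        s$seed, step)
  if (res$degenerate_pairs > 0)
    warn(paste0(res$degenerate_pairs,
                " degenerate (coincident) pair(s) skipped in force loop"))
  res
}

#' Advance a system by an integer number of steps
#'
#' The raw integration primitive beneath [equilibrate()] and
#' [run_production()]: Groot--Warren modified velocity-Verlet for free beads,
#' kinematic displacement for driven beads, tethered beads pinned. The force
#' of the final evaluation is stored on the returned system so that a
#' follow-on call reproduces an unsplit run bit-for-bit.
#'
#' @param system a `dpd_system`.
#' @param time span to integrate, in tau (converted to steps with the
#'   system timestep).
#' @param frame_every,sample_every,record_every output intervals in tau
#'   (0 disables). Frames carry positions and velocities; samples carry the
#'   instantaneous kinetic temperature; records carry the accumulated
#'   non-bonded force on `record_ids` beads, split into the solvent-only and
#'   total pair contributions.
#' @param record_ids bead indices (1-based) whose per-bead pair forces are
#'   streamed.
#' @param obs_bonds,obs_angles index pairs/triples (1-based) whose bond
#'   lengths / bending angles are sampled every `obs_every` tau (cheap
#'   high-rate observables for equipartition checks).
#' @param obs_every observable sampling interval (tau; 0 disables).
#' @param noise thermostat on (default) or off.
#' @return List with the advanced `system`, a frames list, `frame_time`,
#'   temperature samples, the force stream and observable samples.
#' @export
dpd_advance <- function(system, time, frame_every = 0, sample_every = 0,
                        record_every = 0, record_ids = integer(),
                        obs_bonds = NULL, obs_angles = NULL, obs_every = 0,
                        noise = TRUE) {
  s <- system
  dt <- s$params$dt
  nsteps <- as.integer(round(time / dt))
  if (nsteps <= 0) {
    return(list(system = s, frames = list(), frame_time = numeric(),
                temperature = numeric(), temperature_time = numeric(),
                rec_water = matrix(0, 0, 0), rec_all = matrix(0, 0, 0),
                rec_time = numeric(), obs_r = matrix(0, 0, 0),
                obs_phi = matrix(0, 0, 0), obs_time = numeric()))
  }
  to_steps <- function(x) if (x > 0) max(1L, as.integer(round(x / dt))) else 0L
  ob <- if (is.null(obs_bonds)) matrix(integer(), 0, 2) else matrix(as.integer(obs_bonds), ncol = 2)
  oa <- if (is.null(obs_angles)) matrix(integer(), 0, 3) else matrix(as.integer(obs_angles), ncol = 3)
  res <- dpd_run_cpp(s$pos, s$vel, s$species, s$role, s$drive,
                     as.numeric(s$mass), s$box$L, s$box$periodic,
                     s$params$a, s$params$beta, s$params$kBT, dt,
                     s$params$lambda, noise, s$params$exclude_12,
                     s$walls, s$params$a_wall, s$params$body_force,
                     s$topology$bonds - 1L, as.numeric(s$topology$bond_ks),
                     as.numeric(s$topology$bond_b0),
                     s$topology$angles - 1L, as.numeric(s$topology$angle_kE),
                     as.numeric(s$topology$angle_phi0),
                     nsteps, s$step, s$seed,
                     to_steps(frame_every), to_steps(sample_every),
                     as.integer(record_ids) - 1L, to_steps(record_every),
                     s$force, ob - 1L, oa - 1L, to_steps(obs_every))
  s$pos <- res$pos
  s$vel <- res$vel
  s$force <- res$force
  s$step <- res$step_end
  s$time <- s$time + nsteps * dt
  list(system = s, frames = res$frames, frame_time = res$frame_time,
       temperature = res$temperature, temperature_time = res$temperature_time,
       rec_water = res$rec_water, rec_all = res$rec_all,
       rec_time = res$rec_time, obs_r = res$obs_r, obs_phi = res$obs_phi,
       obs_time = res$obs_time, reflections = res$reflections)
}

#' Instantaneous kinetic temperature
#'
#' \eqn{k_B T = \sum m v^2 / (3 N_{free})} over free beads only; tethered and
#' driven beads carry no thermal kinetic energy and are excluded.
#'
#' @param system a `dpd_system`.
#' @return Reduced temperature estimate (scalar).
#' @export
kinetic_temperature <- function(system) {
  free <- system$role == .ROLES[["free"]]
  if (!any(free)) abort("no free beads: kinetic temperature undefined")
  v <- system$vel[free, , drop = FALSE]
  m <- if (length(system$mass) == 1) system$mass else system$mass[free]
  sum(m * rowSums(v^2)) / (3 * sum(free))
}

#' Draw Maxwell-Boltzmann velocities for the free beads
#'
#' Gaussian components at the target temperature with the centre-of-mass
#' drift of the free beads removed; tethered and driven beads are zeroed.
#'
#' @param system a `dpd_system`.
#' @return The system with refreshed velocities.
#' @export
thermalise <- function(system) {
  n <- nrow(system$pos)
  v <- matrix(rnorm(3 * n, sd = sqrt(system$params$kBT)), n, 3)
  free <- system$role == .ROLES[["free"]]
  v[!free, ] <- 0
  if (any(free)) {
    v[free, ] <- sweep(v[free, , drop = FALSE], 2,
                       colMeans(v[free, , drop = FALSE]))
  }
  system$vel <- v
  system$drive[system$role == .ROLES[["driven"]], ] <-
    system$drive[system$role == .ROLES[["driven"]], , drop = FALSE]
  system
}

#' Total momentum of the system
#' @param system a `dpd_system`.
#' @return Length-3 momentum vector (reduced units).
#' @export
total_momentum <- function(system) {
  m <- if (length(system$mass) == 1) rep(system$mass, nrow(system$vel)) else system$mass
  colSums(system$vel * m)
}

#' @export
as_tibble.dpd_system <- function(x, ...) {
  chains <- x$topology$chains
  chain_of <- rep(NA_integer_, nrow(x$pos))
  label_of <- rep(NA_character_, nrow(x$pos))
  if (!is.null(chains)) {
    for (i in seq_len(nrow(chains))) {
      idx <- chains$first[i]:chains$last[i]
      chain_of[idx] <- chains$chain[i]
      label_of[idx] <- chains$label[i]
    }
  }
  p <- x$pos; v <- x$vel
  tibble(id = seq_len(nrow(p)),
         species = names(.SPECIES)[x$species + 1L],
         role = names(.ROLES)[x$role + 1L],
         chain = chain_of, label = label_of,
         x = p[, 1], y = p[, 2], z = p[, 3],
         vx = v[, 1], vy = v[, 2], vz = v[, 3])
}
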