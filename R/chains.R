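#' Specification of a single glycocalyx chain
#'
#' A bead-string chain: `n_beads` beads at equilibrium bond length `b0`
#' (contour length `l0 = (n_beads - 1) * b0`), harmonic bonds of stiffness
#' `k_s` (energy `k_s (r - b0)^2`, no 1/2 prefactor) and harmonic bending of
#' constant `k_E` about the straight angle.
#'
#' @param n_beads beads per chain (>= 2).
#' @param b0 equilibrium bond length (r_c).
#' @param k_s spring coefficient (kBT / r_c^2).
#' @param k_E bending constant (kBT / rad^2); the baseline brush uses
#'   `k_E = 462` (i.e. `k_E/2 = 231`).
#' @param anchor `"wall"` (tethered at the bottom, grows upward, endothelial
#'   side) or `"top"` (anchored on the upper plane, grows downward, red-cell
#'   side).
#' @param drive prescribed anchor velocity vector for driven chains
#'   (r_c/tau); `c(0,0,0)` tethers the anchor instead.
#' @return A `chain_spec` list; `l0` is derived.
#' @export
chain_spec <- function(n_beads = 60, b0 = 0.5, k_s = 100, k_E = 462,
                       anchor = c("wall", "top"), drive = c(0, 0, 0)) {
  anchor <- match.arg(anchor)
  stopifnot(n_beads >= 2, b0 > 0, k_s > 0, k_E >= 0)
  structure(list(n_beads = as.integer(n_beads), b0 = b0, k_s = k_s, k_E = k_E,
                 anchor = anchor, drive = as.numeric(drive),
                 l0 = (n_beads - 1) * b0),
            class = "chain_spec")
}

#' Build one chain's coordinates and local topology
#'
#' Beads are laid out collinearly from the anchor point: upward (+y) for
#' wall-anchored chains, downward (-y) for top-anchored chains.
#'
#' @param spec a [chain_spec()].
#' @param anchor_position length-3 anchor coordinates (r_c).
#' @return List with `pos` (n_beads x 3), `bonds` (local 1-based,
#'   `n_beads - 1` rows) and `angles` (`n_beads - 2` rows, centre second).
#' @examples
#' ch <- build_chain(chain_spec(n_beads = 60), c(10, 0, 20))
#' nrow(ch$bonds)   # 59
#' nrow(ch$angles)  # 58
#' @export
build_chain <- function(spec, anchor_position) {
  n <- spec$n_beads
  dirn <- if (spec$anchor == "wall") 1 else -1
  pos <- cbind(rep(anchor_position[1], n),
               anchor_position[2] + dirn * spec$b0 * (seq_len(n) - 1),
               rep(anchor_position[3], n))
  bonds <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  angles <- if (n >= 3) cbind(seq_len(n - 2), seq_len(n - 2) + 1L,
                              seq_len(n - 2) + 2L)
            else matrix(integer(), 0, 3)
  list(pos = pos, bonds = bonds, angles = angles)
}

# ---------------------------------------------------------------------------
# case matrix: one row per study condition

.case_table <- function() {
  tibble::tribble(
    ~case, ~d0,  ~d1,  ~n_eg, ~beads, ~kE_half, ~drive, ~n_rbc, ~remark,
    "0",   NA,   5,    12L,   60L,    231,      NA,     0L,  "brush in flow (two-compartment)",
    "A",   32.5, 5,    12L,   60L,    231,      0.05,   12L, "normal condition",
    "A1",  32.5, 5,    12L,   60L,    231,      0.005,  12L, "slow red cells",
    "A2",  32.5, 5,    12L,   60L,    231,      0.2,    12L, "fast red cells",
    "A3",  32.5, 5,    12L,   60L,    231,      0.05,   1L,  "red-cell glycocalyx shedding",
    "B",   32.5, 2.5,  24L,   60L,    231,      0.05,   12L, "dense brush",
    "C",   32.5, 10,   6L,    60L,    231,      0.05,   12L, "rarefied brush",
    "D",   32.5, 5,    12L,   30L,    231,      0.05,   12L, "short chains",
    "E1",  32.5, 5,    12L,   60L,    347,      0.05,   12L, "stiffer brush",
    "E2",  32.5, 5,    12L,   60L,    115,      0.05,   12L, "softer brush",
    "E3",  32.5, 5,    12L,   60L,    462,      0.05,   12L, "stiffer brush",
    "E4",  32.5, 5,    12L,   60L,    693,      0.05,   12L, "stiffest brush",
    "F",   27.5, 5,    12L,   60L,    231,      0.05,   12L, "close separation",
    "G",   32.5, 5,    12L,   60L,    231,      0.05,   12L, "release central chain",
    "H",   32.5, 5,    5L,    60L,    231,      0,      3L,  "brush propels red cell"
  )
}

#' Named study cases
#'
#' The case matrix of the study: anchor-plane separation `d0`, anchor spacing
#' `d1`, endothelial chain count and length, bending constant (as `k_E/2`),
#' drive speed of the red-cell anchors, and the red-cell chain count. Cases
#' `G` (timed release of the central chain) and `H` (activation pulse on the
#' endothelial tips, no drive) additionally carry events, attached by
#' [case_config()].
#'
#' @return A tibble, one row per case.
#' @export
glyco_cases <- function() .case_table()

#' Configuration for one simulation case
#'
#' Produces the reproducibility unit for a run: geometry, chain counts,
#' spans, events and seed. Three problem scales are provided: `"full"` is
#' the published geometry (80 x 45 x 40 r_c^3, 432,000 beads, 200 + 1600
#' tau); `"mini"` and `"micro"` are geometrically similar reductions for
#' desk-scale work (see [make_mini_case()]).
#'
#' @param case case id, one of `glyco_cases()$case`.
#' @param scale `"full"`, `"mini"` or `"micro"`.
#' @param seed integer seed for construction and pair noise.
#' @param ... field overrides (any of the returned list's scalars).
#' @return A `case_config` list.
#' @export
case_config <- function(case = "A", scale = c("full", "mini", "micro"),
                        seed = 1L, ...) {
  scale <- match.arg(scale)
  tab <- .case_table()
  if (!case %in% tab$case) abort(paste0("unknown case '", case, "'"))
  row <- tab[tab$case == case, ]
  cfg <- list(case = case, scale = scale, seed = as.integer(seed),
              d0 = row$d0, d1 = row$d1,
              n_eg = row$n_eg, beads = row$beads, kE_half = row$kE_half,
              drive = row$drive, n_rbc = row$n_rbc,
              b0 = 0.5, k_s = 100,
              L = c(80, 45, 40), density = 3.0,
              equil = 200, production = 1600,
              rbc_d1 = 5, rbc_beads = 60L,
              frame_every = 1, sample_every = 1,
              body_force = if (case == "0") 0.0006 else 0,
              remark = row$remark)
  if (scale != "full") cfg <- .scale_config(cfg, scale)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg$l0 <- (cfg$beads - 1) * cfg$b0
  cfg$events <- .case_events(cfg)
  class(cfg) <- "case_config"
  cfg
}

# geometric reduction keeping the published dimensionless ratios:
# d0/l0 ~ 1.1, anchor spacing d1/l0, persistence-to-contour ratio
# l_p / l0 = k_E b0 / (kBT l0) (so the bending constant scales with the
# baseline contour length -- shorter chains at the same flexibility class,
# not rigid rods), drive speeds and number density as printed
.scale_config <- function(cfg, scale) {
  if (scale == "mini") {
    geo <- list(L = c(20, 20, 10), beads = 20L, d0 = 10.5, d1 = 4,
                n_eg = 4L, n_rbc = 4L, rbc_d1 = 4, rbc_beads = 20L,
                equil = 20, production = 60)
  } else {
    geo <- list(L = c(10, 6, 4), beads = 8L, d0 = 4, d1 = 2.5,
                n_eg = 4L, n_rbc = 4L, rbc_d1 = 2.5, rbc_beads = 8L,
                equil = 5, production = 16, frame_every = 0.25)
  }
  full <- .case_table()[.case_table()$case == cfg$case, ]
  base <- .case_table()[.case_table()$case == "A", ]
  # bending constant follows the scale's baseline contour length (l_p/l0
  # similarity); the case's stiffness deviations (E1-E4) carry over as the
  # same multiples of the scaled baseline
  l0_ratio <- ((geo$beads - 1) * cfg$b0) / 29.5
  cfg$kE_half <- max(1, round(full$kE_half * l0_ratio))
  # carry the case's deviations from A over to the reduced geometry
  geo$d1 <- geo$d1 * full$d1 / base$d1
  geo$n_eg <- as.integer(round(geo$n_eg * full$n_eg / base$n_eg))
  geo$beads <- as.integer(round(geo$beads * full$beads / base$beads))
  if (!is.na(full$d0)) geo$d0 <- geo$d0 * full$d0 / base$d0 else geo$d0 <- NA
  if (full$n_rbc != base$n_rbc)
    geo$n_rbc <- max(if (full$n_rbc > 0) 1L else 0L,
                     as.integer(round(geo$n_rbc * full$n_rbc / base$n_rbc)))
  if (cfg$case == "H") {
    # three upper / five lower chains at every scale, as in the published
    # case; spacings tile the periodic x axis
    geo$n_eg <- 5L
    geo$n_rbc <- 3L
    geo$d1 <- geo$L[1] / 5
    geo$rbc_d1 <- geo$L[1] / 3
  }
  for (nm in names(geo)) cfg[[nm]] <- geo[[nm]]
  cfg
}

.case_events <- function(cfg) {
  ev <- list()
  if (cfg$case == "G") {
    # central chain displaced +2 r_c (scaled) and untethered at half production
    dy <- if (cfg$scale == "full") 2 else 2 * cfg$l0 / 29.5
    ev <- list(event_release_chain(time = cfg$production / 2,
                                   chain = floor(cfg$n_eg / 2) + 1L,
                                   displacement = c(0, dy, 0)))
  } else if (cfg$case == "H") {
    pulse <- if (cfg$scale == "micro") 2 else 5
    ev <- list(event_velocity_pulse(time = 0, chains = seq_len(cfg$n_eg),
                                    velocity = c(0.05, 0, 0),
                                    duration = pulse))
  }
  ev
}

#' Validate a case configuration
#'
#' Reports (never throws) geometric and physical infeasibilities: chain rows
#' wider than the box, chains longer than the available height, non-positive
#' separations or densities.
#'
#' @param config a [case_config()].
#' @return Tibble of violations with columns `field` and `message`; zero rows
#'   when the configuration is buildable.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, msg) v[[length(v) + 1]] <<- tibble(field = field, message = msg)
  with(config, {
    if (any(L <= 0)) bad("L", "box lengths must be positive")
    if (density <= 0) bad("density", "number density must be positive")
    if (!is.na(d0) && d0 <= 0) bad("d0", "anchor-plane separation must be positive")
    if (d1 <= 0) bad("d1", "anchor spacing must be positive")
    span <- (n_eg - 1) * d1
    if (span > L[1]) bad("d1", sprintf("chain row span %.3g exceeds Lx = %.3g", span, L[1]))
    if ((beads - 1) * b0 >= L[2]) bad("beads", "chain contour length exceeds box height")
    if (!is.na(d0) && d0 > L[2]) bad("d0", "anchor plane above the box")
    if (n_rbc > 0) {
      rspan <- (n_rbc - 1) * rbc_d1
      if (rspan > L[1]) bad("rbc_d1", sprintf("upper row span %.3g exceeds Lx = %.3g", rspan, L[1]))
    }
    if (beads < 2) bad("beads", "chains need at least 2 beads")
    if (equil < 0 || production <= 0) bad("schedule", "spans must be non-negative/positive")
  })
  if (length(v) == 0) tibble(field = character(), message = character())
  else dplyr::bind_rows(v)
}

#' Build the full particle system for a case
#'
#' Places the endothelial chains in a single row along x at `z = Lz/2`
#' (anchors on the `y = 0` wall, spacing `d1`, row centred in x), the
#' red-cell chains hanging from the `y = d0` anchor plane, and fills the
#' remaining volume with solvent beads to the target number density
#' (uniform insertion, re-drawn where closer than 0.1 r_c to a chain bead).
#' Free-bead velocities are Maxwell-Boltzmann at the target temperature.
#' Construction is deterministic given `config$seed`.
#'
#' @param config a [case_config()].
#' @return A `dpd_system` with chain topology attached.
#' @export
build_case <- function(config) {
  viol <- validate_config(config)
  if (nrow(viol) > 0)
    abort(paste0("invalid configuration:\n",
                 paste0("  ", viol$field, ": ", viol$message, collapse = "\n")))
  set.seed(config$seed)
  L <- config$L
  box <- dpd_box(L)

  eg_spec <- chain_spec(n_beads = config$beads, b0 = config$b0,
                        k_s = config$k_s, k_E = 2 * config$kE_half,
                        anchor = "wall")
  x0 <- (L[1] - (config$n_eg - 1) * config$d1) / 2
  eg_anchors <- x0 + (seq_len(config$n_eg) - 1) * config$d1

  pos_list <- list(); bonds <- list(); angles <- list(); chains <- list()
  species <- integer(); role <- integer()
  offset <- 0L
  add_chain <- function(spec, anchor, label, sp_code, chain_id) {
    ch <- build_chain(spec, anchor)
    n <- spec$n_beads
    pos_list[[length(pos_list) + 1]] <<- ch$pos
    bonds[[length(bonds) + 1]] <<- ch$bonds + offset
    if (nrow(ch$angles) > 0)
      angles[[length(angles) + 1]] <<- ch$angles + offset
    anchor_id <- offset + 1L
    tip_id <- offset + n
    ax <- anchor[1]
    driven <- any(spec$drive != 0)
    r <- rep(.ROLES[["free"]], n)
    r[1] <- if (driven) .ROLES[["driven"]] else .ROLES[["tethered"]]
    role <<- c(role, r)
    species <<- c(species, rep(sp_code, n))
    chains[[length(chains) + 1]] <<- tibble(
      chain = chain_id, label = label, first = anchor_id, last = tip_id,
      n_beads = n, b0 = spec$b0, l0 = spec$l0,
      anchor = anchor_id, tip = tip_id,
      anchor_x = ax, k_E = spec$k_E)
    offset <<- offset + n
  }

  cid <- 0L
  for (ax in eg_anchors) {
    cid <- cid + 1L
    add_chain(eg_spec, c(ax, 0, L[3] / 2), "EG", .SPECIES[["eg_bead"]], cid)
  }
  if (config$n_rbc > 0) {
    rbc_spec <- chain_spec(n_beads = config$rbc_beads, b0 = config$b0,
                           k_s = config$k_s, k_E = 2 * config$kE_half,
                           anchor = "top",
                           drive = c(config$drive, 0, 0))
    rx0 <- (L[1] - (config$n_rbc - 1) * config$rbc_d1) / 2
    rbc_anchors <- rx0 + (seq_len(config$n_rbc) - 1) * config$rbc_d1
    # chains longer than the anchor height are laid in at a tilt so the
    # initial state fits above the wall; they relax freely afterwards
    tilt <- acos(min(1, (config$d0 - 0.1) / rbc_spec$l0))
    for (ax in rbc_anchors) {
      cid <- cid + 1L
      add_chain(rbc_spec, c(ax, config$d0, L[3] / 2), "RBC",
                .SPECIES[["rbc_bead"]], cid)
      if (tilt > 0) {
        row <- chains[[length(chains)]]
        idx <- row$first:row$last
        dy <- config$d0 - pos_list[[length(pos_list)]][, 2]
        pos_list[[length(pos_list)]][, 1] <- ax + dy * sin(tilt)
        pos_list[[length(pos_list)]][, 2] <- config$d0 - dy * cos(tilt)
      }
    }
  }

  chain_pos <- do.call(rbind, pos_list)
  n_chain <- nrow(chain_pos)
  n_total <- round(config$density * prod(L))
  n_water <- n_total - n_chain
  if (n_water < 0) abort("chain beads alone exceed the target density")

  water <- matrix(runif(3 * n_water), n_water, 3) %*% diag(L)
  for (k in 1:20) {
    ok <- overlap_ok_cpp(water, chain_pos, L, box$periodic, 0.1)
    if (all(ok)) break
    nbad <- sum(!ok)
    water[!ok, ] <- matrix(runif(3 * nbad), nbad, 3) %*% diag(L)
  }

  pos <- rbind(chain_pos, water)
  species <- c(species, rep(.SPECIES[["water"]], n_water))
  role <- c(role, rep(.ROLES[["free"]], n_water))
  chains <- dplyr::bind_rows(chains)

  nb <- do.call(rbind, bonds)
  na_ <- if (length(angles)) do.call(rbind, angles) else matrix(integer(), 0, 3)
  topology <- list(bonds = nb, bond_ks = config$k_s, bond_b0 = config$b0,
                   angles = na_, angle_kE = 2 * config$kE_half,
                   angle_phi0 = pi, chains = chains)

  drive <- matrix(0, nrow(pos), 3)
  driven_ids <- chains$anchor[chains$label == "RBC"]
  if (length(driven_ids) > 0 && !is.na(config$drive) && config$drive != 0)
    drive[driven_ids, 1] <- config$drive

  params <- dpd_params(body_force = c(config$body_force, 0, 0))
  sys <- dpd_system(pos = pos, species = species, role = role, box = box,
                    params = params, topology = topology, drive = drive,
                    seed = config$seed)
  sys <- thermalise(sys)
  sys$config <- config
  sys
}
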