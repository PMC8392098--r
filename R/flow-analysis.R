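#' Bin bead velocities on a cuboid mesh
#'
#' Divides the domain into `grid = c(nx, ny, nz)` equal cuboid bins (the
#' published analysis uses 16 x 9 x 1 over the 80 x 45 x 40 domain, i.e.
#' 5 x 5 x 40 r_c bins) and averages the velocities of the selected beads
#' over all frames in the time window. Each occupied bin carries its mean
#' velocity vector, sample count and in-plane orientation
#' `theta = atan2(vy, vx)`; empty bins are flagged and excluded from
#' statistics.
#'
#' @param x a `dpd_run`, `dpd_trajectory` or tidy trajectory tibble.
#' @param grid bin counts `c(nx, ny, nz)`.
#' @param species species filter, default `"water"`; `NULL` keeps all beads.
#' @param window time window `c(from, to)` in tau, or `"last:<span>"`
#'   (e.g. `"last:400"`), or `NULL` for all frames.
#' @param box box lengths when `x` is a plain tibble.
#' @return A `flow_grid` tibble: one row per bin with `ix, iy, iz`,
#'   bin centres, `n`, `vx, vy, vz`, `speed`, `theta`, `occupied`.
#' @export
bin_velocities <- function(x, grid = c(16, 9, 1), species = "water",
                           window = NULL, box = NULL) {
  L <- .traj_box(x)
  if (anyNA(L)) {
    if (is.null(box)) abort("supply box lengths for a plain trajectory table")
    L <- box
  }
  tb <- .as_traj_tbl(x)
  stopifnot(length(grid) == 3, all(grid >= 1))
  tb <- .window_filter(tb, window)
  if (!is.null(species)) tb <- tb[tb$species %in% species, ]
  if (nrow(tb) == 0) abort("no beads left after filtering")
  h <- L / grid
  bx <- pmin(pmax(floor(tb$x / h[1]), 0), grid[1] - 1)
  by <- pmin(pmax(floor(tb$y / h[2]), 0), grid[2] - 1)
  bz <- pmin(pmax(floor(tb$z / h[3]), 0), grid[3] - 1)
  full <- tidyr::expand_grid(ix = seq_len(grid[1]) - 1L,
                             iy = seq_len(grid[2]) - 1L,
                             iz = seq_len(grid[3]) - 1L)
  agg <- tibble(ix = as.integer(bx), iy = as.integer(by), iz = as.integer(bz),
                vx = tb$vx, vy = tb$vy, vz = tb$vz) |>
    dplyr::group_by(.data$ix, .data$iy, .data$iz) |>
    dplyr::summarise(n = dplyr::n(), vx = mean(.data$vx), vy = mean(.data$vy),
                     vz = mean(.data$vz), .groups = "drop")
  out <- dplyr::left_join(full, agg, by = c("ix", "iy", "iz")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  occupied = .data$n > 0,
                  x_mid = (.data$ix + 0.5) * h[1],
                  y_mid = (.data$iy + 0.5) * h[2],
                  z_mid = (.data$iz + 0.5) * h[3],
                  speed = sqrt(.data$vx^2 + .data$vy^2 + .data$vz^2),
                  theta = dplyr::if_else(.data$occupied,
                                         atan2(.data$vy, .data$vx), NA_real_))
  structure(out, class = c("flow_grid", class(out)),
            box = L, grid = as.integer(grid))
}

.window_filter <- function(tb, window) {
  if (is.null(window)) return(tb)
  if (is.character(window) && grepl("^last:", window)) {
    span <- as.numeric(sub("^last:", "", window))
    tmax <- max(tb$time)
    return(tb[tb$time > tmax - span + 1e-9, ])
  }
  stopifnot(is.numeric(window), length(window) == 2)
  tb[tb$time >= window[1] & tb$time <= window[2], ]
}

#' Circular statistics of flow orientations
#'
#' Pools the in-plane orientations `theta` of the occupied bins and returns
#' the mean resultant direction and the circular standard deviation
#' \eqn{\sqrt{-2\ln \bar R}} (the "angle variation" of the flow field).
#'
#' @param x a `flow_grid` or numeric vector of angles (rad).
#' @return One-row tibble: `n`, `mean_theta`, `resultant_length`, `circ_sd`.
#' @export
orientation_stats <- function(x) {
  theta <- if (inherits(x, "flow_grid")) x$theta[x$occupied] else as.numeric(x)
  theta <- theta[!is.na(theta)]
  if (length(theta) == 0) abort("no occupied bins: orientation undefined")
  C <- mean(cos(theta)); S <- mean(sin(theta))
  R <- sqrt(C^2 + S^2)
  tibble(n = length(theta), mean_theta = atan2(S, C), resultant_length = R,
         circ_sd = sqrt(pmax(0, -2 * log(pmax(R, 1e-300)))))
}

#' Compare two orientation samples (two-sample Kolmogorov-Smirnov)
#'
#' Two-sided two-sample KS test on the orientation angles of two flow
#' fields, as used to compare flow-orderliness between brush layouts.
#'
#' @param theta_a,theta_b numeric angle samples (rad), or `flow_grid`s.
#' @return One-row tibble: `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
compare_orientations <- function(theta_a, theta_b) {
  ta <- if (inherits(theta_a, "flow_grid")) theta_a$theta[theta_a$occupied] else as.numeric(theta_a)
  tb <- if (inherits(theta_b, "flow_grid")) theta_b$theta[theta_b$occupied] else as.numeric(theta_b)
  ta <- ta[!is.na(ta)]; tb <- tb[!is.na(tb)]
  if (length(ta) < 2 || length(tb) < 2) abort("need at least 2 angles per sample")
  ht <- suppressWarnings(ks.test(ta, tb))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n_a = length(ta), n_b = length(tb))
}

#' Streamwise shear profile
#'
#' Bins the solvent `v_x` by height into `ny` equal slabs, differentiates by
#' central differences to the shear rate \eqn{\delta v_x/\delta y}
#' (one-sided at the ends), and, when a viscosity is supplied, forms the
#' shear stress \eqn{f = \gamma\, \delta v_x/\delta y}.
#'
#' @inheritParams bin_velocities
#' @param ny number of y slabs.
#' @param gamma dynamic viscosity (reduced); `NA` leaves stress unset.
#' @return Tibble with `y_mid`, `n`, `vx`, `shear_rate`, `stress`.
#' @export
shear_profile <- function(x, ny = 9, species = "water", window = NULL,
                          gamma = NA, box = NULL) {
  if (ny < 3) abort("need at least 3 y bins for finite differences")
  g <- bin_velocities(x, grid = c(1, ny, 1), species = species,
                      window = window, box = box)
  g <- g[order(g$y_mid), ]
  vx <- g$vx; yv <- g$y_mid
  nb <- length(vx)
  rate <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    lo <- max(1, i - 1); hi <- min(nb, i + 1)
    if (!is.na(vx[lo]) && !is.na(vx[hi]) && hi > lo)
      rate[i] <- (vx[hi] - vx[lo]) / (yv[hi] - yv[lo])
  }
  tibble(y_mid = yv, n = g$n, vx = vx, shear_rate = rate,
         stress = gamma * rate)
}

#' Time series of the mean shear rate in a height band
#'
#' Shear rate averaged over the band `region = c(y_lo, y_hi)` (the
#' published propulsion analysis uses the 25--30 r_c band below the
#' red-cell surface), one value per frame.
#'
#' @inheritParams shear_profile
#' @param region `c(y_lo, y_hi)` in r_c.
#' @return Tibble `time`, `shear_rate`.
#' @export
shear_rate_series <- function(x, region, ny = 9, species = "water",
                              box = NULL) {
  tb <- .as_traj_tbl(x)
  L <- .traj_box(x); if (anyNA(L)) L <- box
  times <- sort(unique(tb$time))
  out <- lapply(times, function(tt) {
    pr <- shear_profile(tb[tb$time == tt, ], ny = ny, species = species,
                        box = L)
    sel <- pr$y_mid >= region[1] & pr$y_mid <= region[2]
    tibble(time = tt, shear_rate = mean(pr$shear_rate[sel], na.rm = TRUE))
  })
  dplyr::bind_rows(out)
}

#' Calibrate the solvent viscosity
#'
#' Runs a small plane-Poiseuille micro-simulation of pure solvent: beads in
#' the bottom and top layers are frozen (rough no-slip walls), a uniform
#' body force `g` drives the interior fluid, and at stationarity the
#' momentum balance \eqn{\gamma\, v_x'' = -\rho g} holds pointwise. The
#' dynamic viscosity is extracted from the curvature of a quadratic fit to
#' the interior velocity profile, \eqn{\gamma = -\rho g / (2 c)} -- a
#' whole-field estimator that needs no wall-force measurement and no
#' channel-width convention. The standard water parameter set gives gamma
#' near 0.9 in reduced units.
#'
#' @param seed integer seed.
#' @param box box lengths (r_c); y is walled, frozen layers one r_c thick.
#' @param g body-force magnitude per bead (+x, reduced units).
#' @param time total span (tau); the first third is discarded as start-up.
#' @param params a [dpd_params()].
#' @return List with `gamma`, `curvature`, `v_max`, `profile` (tibble) and
#'   the run parameters.
#' @export
calibrate_viscosity <- function(seed = 1, box = c(12, 8, 6), g = 0.02,
                                time = 90, params = dpd_params()) {
  set.seed(seed)
  L <- box
  n <- round(3 * prod(L))
  pos <- matrix(runif(3 * n), n, 3) %*% diag(L)
  role <- rep(.ROLES[["free"]], n)
  frozen <- pos[, 2] < 1 | pos[, 2] > L[2] - 1
  role[frozen] <- .ROLES[["tethered"]]
  params$body_force <- c(g, 0, 0)
  sys <- dpd_system(pos = pos, species = "water", role = role,
                    box = dpd_box(L), params = params, seed = seed)
  sys <- thermalise(sys)
  burn <- dpd_advance(sys, time / 3)
  out <- dpd_advance(burn$system, 2 * time / 3, frame_every = 0.25)
  tb <- as_tibble(new_dpd_trajectory(out$frame_time, out$frames,
                                     sys$species, sys$role, NULL,
                                     sys$box, params))
  tb <- tb[tb$role == "free", ]
  pr <- shear_profile(tb, ny = max(12, round(2 * L[2])), box = L)
  inner <- pr[!is.na(pr$vx) & pr$y_mid > 1.5 & pr$y_mid < L[2] - 1.5, ]
  fit <- stats::lm(vx ~ y_mid + I(y_mid^2), data = inner)
  curv <- 2 * unname(stats::coef(fit)[3])
  if (!is.finite(curv) || curv >= 0)
    abort("flow not stationary: no Poiseuille curvature developed")
  rho <- 3
  list(gamma = -rho * g / curv, curvature = curv,
       v_max = max(inner$vx), profile = pr, g = g, box = L, seed = seed)
}

#' Mean per-bead lifting force on a chain
#'
#' Time- and bead-averaged y component of the non-bonded force exerted by
#' the solvent on the beads of a chain, from the force stream recorded by
#' [run_production()] (`record_chains`). A positive value is an upward,
#' wall-normal "lifting" force of the kind that maintains the cell-free
#' layer.
#'
#' @param run a `dpd_run` with a force stream, or a force-stream list.
#' @param chain chain id to average over; `NULL` uses all recorded beads.
#' @param window time window `c(from, to)` in tau or `"last:<span>"`.
#' @return List with `mean_fy` (per-bead mean), `per_bead` tibble and the
#'   sample count.
#' @export
lifting_force <- function(run, chain = NULL, window = NULL) {
  fs <- if (inherits(run, "dpd_run")) run$force_stream else run
  if (is.null(fs)) abort("no force stream recorded for this run")
  keep <- rep(TRUE, length(fs$time))
  if (!is.null(window)) {
    if (is.character(window) && grepl("^last:", window)) {
      span <- as.numeric(sub("^last:", "", window))
      keep <- fs$time > max(fs$time) - span + 1e-9
    } else keep <- fs$time >= window[1] & fs$time <= window[2]
  }
  beads <- fs$bead
  sel <- rep(TRUE, length(beads))
  if (!is.null(chain) && inherits(run, "dpd_run")) {
    ct <- run$trajectory$chains
    row <- ct[ct$chain == chain, ]
    if (nrow(row) == 0) abort("chain not found")
    sel <- beads %in% (row$first:row$last)
  }
  fy_cols <- seq(2, by = 3, length.out = length(beads))[sel]
  m <- fs$water[keep, fy_cols, drop = FALSE]
  per_bead <- tibble(bead = beads[sel], mean_fy = colMeans(m))
  list(mean_fy = mean(per_bead$mean_fy), per_bead = per_bead,
       n_samples = sum(keep))
}
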