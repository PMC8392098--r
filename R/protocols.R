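#' Timed events
#'
#' Events mutate the system at a prescribed production time:
#' `event_release_chain` displaces a chain rigidly and removes its tether
#' (the shedding protocol); `event_velocity_pulse` drives the tip beads of
#' the named chains at a fixed velocity for a finite duration, then frees
#' them (the activation protocol); `event_set_drive` changes the prescribed
#' velocity of all driven anchors.
#'
#' @param time trigger time in tau, measured from the start of production.
#' @param chain,chains chain id(s) as in the topology's chain table.
#' @param displacement rigid displacement applied at release (r_c).
#' @param velocity prescribed velocity (r_c/tau).
#' @param duration pulse length (tau).
#' @return An event object (`dpd_event`).
#' @name events
NULL

#' @rdname events
#' @export
event_release_chain <- function(time, chain, displacement = c(0, 0, 0)) {
  structure(list(kind = "release_chain", time = time, chain = chain,
                 displacement = as.numeric(displacement)),
            class = "dpd_event")
}

#' @rdname events
#' @export
event_velocity_pulse <- function(time, chains, velocity, duration) {
  structure(list(kind = "velocity_pulse", time = time, chains = chains,
                 velocity = as.numeric(velocity), duration = duration),
            class = "dpd_event")
}

#' @rdname events
#' @export
event_set_drive <- function(time, velocity) {
  structure(list(kind = "set_drive", time = time,
                 velocity = as.numeric(velocity)),
            class = "dpd_event")
}

.apply_event <- function(system, ev) {
  ch <- system$topology$chains
  if (ev$kind == "release_chain") {
    if (!ev$chain %in% ch$chain) abort("event references a missing chain")
    row <- ch[ch$chain == ev$chain, ]
    idx <- row$first:row$last
    system$pos[idx, ] <- sweep(system$pos[idx, , drop = FALSE], 2,
                               -ev$displacement)
    system$role[row$anchor] <- .ROLES[["free"]]
    system$drive[row$anchor, ] <- 0
  } else if (ev$kind == "velocity_pulse") {
    if (!all(ev$chains %in% ch$chain)) abort("event references a missing chain")
    tips <- ch$tip[match(ev$chains, ch$chain)]
    system$role[tips] <- .ROLES[["driven"]]
    system$drive[tips, ] <- matrix(ev$velocity, length(tips), 3, byrow = TRUE)
    system$vel[tips, ] <- system$drive[tips, , drop = FALSE]
  } else if (ev$kind == "set_drive") {
    driven <- system$role == .ROLES[["driven"]]
    system$drive[driven, ] <- matrix(ev$velocity, sum(driven), 3, byrow = TRUE)
    system$vel[driven, ] <- system$drive[driven, , drop = FALSE]
  } else abort(paste0("unknown event kind '", ev$kind, "'"))
  system
}

.end_pulse <- function(system, ev) {
  ch <- system$topology$chains
  tips <- ch$tip[match(ev$chains, ch$chain)]
  system$role[tips] <- .ROLES[["free"]]
  # freed beads carry the pulse velocity onward
  system$vel[tips, ] <- matrix(ev$velocity, length(tips), 3, byrow = TRUE)
  system$drive[tips, ] <- 0
  system
}

#' Equilibrate a built system
#'
#' Runs the thermostat with no drives active (driven anchors are held in
#' place). A warning is raised if the mean kinetic temperature over the last
#' fifth of the span misses the target by more than 5%.
#'
#' @param system a `dpd_system`, typically from [build_case()].
#' @param time span in tau; defaults to the case configuration
#'   (200 tau at full scale).
#' @return The equilibrated system (drives still inactive).
#' @export
equilibrate <- function(system, time = NULL) {
  if (is.null(time)) {
    time <- if (!is.null(system$config)) system$config$equil else 200
  }
  if (time <= 0) return(system)
  drive_saved <- system$drive
  system$drive[] <- 0
  out <- dpd_advance(system, time, sample_every = max(system$params$dt, time / 200))
  sys <- out$system
  sys$drive <- drive_saved
  nT <- length(out$temperature)
  if (nT > 0) {
    Tbar <- mean(out$temperature[max(1, floor(0.8 * nT)):nT])
    tgt <- sys$params$kBT
    if (abs(Tbar - tgt) > 0.05 * tgt)
      warn(sprintf("equilibration temperature %.3f misses target %.3f by >5%%",
                   Tbar, tgt))
    sys$equil_temperature <- Tbar
  }
  sys$force <- NULL  # production re-keys the noise stream from its own state
  sys
}

#' Run the production phase
#'
#' Applies the configured drive to the red-cell anchors from `t = 0`, fires
#' events at their trigger times, and collects frames, temperature samples
#' and (optionally) per-bead non-bonded force streams.
#'
#' @param system an equilibrated `dpd_system`.
#' @param time production span (tau); defaults to the case configuration.
#' @param events list of event objects; defaults to the case configuration.
#' @param frame_every frame output interval (tau).
#' @param record_chains chain ids whose beads' solvent forces are streamed
#'   (for lifting-force analysis), or `NULL`.
#' @param record_every force-stream sampling interval (tau); default one
#'   sample per tau (metrics are accumulated every DPD step internally).
#' @return A `dpd_run` object: the final system, a `dpd_trajectory`,
#'   temperature samples and the force stream.
#' @export
run_production <- function(system, time = NULL, events = NULL,
                           frame_every = NULL, record_chains = NULL,
                           record_every = 0.1) {
  cfg <- system$config
  if (is.null(time)) time <- if (!is.null(cfg)) cfg$production else 1600
  if (is.null(events)) events <- if (!is.null(cfg)) cfg$events else list()
  if (is.null(frame_every))
    frame_every <- if (!is.null(cfg)) cfg$frame_every else 1

  record_ids <- integer()
  if (!is.null(record_chains)) {
    ch <- system$topology$chains
    if (!all(record_chains %in% ch$chain))
      abort("record_chains references a missing chain")
    record_ids <- unlist(lapply(record_chains, function(ci) {
      row <- ch[ch$chain == ci, ]
      row$first:row$last
    }))
  }

  # expand pulses into start/stop boundaries
  bounds <- list()
  for (ev in events) {
    if (ev$time < 0 || ev$time > time)
      abort("event trigger outside the production window")
    bounds[[length(bounds) + 1]] <- list(time = ev$time, what = "start", ev = ev)
    if (ev$kind == "velocity_pulse")
      bounds[[length(bounds) + 1]] <-
        list(time = min(ev$time + ev$duration, time), what = "stop", ev = ev)
  }
  times <- vapply(bounds, function(b) b$time, numeric(1))
  ord <- order(times)
  bounds <- bounds[ord]; times <- times[ord]

  t0 <- system$time
  sys <- system
  frames <- list(); frame_time <- numeric()
  temps <- numeric(); temp_time <- numeric()
  recw <- list(); reca <- list(); rec_time <- numeric()

  run_seg <- function(span) {
    if (span <= 0) return(invisible())
    out <- dpd_advance(sys, span, frame_every = frame_every,
                       sample_every = max(sys$params$dt, span / 400),
                       record_every = if (length(record_ids)) record_every else 0,
                       record_ids = record_ids)
    sys <<- out$system
    frames <<- c(frames, out$frames)
    frame_time <<- c(frame_time, out$frame_time - t0)
    temps <<- c(temps, out$temperature)
    temp_time <<- c(temp_time, out$temperature_time - t0)
    if (length(record_ids)) {
      recw[[length(recw) + 1]] <<- out$rec_water
      reca[[length(reca) + 1]] <<- out$rec_all
      rec_time <<- c(rec_time, out$rec_time - t0)
    }
    invisible()
  }

  cursor <- 0
  for (b in seq_along(bounds)) {
    run_seg(times[b] - cursor)
    cursor <- times[b]
    sys <- if (bounds[[b]]$what == "start") .apply_event(sys, bounds[[b]]$ev)
           else .end_pulse(sys, bounds[[b]]$ev)
    sys$force <- NULL  # topology/roles changed: re-evaluate forces
  }
  run_seg(time - cursor)

  traj <- new_dpd_trajectory(
    time = frame_time, frames = frames, species = sys$species,
    role = sys$role, chains = sys$topology$chains, box = sys$box,
    params = sys$params, case = if (!is.null(cfg)) cfg$case else NA_character_)

  force_stream <- NULL
  if (length(record_ids)) {
    force_stream <- list(time = rec_time,
                         bead = record_ids,
                         water = do.call(rbind, recw),
                         total = do.call(rbind, reca))
  }

  structure(list(system = sys, trajectory = traj,
                 temperature = tibble(time = temp_time, kBT = temps),
                 force_stream = force_stream,
                 events = events, production = time,
                 config = cfg),
            class = "dpd_run")
}

#' @export
print.dpd_run <- function(x, ...) {
  cat("<dpd_run>", if (!is.null(x$config)) paste0("case ", x$config$case) else "",
      "-", length(x$trajectory$time), "frames over", format(x$production),
      "tau production\n")
  invisible(x)
}

#' Scaled-down case generator
#'
#' Convenience wrapper producing the reduced, geometrically similar variant
#' of a named case: `"mini"` (20 x 20 x 10 r_c^3, 20-bead chains, 20 + 60
#' tau, ~12,000 beads) or `"micro"` (10 x 6 x 4 r_c^3, 8-bead chains,
#' 5 + 20 tau, 720 beads). Ratios to the full geometry are preserved
#' (anchor separation ~1.1 contour lengths, brush interdigitation ~0.9
#' contour lengths, printed drive speeds and density); at micro scale the
#' anchor spacings tile the periodic x axis exactly, so the brush is
#' uniform through the boundary.
#'
#' @param case case id.
#' @param scale `"mini"` or `"micro"`.
#' @param seed integer seed.
#' @param ... overrides passed to [case_config()].
#' @return A `case_config`.
#' @export
make_mini_case <- function(case = "A", scale = c("mini", "micro"), seed = 1L, ...) {
  scale <- match.arg(scale)
  case_config(case, scale = scale, seed = seed, ...)
}
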