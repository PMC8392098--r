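#' Trajectory container
#'
#' A run's saved frames (positions and velocities at a fixed interval) with
#' the per-bead species/role tags, the chain table, box and parameters.
#' Time is measured from the start of production. Convert to a tidy tibble
#' (one row per bead per frame) with [as_tibble()]; all analysis functions
#' accept either form.
#'
#' @param time frame times (tau), strictly increasing.
#' @param frames list of N x 6 matrices (x, y, z, vx, vy, vz).
#' @param species,role integer per-bead codes.
#' @param chains chain table (tibble) or `NULL`.
#' @param box a [dpd_box()].
#' @param params a [dpd_params()].
#' @param case case id or `NA`.
#' @return A `dpd_trajectory`.
#' @export
new_dpd_trajectory <- function(time, frames, species, role, chains, box,
                               params, case = NA_character_) {
  stopifnot(length(time) == length(frames))
  if (length(time) > 1) stopifnot(all(diff(time) > 0))
  n <- if (length(frames)) nrow(frames[[1]]) else length(species)
  for (f in frames) stopifnot(nrow(f) == n, ncol(f) == 6)
  structure(list(time = time, frames = frames, species = species,
                 role = role, chains = chains, box = box, params = params,
                 case = case),
            class = "dpd_trajectory")
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat("<dpd_trajectory>", length(x$time), "frames,",
      if (length(x$frames)) nrow(x$frames[[1]]) else 0, "beads",
      if (!is.na(x$case)) paste0("(case ", x$case, ")") else "", "\n")
  invisible(x)
}

.chain_map <- function(n, chains) {
  chain_of <- rep(NA_integer_, n)
  label_of <- rep(NA_character_, n)
  if (!is.null(chains)) {
    for (i in seq_len(nrow(chains))) {
      idx <- chains$first[i]:chains$last[i]
      chain_of[idx] <- chains$chain[i]
      label_of[idx] <- chains$label[i]
    }
  }
  list(chain = chain_of, label = label_of)
}

#' @export
as_tibble.dpd_trajectory <- function(x, ...) {
  if (length(x$frames) == 0)
    return(tibble(time = numeric(), id = integer(), species = character(),
                  role = character(), chain = integer(), label = character(),
                  x = numeric(), y = numeric(), z = numeric(),
                  vx = numeric(), vy = numeric(), vz = numeric()))
  n <- nrow(x$frames[[1]])
  cm <- .chain_map(n, x$chains)
  per_frame <- function(i) {
    f <- x$frames[[i]]
    tibble(time = x$time[i], id = seq_len(n),
           species = names(.SPECIES)[x$species + 1L],
           role = names(.ROLES)[x$role + 1L],
           chain = cm$chain, label = cm$label,
           x = f[, 1], y = f[, 2], z = f[, 3],
           vx = f[, 4], vy = f[, 5], vz = f[, 6])
  }
  dplyr::bind_rows(lapply(seq_along(x$frames), per_frame))
}

.as_traj_tbl <- function(x) {
  if (inherits(x, "dpd_run")) x <- x$trajectory
  if (inherits(x, "dpd_trajectory")) return(as_tibble(x))
  if (is.data.frame(x)) {
    need <- c("time", "id", "x", "y", "z", "vx", "vy", "vz")
    miss <- setdiff(need, names(x))
    if (length(miss))
      abort(paste0("trajectory table is missing column(s): ",
                   paste(miss, collapse = ", ")))
    return(x)
  }
  abort("expected a dpd_run, dpd_trajectory or tidy trajectory data frame")
}

.traj_chains <- function(x) {
  if (inherits(x, "dpd_run")) return(x$trajectory$chains)
  if (inherits(x, "dpd_trajectory")) return(x$chains)
  NULL
}

# ---------------------------------------------------------------------------
# XYZ dialect

#' Write / read extended XYZ trajectories
#'
#' Plain-text XYZ with columns `species x y z vx vy vz`; one block per frame
#' with the time in the comment line. Lossless to the written precision.
#'
#' @param traj a `dpd_trajectory` (or `dpd_run`).
#' @param path file path.
#' @param digits significant digits written.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` returns a tidy
#'   tibble (one row per bead per frame).
#' @export
write_xyz <- function(traj, path, digits = 10) {
  if (inherits(traj, "dpd_run")) traj <- traj$trajectory
  con <- file(path, "w")
  on.exit(close(con))
  n <- if (length(traj$frames)) nrow(traj$frames[[1]]) else 0
  sp <- names(.SPECIES)[traj$species + 1L]
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%.10g", traj$time[i]), con)
    lines <- sprintf("%s %.*g %.*g %.*g %.*g %.*g %.*g", sp,
                     digits, f[, 1], digits, f[, 2], digits, f[, 3],
                     digits, f[, 4], digits, f[, 5], digits, f[, 6])
    writeLines(lines, con)
  }
  if (length(traj$frames) == 0) {
    writeLines("0", con)
    writeLines("time=0 (empty trajectory)", con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list(); i <- 1; frame <- 0
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      abort(sprintf("malformed XYZ header at line %d", i))
    n <- as.integer(lines[i])
    tm <- sub(".*time=([-0-9.eE+]+).*", "\\1", lines[i + 1])
    tval <- suppressWarnings(as.numeric(tm))
    if (is.na(tval)) tval <- frame
    if (i + 1 + n > length(lines))
      abort(sprintf("truncated XYZ frame starting at line %d", i))
    if (n > 0) {
      frame <- frame + 1
      body <- lines[(i + 2):(i + 1 + n)]
      parts <- strsplit(trimws(body), "\\s+")
      ncol <- lengths(parts)
      if (any(ncol < 7))
        abort(sprintf("XYZ frame at line %d: expected 7 columns, found %d",
                      i, min(ncol)))
      m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:7))), ncol = 6,
                  byrow = TRUE)
      out[[frame]] <- tibble(time = tval, id = seq_len(n),
                             species = vapply(parts, `[`, "", 1),
                             x = m[, 1], y = m[, 2], z = m[, 3],
                             vx = m[, 4], vy = m[, 5], vz = m[, 6])
    }
    i <- i + 2 + n
  }
  dplyr::bind_rows(out)
}

# ---------------------------------------------------------------------------
# LAMMPS dump dialect (text)

#' Write / read LAMMPS-dump text trajectories
#'
#' The `ITEM:`-structured dump dialect with columns
#' `id type x y z vx vy vz`; species map to numeric types
#' (water 1, endothelial bead 2, red-cell bead 3). Timesteps are written as
#' `round(time / dt)`.
#'
#' @inheritParams write_xyz
#' @param dt timestep used to convert times to integer step counts.
#' @export
write_lammps_dump <- function(traj, path, digits = 10, dt = NULL) {
  if (inherits(traj, "dpd_run")) traj <- traj$trajectory
  if (is.null(dt)) dt <- traj$params$dt
  con <- file(path, "w")
  on.exit(close(con))
  n <- if (length(traj$frames)) nrow(traj$frames[[1]]) else 0
  L <- traj$box$L
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(c("ITEM: TIMESTEP", as.character(round(traj$time[i] / dt)),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp ff pp",
                 sprintf("0 %.10g", L[1]), sprintf("0 %.10g", L[2]),
                 sprintf("0 %.10g", L[3]),
                 "ITEM: ATOMS id type x y z vx vy vz"), con)
    lines <- sprintf("%d %d %.*g %.*g %.*g %.*g %.*g %.*g",
                     seq_len(n), traj$species + 1L,
                     digits, f[, 1], digits, f[, 2], digits, f[, 3],
                     digits, f[, 4], digits, f[, 5], digits, f[, 6])
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_lammps_dump
#' @export
read_lammps_dump <- function(path, dt = 0.001) {
  lines <- readLines(path)
  out <- list(); i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      abort(sprintf("malformed dump: expected 'ITEM: TIMESTEP' at line %d", i))
    step <- as.numeric(lines[i + 1])
    if (!startsWith(lines[i + 2], "ITEM: NUMBER OF ATOMS"))
      abort(sprintf("malformed dump: expected 'ITEM: NUMBER OF ATOMS' at line %d", i + 2))
    n <- as.integer(lines[i + 3])
    j <- i + 4
    if (!startsWith(lines[j], "ITEM: BOX BOUNDS"))
      abort(sprintf("malformed dump: expected 'ITEM: BOX BOUNDS' at line %d", j))
    j <- j + 4
    if (!startsWith(lines[j], "ITEM: ATOMS"))
      abort(sprintf("malformed dump: expected 'ITEM: ATOMS' at line %d", j))
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[j]), "\\s+")[[1]]
    need <- c("id", "type", "x", "y", "z", "vx", "vy", "vz")
    miss <- setdiff(need, cols)
    if (length(miss))
      abort(paste0("dump frame at line ", i, " missing column(s): ",
                   paste(miss, collapse = ", ")))
    if (j + n > length(lines))
      abort(sprintf("truncated dump frame starting at line %d", i))
    body <- lines[(j + 1):(j + n)]
    parts <- strsplit(trimws(body), "\\s+")
    m <- matrix(as.numeric(unlist(parts)), nrow = n, byrow = TRUE)
    colnames(m) <- cols
    tb <- as_tibble(as.data.frame(m))
    tb <- tb[order(tb$id), ]
    tb$time <- step * dt
    out[[length(out) + 1]] <- tb[, c("time", need,
                                     setdiff(cols, need))]
    i <- j + n + 1
  }
  dplyr::bind_rows(out)
}

# ---------------------------------------------------------------------------
# metrics tables

#' Write / read tidy metrics tables
#'
#' One row per (time, chain) or (time, bin) observation; CSV with a
#' `#`-prefixed JSON header carrying a schema version, the case id and seed
#' for provenance.
#'
#' @param table data frame of metrics.
#' @param path file path (`.csv`).
#' @param meta named list merged into the provenance header.
#' @export
write_metrics <- function(table, path, meta = list()) {
  hdr <- c(list(schema = "glycodpd-metrics-1"), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  first <- readLines(path, n = 1)
  meta <- NULL
  if (startsWith(first, "# "))
    meta <- jsonlite::fromJSON(sub("^# ", "", first))
  tb <- as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(tb, "meta") <- meta
  tb
}

# ---------------------------------------------------------------------------
# case configs on disk

#' Write / read case configurations as YAML
#'
#' Field-for-field serialisation of a [case_config()]; events are stored by
#' kind and parameters.
#'
#' @param config a `case_config`.
#' @param path file path (`.yml`).
#' @export
write_case_config <- function(config, path) {
  x <- unclass(config)
  x$events <- lapply(x$events, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_case_config
#' @export
read_case_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$events <- lapply(x$events, function(e) {
    structure(e, class = "dpd_event")
  })
  for (nm in c("L", "n_eg", "beads", "n_rbc", "seed"))
    if (!is.null(x[[nm]])) x[[nm]] <- if (nm == "L") as.numeric(x[[nm]]) else as.integer(x[[nm]])
  class(x) <- "case_config"
  x
}
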