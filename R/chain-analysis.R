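#' Tip deflection of tethered chains
#'
#' Streamwise tip displacement \eqn{\Delta x(t) = x_{tip}(t) -
#' x_{tip}(t_{ref})} (and the height change \eqn{\Delta y}) of each tethered
#' chain's free-end bead, relative to the reference frame (default: the
#' first saved frame, i.e. the end of equilibration). Periodic x crossings
#' are unwrapped before differencing.
#'
#' @param x a `dpd_run`, `dpd_trajectory` or tidy trajectory tibble.
#' @param chains chain ids; default all endothelial (`"EG"`) chains.
#' @param reference_time reference frame time; default the earliest frame.
#' @return Tibble with columns `time`, `chain`, `dx`, `dy` and `released`
#'   (flagging chains whose tether was removed: their tip is tracked but the
#'   deflection origin no longer anchors them).
#' @export
tip_deflection <- function(x, chains = NULL, reference_time = NULL) {
  ct <- .traj_chains(x)
  tb <- .as_traj_tbl(x)
  Lx <- .traj_box(x)[1]
  if (is.null(chains)) chains <- .default_chains(tb, ct)
  if (length(chains) == 0) abort("no chains to analyse")
  tips <- .tip_ids(tb, ct, chains)
  sub <- tb[tb$id %in% tips$tip, c("time", "id", "x", "y", "role")]
  sub$chain <- tips$chain[match(sub$id, tips$tip)]
  if (is.null(reference_time)) reference_time <- min(sub$time)
  released <- .released_chains(tb, ct, chains)
  sub |>
    dplyr::group_by(.data$chain) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::mutate(xu = .unwrap(.data$x, Lx)) |>
    dplyr::mutate(dx = .data$xu - .data$xu[.data$time == reference_time][1],
                  dy = .data$y - .data$y[.data$time == reference_time][1]) |>
    dplyr::ungroup() |>
    dplyr::mutate(released = .data$chain %in% released) |>
    dplyr::select("time", "chain", "dx", "dy", "released")
}

.traj_box <- function(x) {
  if (inherits(x, "dpd_run")) return(x$trajectory$box$L)
  if (inherits(x, "dpd_trajectory")) return(x$box$L)
  rep(NA_real_, 3)
}

# unwrap a chain's bead coordinates along its backbone (periodic x, z)
.unwrap_chain <- function(m, L) {
  if (anyNA(L) || nrow(m) < 2) return(m)
  for (k in c(1, 3)) {
    d <- diff(m[, k])
    d <- d - L[k] * round(d / L[k])
    m[, k] <- c(m[1, k], m[1, k] + cumsum(d))
  }
  m
}

.default_chains <- function(tb, ct) {
  if (!is.null(ct)) return(ct$chain[ct$label == "EG"])
  if ("label" %in% names(tb)) return(sort(unique(tb$chain[tb$label == "EG"])))
  sort(unique(tb$chain[!is.na(tb$chain)]))
}

.tip_ids <- function(tb, ct, chains) {
  if (!is.null(ct)) {
    ct2 <- ct[ct$chain %in% chains, ]
    return(tibble(chain = ct2$chain, tip = ct2$tip))
  }
  tb |> dplyr::filter(.data$chain %in% chains) |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(tip = max(.data$id), .groups = "drop")
}

.released_chains <- function(tb, ct, chains) {
  if (is.null(ct)) return(integer())
  ct2 <- ct[ct$chain %in% chains, ]
  anchors <- ct2$anchor
  roles <- tb$role[match(anchors, tb$id)]
  ct2$chain[!is.na(roles) & roles == "free" & ct2$label == "EG"]
}

# unwrap periodic x coordinate of a single bead time series
.unwrap <- function(x, L) {
  if (is.na(L) || length(x) < 2) return(x)
  d <- diff(x)
  d <- d - L * round(d / L)
  c(x[1], x[1] + cumsum(d))
}

#' Relative deflection averaged over chains
#'
#' \eqn{\Delta x / l_0}, the tip deflection normalised by the contour
#' length, averaged over the selected chains at each frame. For fast-drive
#' analyses restrict to the central chains (`central_only = TRUE` picks the
#' middle two by anchor position) to avoid periodic-image artefacts.
#'
#' @inheritParams tip_deflection
#' @param central_only use only the two central chains.
#' @param l0 contour length override when `x` is a plain tibble without a
#'   chain table.
#' @param each return per-chain series instead of the chain average.
#' @return Tibble with `time` and `rel_deflection` (and `chain` when
#'   `each = TRUE`).
#' @export
relative_deflection <- function(x, chains = NULL, central_only = FALSE,
                                reference_time = NULL, l0 = NULL,
                                each = FALSE) {
  ct <- .traj_chains(x)
  tb <- .as_traj_tbl(x)
  if (is.null(chains)) chains <- .default_chains(tb, ct)
  if (length(chains) == 0) abort("no chains to analyse")
  if (central_only) {
    if (!is.null(ct)) {
      eg <- ct[ct$chain %in% chains, ]
      eg <- eg[order(eg$anchor_x), ]
    } else {
      eg <- tibble(chain = sort(chains))
    }
    m <- nrow(eg)
    chains <- eg$chain[c(ceiling(m / 2), ceiling(m / 2) + 1)]
    chains <- chains[!is.na(chains)]
  }
  defl <- tip_deflection(x, chains = chains, reference_time = reference_time)
  if (is.null(l0)) {
    if (is.null(ct)) abort("supply l0 when passing a plain trajectory table")
    l0v <- setNames(ct$l0, ct$chain)
    defl$rel <- defl$dx / l0v[as.character(defl$chain)]
  } else {
    defl$rel <- defl$dx / l0
  }
  if (each)
    return(dplyr::select(defl, "time", "chain", rel_deflection = "rel"))
  defl |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(rel_deflection = mean(.data$rel), .groups = "drop")
}

#' Root-mean-square deviation between two chain configurations
#'
#' Deformation measure between two structures of the same chain:
#' \deqn{RMSD = \left(\frac{\sum_i w_i \lVert x_i - y_i\rVert^2}
#'   {N_b \sum_i w_i}\right)^{1/2}}
#' The default (`form = "printed"`) carries the extra \eqn{N_b} in the
#' denominator; `form = "standard"` uses the conventional
#' \eqn{\sum w_i} normalisation (the two differ by a factor
#' \eqn{\sqrt{N_b}}; orderings between cases are unaffected).
#'
#' @param a,b N x 3 coordinate matrices of the same chain.
#' @param weights per-bead weights; default uniform.
#' @param form `"printed"` or `"standard"`.
#' @return Non-negative scalar.
#' @examples
#' a <- matrix(0, 60, 3); b <- a; b[1, 1] <- 1
#' chain_rmsd(a, b)                      # 1/60
#' chain_rmsd(a, b, form = "standard")   # 1/sqrt(60)
#' @export
chain_rmsd <- function(a, b, weights = NULL, form = c("printed", "standard")) {
  form <- match.arg(form)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) abort("mismatched bead counts")
  n <- nrow(a)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  ss <- sum(weights * rowSums((a - b)^2))
  denom <- if (form == "printed") n * sum(weights) else sum(weights)
  sqrt(ss / denom)
}

#' Windowed consecutive-frame RMSD
#'
#' Per-chain RMSD between consecutive saved frames, averaged within fixed
#' windows (default 100 tau at full scale) and across the selected chains.
#'
#' @inheritParams tip_deflection
#' @param window window length (tau); must be at least the frame interval.
#' @param weights,form passed to [chain_rmsd()].
#' @return Tibble with `window_start`, `time` (window midpoint), `rmsd` and
#'   `n_pairs`.
#' @export
windowed_rmsd <- function(x, chains = NULL, window = 100, weights = NULL,
                          form = c("printed", "standard")) {
  form <- match.arg(form)
  ct <- .traj_chains(x)
  tb <- .as_traj_tbl(x)
  if (is.null(chains)) chains <- .default_chains(tb, ct)
  if (length(chains) == 0) abort("no chains to analyse")
  times <- sort(unique(tb$time))
  if (length(times) < 2) abort("need at least two frames")
  if (window < min(diff(times)))
    abort("window shorter than the frame interval")
  L <- .traj_box(x)
  sub <- tb[!is.na(tb$chain) & tb$chain %in% chains, ]
  sub <- sub[order(sub$time, sub$chain, sub$id), ]
  per <- sub |>
    dplyr::group_by(.data$chain) |>
    dplyr::group_modify(function(d, key) {
      ts <- sort(unique(d$time))
      m <- matrix(c(d$x, d$y, d$z), ncol = 3)
      nb <- nrow(d) / length(ts)
      slice <- function(k)
        .unwrap_chain(m[((k - 1) * nb + 1):(k * nb), , drop = FALSE], L)
      prev <- slice(1)
      vals <- vapply(seq_len(length(ts) - 1), function(k) {
        cur <- slice(k + 1)
        v <- chain_rmsd(prev, cur, weights = weights, form = form)
        prev <<- cur
        v
      }, numeric(1))
      tibble(time = ts[-1], rmsd = vals)
    }) |>
    dplyr::ungroup()
  t0 <- min(per$time)
  per$window_start <- t0 + floor((per$time - t0 - 1e-12) / window) * window
  per |>
    dplyr::group_by(.data$window_start) |>
    dplyr::summarise(time = .data$window_start[1] + window / 2,
                     rmsd = mean(.data$rmsd),
                     n_pairs = dplyr::n(), .groups = "drop")
}

#' Interface curve through the chain tips
#'
#' Cubic interpolating spline through the tip `(x, y)` points ordered by
#' anchor position, tracing the free surface of the brush. Falls back to
#' lower order (with a warning) below 4 tips.
#'
#' @param tips data frame with columns `x` and `y` (tip coordinates), in
#'   anchor order or orderable by `x`.
#' @param n_out number of curve samples.
#' @return Tibble with `x`, `y` samples; the input knots are interpolated
#'   exactly.
#' @export
interface_spline <- function(tips, n_out = 100) {
  stopifnot(all(c("x", "y") %in% names(tips)))
  ord <- order(tips$x)
  xs <- tips$x[ord]; ys <- tips$y[ord]
  if (anyDuplicated(xs)) abort("tip x positions are not strictly monotone")
  if (length(xs) < 2) abort("need at least 2 tips")
  if (length(xs) < 4)
    warn("fewer than 4 tips: spline degrades to lower order")
  f <- splinefun(xs, ys, method = "natural")
  xg <- seq(min(xs), max(xs), length.out = n_out)
  tibble(x = xg, y = f(xg))
}

#' Settling time of a deflection series
#'
#' First time after which the series stays within `tol` of its final
#' plateau (the mean of the trailing fraction). Mirrors the cantilever-beam
#' picture in which the time to the first equilibrated deflection scales
#' with the squared contour length.
#'
#' @param time,x the series.
#' @param tol absolute tolerance band; default twice the standard deviation
#'   of the plateau segment.
#' @param plateau_frac trailing fraction used to estimate the plateau.
#' @return Scalar time, or `NA` (with a warning) if the series has not
#'   plateaued.
#' @export
settling_time <- function(time, x, tol = NULL, plateau_frac = 0.25) {
  stopifnot(length(time) == length(x), length(x) >= 4)
  ord <- order(time)
  time <- time[ord]; x <- x[ord]
  n <- length(x)
  ip <- max(1, floor((1 - plateau_frac) * n) + 1)
  plateau <- mean(x[ip:n])
  if (is.null(tol)) tol <- 2 * sd(x[ip:n])
  # plateau check: the preceding quarter must already be commensurate
  if (sd(x[ip:n]) > 0 && n >= 8) {
    prev <- x[max(1, ip - (n - ip + 1)):(ip - 1)]
    if (length(prev) > 1 && abs(mean(prev) - plateau) > 4 * tol + 4 * sd(x[ip:n])) {
      warn("series has not plateaued; settling time undefined")
      return(NA_real_)
    }
  }
  out <- which(abs(x - plateau) > tol)
  if (length(out) == 0) return(time[1])
  if (max(out) == n) {
    warn("series has not plateaued; settling time undefined")
    return(NA_real_)
  }
  time[max(out) + 1]
}
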