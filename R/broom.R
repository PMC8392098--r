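#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-chain summary of a run
#'
#' One row per chain: mean and final tip deflection, final relative
#' deflection, and the mean consecutive-frame RMSD over the run.
#'
#' @param x a `dpd_run`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.dpd_run <- function(x, ...) {
  ct <- x$trajectory$chains
  eg <- ct$chain[ct$label == "EG"]
  defl <- tip_deflection(x, chains = ct$chain)
  rmsd <- windowed_rmsd(x, chains = if (length(eg)) eg else ct$chain,
                        window = max(diff(sort(unique(x$trajectory$time)))))
  per <- defl |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(mean_dx = mean(.data$dx),
                     final_dx = .data$dx[which.max(.data$time)],
                     final_dy = .data$dy[which.max(.data$time)],
                     released = any(.data$released), .groups = "drop")
  per$label <- ct$label[match(per$chain, ct$chain)]
  per$l0 <- ct$l0[match(per$chain, ct$chain)]
  per$final_rel_dx <- per$final_dx / per$l0
  per$mean_rmsd <- mean(rmsd$rmsd)
  per[, c("chain", "label", "l0", "mean_dx", "final_dx", "final_rel_dx",
          "final_dy", "released", "mean_rmsd")]
}

#' One-row summary of a run
#'
#' @param x a `dpd_run`.
#' @param ... unused.
#' @return A tibble with bead/chain counts, spans and the mean production
#'   kinetic temperature.
#' @export
glance.dpd_run <- function(x, ...) {
  ct <- x$trajectory$chains
  tibble(case = if (!is.null(x$config)) x$config$case else NA_character_,
         n_beads = length(x$trajectory$species),
         n_chains = if (!is.null(ct)) nrow(ct) else 0L,
         n_frames = length(x$trajectory$time),
         production = x$production,
         mean_kBT = mean(x$temperature$kBT),
         n_events = length(x$events))
}

#' @export
tidy.flow_grid <- function(x, ...) {
  as_tibble(x[x$occupied, c("ix", "iy", "iz", "x_mid", "y_mid", "z_mid",
                            "n", "vx", "vy", "vz", "speed", "theta")])
}
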