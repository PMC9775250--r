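#' Plot a simulated trajectory
#'
#' Facets the seven model species over time (solid lines), overlaying the
#' smoothed measured total of each species' conservation group as a dashed
#' line (S over the SigB forms, AS over the RsbW forms, AAS over the RsbV
#' forms).  Phosphatase inputs sit on their own panels because their scale
#' is two orders of magnitude below the operon genes.
#'
#' @param object a `sigb_trajectory`.
#' @param species character vector of species panels to keep (default all).
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sigb_trajectory <- function(object, species = NULL, ...) {
  species <- species %||% .sigb_species
  sim <- tidy(object) |>
    dplyr::filter(.data$species %in% !!species)
  totals <- trajectory_total_overlays(object) |>
    dplyr::filter(.data$species %in% !!species)
  ggplot2::ggplot(sim, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(data = totals, linetype = "dashed",
                       colour = "grey30") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "expression intensity (a.u.)",
                  title = object$meta$run_label %||% "trajectory",
                  subtitle = "solid: model, dashed: measured group total")
}

# Dashed-overlay table: the measured total of each species' group,
# shifted to time-zero origin to match the zero-initial-state convention.
trajectory_total_overlays <- function(traj) {
  g <- traj$forcing$grid
  group_total <- list(
    SigB_f = g$S - g$S[1], W2SigB = g$S - g$S[1],
    W2_f = g$AS - g$AS[1], W2V = g$AS - g$AS[1], W2V2 = g$AS - g$AS[1],
    V_f = g$AAS - g$AAS[1], VP = g$AAS - g$AAS[1]
  )
  purrr::imap(group_total, function(v, sp) {
    tibble::tibble(time_min = g$time_min, species = sp, value = v)
  }) |> purrr::list_rbind()
}

#' Per-panel figure list for a trajectory report
#'
#' Builds the individual panels written by [render_trajectory_report()]:
#' one panel per model species (simulation solid, group total dashed) and
#' one per forcing input (S, AS, AAS, RsbU, RsbP).
#'
#' @param traj a `sigb_trajectory`.
#' @return Named list of 12 ggplot objects (7 species + 5 forcing panels).
#' @export
trajectory_plots <- function(traj) {
  stopifnot(inherits(traj, "sigb_trajectory"))
  totals <- trajectory_total_overlays(traj)
  species_panels <- lapply(.sigb_species, function(sp) {
    sim <- tibble::tibble(time_min = traj$states$time_min,
                          value = traj$states[[sp]])
    tot <- dplyr::filter(totals, .data$species == sp)
    ggplot2::ggplot(sim, ggplot2::aes(.data$time_min, .data$value)) +
      ggplot2::geom_line(data = dplyr::select(tot, -"species"),
                         linetype = "dashed", colour = "grey30") +
      ggplot2::geom_line(colour = "#2166ac") +
      ggplot2::labs(title = sp, x = "time (min)", y = "intensity (a.u.)")
  })
  names(species_panels) <- .sigb_species
  forcing_cols <- c("S", "AS", "AAS", "RsbU", "RsbP")
  forcing_panels <- lapply(forcing_cols, function(cl) {
    g <- traj$forcing$grid
    ggplot2::ggplot(tibble::tibble(time_min = g$time_min, value = g[[cl]]),
                    ggplot2::aes(.data$time_min, .data$value)) +
      ggplot2::geom_line(colour = "grey20") +
      ggplot2::labs(title = paste0("forcing ", cl), x = "time (min)",
                    y = "intensity (a.u.)")
  })
  names(forcing_panels) <- paste0("forcing_", forcing_cols)
  c(species_panels, forcing_panels)
}

#' Plot a perturbation scan
#'
#' Overlays the species time courses of every scan level, coloured by
#' level, faceted by species -- the standard dose-response panel layout
#' for this network.
#'
#' @param object a `sigb_scan`.
#' @param species species to facet (default the seven model species).
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sigb_scan <- function(object, species = NULL, ...) {
  species <- species %||% .sigb_species
  dat <- tidy(object) |>
    dplyr::filter(.data$species %in% !!species) |>
    dplyr::mutate(level = factor(.data$level))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_min, y = .data$value,
                                    colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "expression intensity (a.u.)",
                  colour = object$scan_name, title = object$scan_name)
}
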