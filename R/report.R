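#' Write a trajectory report to disk
#'
#' Deterministic presentation layer: writes the full tidy series table
#' (model species plus forcing) as CSV, a JSON run manifest capturing
#' everything that determines the numbers (constants, tolerances, grid
#' provenance, config hash, package version), and optionally the 12
#' per-panel figures of [trajectory_plots()] as PNG files.  No quantity is
#' computed here beyond axis scaling; every plotted number is present in
#' the CSV.
#'
#' @param traj a `sigb_trajectory` with at least one output time.
#' @param out_dir output directory (created if needed).
#' @param plots write PNG panels too (default `FALSE`, so headless runs
#'   need no graphics device).
#' @return Invisibly, the character vector of files written.
#' @export
render_trajectory_report <- function(traj, out_dir, plots = FALSE) {
  stopifnot(inherits(traj, "sigb_trajectory"))
  if (nrow(traj$states) == 0L) abort("Empty trajectory; nothing to report.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  csv <- file.path(out_dir, "trajectory.csv")
  readr::write_csv(tidy(traj), csv)
  files <- c(files, csv)

  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run_manifest(traj), manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest)

  if (plots) {
    panels <- trajectory_plots(traj)
    for (nm in names(panels)) {
      f <- file.path(out_dir, paste0(nm, ".png"))
      ggplot2::ggsave(f, panels[[nm]], width = 5, height = 4, dpi = 150)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Run manifest of a trajectory
#'
#' Collects the provenance needed to reproduce a run bit-identically
#' (timestamps aside): rate constants, solver tolerances, preprocessing
#' settings, run label, config hash and package version.
#'
#' @param traj a `sigb_trajectory`.
#' @return A named list, ready for JSON serialisation.
#' @export
run_manifest <- function(traj) {
  stopifnot(inherits(traj, "sigb_trajectory"))
  list(
    run_label = traj$meta$run_label %||% "run",
    config_hash = traj$meta$config_hash,
    constants = as.list(unclass(traj$constants)),
    rel_tol = traj$rel_tol,
    abs_tol = traj$abs_tol,
    grid_step_min = traj$forcing$step,
    smooth_window_min = traj$forcing$window,
    t_start = traj$forcing$t_start,
    t_end = traj$forcing$t_end,
    n_times = nrow(traj$states),
    package_version = as.character(utils::packageVersion("sigbswitch")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}
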