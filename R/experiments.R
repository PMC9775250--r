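#' Perturbation scans of the partner-switching network
#'
#' Three scans probe how the amount of free SigB is controlled:
#'
#' * `scan_phosphatase()` multiplies both phosphatase inputs (RsbU and
#'   RsbP) by each factor in `multipliers`, leaving everything else
#'   unchanged.  Raising phosphatase dose drains the phosphorylated RsbV
#'   pool and frees SigB, with diminishing returns at high dose.
#' * `scan_k5_ratio()` varies the dissociation-to-association ratio
#'   `k5m/k5p` of the SigB--anti-sigma binding reaction.  The forward
#'   constant `k5p` is held at its default and `k5m = ratio * k5p`
#'   (`vary = "forward"` instead holds `k5m` and moves `k5p`).  The
#'   default ratio is 5000.
#' * `scan_k6_ratio()` varies `k6m/k6p` of the SigB-displacement reaction
#'   the same way; the default ratio is 1.
#'
#' Each level re-runs the full simulation; levels are independent, so the
#' result does not depend on evaluation order.
#'
#' @param forcing a `forcing_set`.
#' @param constants baseline [sigb_constants()].
#' @param multipliers non-negative phosphatase dose multipliers
#'   (default `c(1, 5, 10)`; 1 is the measured dose).
#' @param ratios positive ratio levels (defaults `c(100, 2500, 50000)` for
#'   k5, `c(1, 100, 1e5)` for k6).
#' @param vary which constant of the pair moves to realise the ratio:
#'   `"reverse"` (default, forward constant fixed) or `"forward"`.
#' @param ... passed on to [run_simulation()] (tolerances).
#' @return A `sigb_scan`: list with `scan_name`, `levels`, `trajectories`
#'   (one `sigb_trajectory` per level) and `endpoints`, a tibble of
#'   end-of-course amounts of all seven species plus the total-to-free
#'   SigB ratio per level.  Methods: `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' \donttest{
#' fs <- synthetic_forcing(seed = 1)
#' scan <- scan_phosphatase(fs)
#' glance(scan)
#' }
#' @name sigb_scans
NULL

#' @rdname sigb_scans
#' @export
scan_phosphatase <- function(forcing, constants = sigb_constants(),
                             multipliers = c(1, 5, 10), ...) {
  if (any(multipliers < 0)) abort("Multipliers must be non-negative.")
  check_levels(multipliers)
  trajs <- purrr::map(multipliers, function(m) {
    f <- if (m == 1) forcing else scale_forcing(forcing, c("RsbU", "RsbP"), m)
    label_run(run_simulation(f, constants, ...),
              paste0("phosphatase_x", m))
  })
  new_scan("phosphatase", multipliers, trajs)
}

#' @rdname sigb_scans
#' @export
scan_k5_ratio <- function(forcing, constants = sigb_constants(),
                          ratios = c(100, 2500, 50000),
                          vary = c("reverse", "forward"), ...) {
  vary <- match.arg(vary)
  if (any(ratios <= 0)) abort("Ratios must be positive.")
  check_levels(ratios)
  trajs <- purrr::map(ratios, function(r) {
    k <- constants
    if (vary == "reverse") {
      k[["k5m"]] <- r * k[["k5p"]]
    } else {
      k[["k5p"]] <- k[["k5m"]] / r
    }
    label_run(run_simulation(forcing, k, ...), paste0("k5_ratio_", r))
  })
  new_scan("k5_ratio", ratios, trajs)
}

#' @rdname sigb_scans
#' @export
scan_k6_ratio <- function(forcing, constants = sigb_constants(),
                          ratios = c(1, 100, 1e5),
                          vary = c("reverse", "forward"), ...) {
  vary <- match.arg(vary)
  if (any(ratios <= 0)) abort("Ratios must be positive.")
  check_levels(ratios)
  trajs <- purrr::map(ratios, function(r) {
    k <- constants
    if (vary == "reverse") {
      k[["k6m"]] <- r * k[["k6p"]]
    } else {
      k[["k6p"]] <- k[["k6m"]] / r
    }
    label_run(run_simulation(forcing, k, ...), paste0("k6_ratio_", r))
  })
  new_scan("k6_ratio", ratios, trajs)
}

check_levels <- function(levels) {
  if (length(levels) == 0L || is.unsorted(levels, strictly = TRUE)) {
    abort("Scan levels must be non-empty and strictly increasing.")
  }
}

label_run <- function(traj, label) {
  traj$meta$run_label <- label
  traj
}

new_scan <- function(scan_name, levels, trajectories) {
  endpoints <- purrr::map2(levels, trajectories, function(lv, tr) {
    ends <- dplyr::slice_tail(tr$states, n = 1)
    dplyr::bind_cols(
      tibble::tibble(level = lv),
      dplyr::select(ends, dplyr::all_of(.sigb_species)),
      tibble::tibble(
        total_to_free_sigb = attr(summarize_free_fraction(tr), "end_ratio")
      )
    )
  }) |> purrr::list_rbind()
  structure(
    list(scan_name = scan_name, levels = levels,
         trajectories = trajectories, endpoints = endpoints),
    class = "sigb_scan"
  )
}

#' @export
print.sigb_scan <- function(x, ...) {
  cat("<sigb_scan> '", x$scan_name, "' over levels ",
      paste(x$levels, collapse = ", "), "\n", sep = "")
  print(x$endpoints)
  invisible(x)
}

#' @describeIn sigb_scans all trajectories of the scan as one long tibble
#'   (`run_label` distinguishes levels) with a `level` column.
#' @param x a `sigb_scan`.
#' @exportS3Method generics::tidy
tidy.sigb_scan <- function(x, ...) {
  purrr::map2(x$levels, x$trajectories, function(lv, tr) {
    dplyr::mutate(tidy(tr), level = lv)
  }) |> purrr::list_rbind()
}

#' @describeIn sigb_scans the per-level endpoint table (end-of-course
#'   amounts of the seven species and the total-to-free SigB ratio).
#' @exportS3Method generics::glance
glance.sigb_scan <- function(x, ...) {
  dplyr::mutate(x$endpoints, scan_name = x$scan_name)
}
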