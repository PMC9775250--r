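#' Integrate the forced partner-switching network
#'
#' Solves the seven-species ODE system from the start to the end of the
#' forcing window with all initial amounts set to zero, using an adaptive
#' explicit Runge-Kutta pair of orders 2(3) (Bogacki-Shampine), and samples
#' the solution on the dense forcing grid.
#'
#' Zero initial states mean the conserved groupings track the measured
#' totals *relative to time zero*: at every output time
#' `SigB_f + W2SigB = S(t) - S(0)`, and analogously for the RsbW and RsbV
#' groupings (see [check_mass_balance()]).  The measured amounts present at
#' t = 0 are implicitly assigned to pools outside the model.
#'
#' @param forcing a `forcing_set` from [build_forcing()] or
#'   [synthetic_forcing()].
#' @param constants a [sigb_constants()] object.
#' @param rel_tol relative integration tolerance (default 1e-6).
#' @param abs_tol absolute tolerance in intensity units; default
#'   `1e-9 * max(forcing values)`.
#' @return A `sigb_trajectory`: list with `states` (tibble `time_min` +
#'   seven species columns), `forcing` (the forcing set), `constants`,
#'   tolerances and a `meta` list (run label, config hash).  Methods:
#'   [tidy.sigb_trajectory()], [glance.sigb_trajectory()],
#'   [autoplot.sigb_trajectory()].
#' @examples
#' \donttest{
#' traj <- run_simulation(synthetic_forcing(seed = 1))
#' glance(traj)
#' }
#' @export
run_simulation <- function(forcing, constants = sigb_constants(),
                           rel_tol = 1e-6, abs_tol = NULL) {
  stopifnot(inherits(forcing, "forcing_set"))
  fmax <- max(forcing$grid$S, forcing$grid$AS, forcing$grid$AAS,
              forcing$grid$RsbU, forcing$grid$RsbP)
  # short decimal so the value survives a JSON manifest round trip exactly
  abs_tol <- abs_tol %||% signif(1e-9 * max(fmax, 1), 3)
  if (rel_tol <= 0 || abs_tol <= 0) abort("Tolerances must be positive.")

  k <- unclass(constants)[c("k1p", "k1m", "k2p", "k2m", "k3p", "k4p",
                            "k5p", "k5m", "k6p", "k6m", "k7p")]
  g <- forcing$grid
  forcings <- list(
    cbind(g$time_min, g$RsbU), cbind(g$time_min, g$RsbP),
    cbind(g$time_min, g$dS), cbind(g$time_min, g$dAS),
    cbind(g$time_min, g$dAAS)
  )
  y0 <- setNames(numeric(7), .sigb_species)
  sol <- deSolve::ode(
    y = y0, times = g$time_min, func = "sigb_derivs",
    parms = as.numeric(k), dllname = "sigbswitch",
    initfunc = "sigb_initparms", initforc = "sigb_initforcs",
    forcings = forcings, fcontrol = list(method = "linear", rule = 2),
    method = deSolve::rkMethod("rk23bs"), rtol = rel_tol, atol = abs_tol,
    maxsteps = 5e5
  )
  states <- tibble::as_tibble(as.data.frame(unclass(sol)))
  names(states)[1] <- "time_min"
  if (nrow(states) < nrow(forcing$grid) ||
      any(!is.finite(as.matrix(states)))) {
    last_t <- if (nrow(states)) max(states$time_min[stats::complete.cases(states)]) else NA
    abort(paste0("Integration failed; last valid time ", last_t, " min."))
  }
  traj <- new_trajectory(states, forcing, constants, rel_tol, abs_tol,
                         meta = list(run_label = "baseline"))
  # integrity guard: an unconverged (e.g. step-starved) run shows up as a
  # gross violation of the structural conservation identities
  mb <- check_mass_balance(traj)
  if (max(mb$rel_error) > 0.02) {
    abort(paste0("Integration failed: conservation violated (max relative ",
                 "mass-balance error ", signif(max(mb$rel_error), 3),
                 "); try tighter tolerances."))
  }
  traj
}

new_trajectory <- function(states, forcing, constants, rel_tol, abs_tol,
                           meta = list()) {
  meta$config_hash <- rlang::hash(list(
    constants = unclass(constants), rel_tol = rel_tol, abs_tol = abs_tol,
    grid = forcing$grid, meta_label = meta$run_label
  ))
  structure(
    list(states = states, forcing = forcing, constants = constants,
         rel_tol = rel_tol, abs_tol = abs_tol, meta = meta),
    class = "sigb_trajectory"
  )
}

#' @export
print.sigb_trajectory <- function(x, ...) {
  cat("<sigb_trajectory> '", x$meta$run_label %||% "run", "': ",
      nrow(x$states), " output times over ",
      x$forcing$t_start, "-", x$forcing$t_end, " min\n", sep = "")
  ends <- dplyr::slice_tail(x$states, n = 1)
  cat("  end-of-course amounts:\n")
  print(round(unlist(ends[.sigb_species]), 2))
  invisible(x)
}

#' @describeIn run_simulation long tibble `time_min`, `species`, `value`,
#'   `run_label` covering the seven model species and the five forcing
#'   series (forcing species are suffixed `_total`, phosphatases bare).
#' @param x a `sigb_trajectory`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.sigb_trajectory <- function(x, ...) {
  states <- x$states |>
    tidyr::pivot_longer(-"time_min", names_to = "species",
                        values_to = "value")
  forcing <- x$forcing$grid |>
    dplyr::select("time_min", "S", "AS", "AAS", "RsbU", "RsbP") |>
    dplyr::rename(S_total = "S", AS_total = "AS", AAS_total = "AAS") |>
    tidyr::pivot_longer(-"time_min", names_to = "species",
                        values_to = "value")
  dplyr::bind_rows(states, forcing) |>
    dplyr::mutate(run_label = x$meta$run_label %||% "run")
}

#' @describeIn run_simulation one-row summary: end-of-course amounts of
#'   all seven species, the end-of-course total-to-free SigB ratio, and the
#'   worst relative mass-balance residual.
#' @exportS3Method generics::glance
glance.sigb_trajectory <- function(x, ...) {
  ends <- dplyr::slice_tail(x$states, n = 1)
  ratio <- summarize_free_fraction(x)
  mb <- check_mass_balance(x)
  dplyr::bind_cols(
    dplyr::select(ends, dplyr::all_of(.sigb_species)),
    tibble::tibble(
      total_to_free_sigb = attr(ratio, "end_ratio"),
      max_rel_balance_error = max(mb$rel_error),
      run_label = x$meta$run_label %||% "run"
    )
  )
}

#' Mass-balance residuals of a trajectory
#'
#' With zero initial amounts, exact integration would keep the three
#' conservation groupings equal to the change in the corresponding measured
#' total since time zero: `SigB_f + W2SigB` tracks `S(t) - S(0)`,
#' `2(W2_f + W2V + W2V2 + W2SigB)` tracks `AS(t) - AS(0)`, and
#' `V_f + W2V + 2 W2V2 + VP` tracks `AAS(t) - AAS(0)`.  The residuals
#' measure the solver error against this structural identity.
#'
#' @param traj a `sigb_trajectory`.
#' @return tibble with columns `time_min`, `grouping` (`S`/`AS`/`AAS`),
#'   `model`, `target`, `abs_error`, `rel_error` (absolute error over the
#'   peak magnitude of the grouping's target, floored at 1).
#' @export
check_mass_balance <- function(traj) {
  stopifnot(inherits(traj, "sigb_trajectory"))
  st <- traj$states
  g <- traj$forcing$grid
  groupings <- tibble::tibble(
    time_min = rep(st$time_min, 3),
    grouping = rep(c("S", "AS", "AAS"), each = nrow(st)),
    model = c(
      st$SigB_f + st$W2SigB,
      2 * (st$W2_f + st$W2V + st$W2V2 + st$W2SigB),
      st$V_f + st$W2V + 2 * st$W2V2 + st$VP
    ),
    target = c(
      g$S - g$S[1],
      g$AS - g$AS[1],
      g$AAS - g$AAS[1]
    )
  )
  groupings |>
    dplyr::group_by(.data$grouping) |>
    dplyr::mutate(
      abs_error = abs(.data$model - .data$target),
      rel_error = .data$abs_error / max(max(abs(.data$target)), 1)
    ) |>
    dplyr::ungroup()
}

#' Ratio of total to free SigB along a trajectory
#'
#' The measured SigB signal counts both free sigma factor and the
#' anti-sigma-bound pool; the regulatorily active amount is only the free
#' form.  This summary reports the per-time ratio of measured total
#' `S(t)` to simulated free `SigB_f(t)`; where the free amount does not
#' exceed the solver's absolute tolerance the ratio is reported as `NA`
#' (undefined), never infinite.
#'
#' @param traj a `sigb_trajectory`.
#' @return tibble with columns `time_min`, `S_total`, `SigB_f`,
#'   `total_to_free` and an attribute `end_ratio`, the headline
#'   end-of-course value.
#' @export
summarize_free_fraction <- function(traj) {
  stopifnot(inherits(traj, "sigb_trajectory"))
  if (nrow(traj$states) == 0L) abort("Empty trajectory.")
  out <- tibble::tibble(
    time_min = traj$states$time_min,
    S_total = traj$forcing$grid$S,
    SigB_f = traj$states$SigB_f,
    total_to_free = ifelse(SigB_f > traj$abs_tol, S_total / SigB_f, NA_real_)
  )
  attr(out, "end_ratio") <- out$total_to_free[nrow(out)]
  out
}
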