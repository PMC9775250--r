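#' Interpolate a sparse series onto a dense uniform grid
#'
#' Shape-preserving piecewise-cubic Hermite (pchip) interpolation of one
#' measured series onto a uniform grid running from the first to the last
#' measured time.  The interpolant passes through every measured point and,
#' being shape preserving, never overshoots the local data extrema -- the
#' property that makes it safe for noisy, strictly non-negative expression
#' intensities.
#'
#' @param series tibble with columns `time_min`, `value` (a single gene; a
#'   `gene` column, if present, is carried through), at least 2 points,
#'   strictly increasing times.
#' @param step grid step in minutes (default 1).
#' @return tibble with columns `gene` (if supplied), `time_min`, `value` on
#'   the uniform grid.
#' @export
interpolate_series <- function(series, step = 1) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    abort("`step` must be a single positive number of minutes.")
  }
  gene <- if ("gene" %in% names(series)) unique(series$gene) else NULL
  if (length(gene) > 1L) abort("interpolate_series() expects a single gene.")
  validate_series(dplyr::mutate(series, gene = gene %||% "series"))
  t0 <- series$time_min[1]
  t1 <- series$time_min[nrow(series)]
  grid <- seq(t0, t1, by = step)
  # guard against step not dividing the range: keep the last measured point
  if (tail(grid, 1) < t1 - 1e-9) grid <- c(grid, t1)
  vals <- pracma::pchip(series$time_min, series$value, grid)
  out <- tibble::tibble(time_min = grid, value = vals)
  if (!is.null(gene)) out <- dplyr::mutate(out, gene = gene, .before = 1)
  out
}

#' Smooth a dense series with a Gaussian-weighted moving average
#'
#' Convolves the series with a truncated Gaussian kernel of the given
#' window.  The kernel is truncated at half the window on either side and
#' its weights are renormalised near the boundaries rather than padding
#' with invented data, so constants are reproduced exactly everywhere and
#' the output never leaves the range of the input.
#'
#' The kernel standard deviation follows the Gaussian-window convention
#' `sigma = (n - 1) / 5` grid steps for a window of `n` samples.
#'
#' @param dense tibble with `time_min`, `value` on a uniform grid (output of
#'   [interpolate_series()]).
#' @param window smoothing window in minutes; must be at least one grid step.
#' @return tibble of the same shape with smoothed `value`.
#' @export
smooth_series <- function(dense, window = 15) {
  step <- grid_step(dense$time_min)
  if (!is.numeric(window) || length(window) != 1L || window < step) {
    abort("`window` must be a single number of at least one grid step.")
  }
  n_w <- max(1L, as.integer(round(window / step)))
  half <- n_w %/% 2L
  smoothed <- if (half == 0L) {
    dense$value
  } else {
    sigma <- (n_w - 1) / 5
    offsets <- -half:half
    w <- exp(-0.5 * (offsets / sigma)^2)
    x <- dense$value
    n <- length(x)
    vapply(seq_len(n), function(i) {
      j <- i + offsets
      keep <- j >= 1L & j <= n
      sum(w[keep] * x[j[keep]]) / sum(w[keep])
    }, numeric(1))
  }
  dplyr::mutate(dense, value = smoothed)
}

#' Differentiate a dense series by finite differences
#'
#' Attaches a `deriv` column: central differences at interior points and
#' second-order one-sided differences at both ends, so the scheme is exact
#' for polynomials up to degree two.
#'
#' @param dense tibble with `time_min`, `value` on a uniform grid of at
#'   least 3 points.
#' @return the input with a `deriv` column (intensity per minute).
#' @export
differentiate_series <- function(dense) {
  n <- nrow(dense)
  if (n < 3L) abort("Differentiation needs at least 3 points.")
  h <- grid_step(dense$time_min)
  x <- dense$value
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * h)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * h)
  dplyr::mutate(dense, deriv = d)
}

# Step of a uniform grid; errors if the grid is not uniform to 1e-9 min.
grid_step <- function(times) {
  if (length(times) < 2L) abort("Grid needs at least 2 points.")
  d <- diff(times)
  if (any(abs(d - d[1]) > 1e-9)) {
    abort("Series must be on a uniform time grid (within 1e-9 min).")
  }
  d[1]
}

#' Build the forcing set that drives the network ODEs
#'
#' Runs the full preprocessing pipeline -- pchip interpolation to a dense
#' uniform grid, Gaussian smoothing, finite-difference differentiation --
#' on the five measured inputs and packages them as the forcing of the
#' partner-switching ODE system: smoothed totals `S` (sigB), `AS` (rsbW),
#' `AAS` (rsbV) with their time-derivatives, and smoothed phosphatase
#' levels `RsbU`, `RsbP`.
#'
#' @param raw tibble with columns `gene`, `time_min`, `value` on the linear
#'   intensity scale containing the genes `sigB`, `rsbW`, `rsbV`, `rsbU`,
#'   `rsbP` (any order).
#' @param step dense grid step in minutes (default 1).
#' @param window Gaussian smoothing window in minutes (default 15).
#' @return A `forcing_set` object: the dense grid tibble plus continuous-
#'   time evaluators (piecewise linear between grid samples) used by the
#'   solver, and the time range `t_start`/`t_end`.
#' @seealso [forcing_eval()], [run_simulation()]
#' @export
build_forcing <- function(raw, step = 1, window = 15) {
  missing <- setdiff(names(.sigb_genes), unique(raw$gene))
  if (length(missing)) {
    abort(paste0("Forcing inputs missing gene(s): ",
                 paste(missing, collapse = ", ")))
  }
  dense <- purrr::map(names(.sigb_genes), function(g) {
    raw |>
      dplyr::filter(.data$gene == g) |>
      interpolate_series(step = step) |>
      smooth_series(window = window)
  })
  names(dense) <- unname(.sigb_genes)
  grid <- tibble::tibble(time_min = dense$S$time_min)
  for (sym in names(dense)) {
    if (!identical(dense[[sym]]$time_min, grid$time_min)) {
      abort("All five genes must be measured on the same time span.")
    }
    grid[[sym]] <- dense[[sym]]$value
  }
  for (sym in c("S", "AS", "AAS")) {
    grid[[paste0("d", sym)]] <- differentiate_series(dense[[sym]])$deriv
  }
  new_forcing_set(grid, step = step, window = window)
}

# Constructor shared by build_forcing() and the scan machinery.  rule = 2
# (constant extrapolation) keeps the evaluators defined when the adaptive
# solver probes marginally past t_end; user-facing evaluation goes through
# forcing_eval(), which enforces the range strictly.
new_forcing_set <- function(grid, step, window) {
  cols <- c("S", "AS", "AAS", "RsbU", "RsbP", "dS", "dAS", "dAAS")
  funs <- lapply(cols, function(cl) approxfun(grid$time_min, grid[[cl]], rule = 2))
  names(funs) <- cols
  structure(
    list(
      grid = grid,
      funs = funs,
      t_start = grid$time_min[1],
      t_end = tail(grid$time_min, 1),
      step = step,
      window = window
    ),
    class = "forcing_set"
  )
}

#' Evaluate a forcing set at arbitrary times
#'
#' Piecewise-linear evaluation of the dense forcing grid (values and stored
#' derivatives).  Times outside the measured range are an error; the model
#' is only defined where data exist.
#'
#' @param forcing a `forcing_set` from [build_forcing()].
#' @param t numeric vector of times in minutes within
#'   `[forcing$t_start, forcing$t_end]`.
#' @return tibble with columns `time_min`, `S`, `AS`, `AAS`, `RsbU`,
#'   `RsbP`, `dS`, `dAS`, `dAAS`.
#' @export
forcing_eval <- function(forcing, t) {
  stopifnot(inherits(forcing, "forcing_set"))
  if (any(t < forcing$t_start - 1e-9) || any(t > forcing$t_end + 1e-9)) {
    abort(paste0("Forcing requested outside [", forcing$t_start, ", ",
                 forcing$t_end, "] min."))
  }
  out <- tibble::tibble(time_min = t)
  for (cl in names(forcing$funs)) out[[cl]] <- forcing$funs[[cl]](t)
  out
}

#' @export
print.forcing_set <- function(x, ...) {
  cat("<forcing_set> ", nrow(x$grid), " points, ",
      x$t_start, "-", x$t_end, " min (step ", x$step,
      " min, smoothing window ", x$window, " min)\n", sep = "")
  cat("  peak S = ", signif(max(x$grid$S), 4),
      ", AS = ", signif(max(x$grid$AS), 4),
      ", AAS = ", signif(max(x$grid$AAS), 4),
      ", RsbU = ", signif(max(x$grid$RsbU), 4),
      ", RsbP = ", signif(max(x$grid$RsbP), 4), "\n", sep = "")
  invisible(x)
}

# Scale selected forcing columns by a multiplier (phosphatase dose scans).
scale_forcing <- function(forcing, cols, multiplier) {
  grid <- forcing$grid
  for (cl in cols) grid[[cl]] <- grid[[cl]] * multiplier
  new_forcing_set(grid, step = forcing$step, window = forcing$window)
}
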