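#' Specification of a synthetic germination/outgrowth expression course
#'
#' Describes a synthetic microarray time course with the magnitude and
#' replication structure of the SigB-network measurements during spore
#' germination and outgrowth: a 14-point irregular grid over 0--100 min,
#' sigmoidal accumulation of the SigB-operon transcripts to intensities
#' above 10^4, phosphatase profiles two orders of magnitude lower (~10^3
#' for rsbP, ~2.5x10^3 for rsbU), biological x technical duplicates, and
#' multiplicative log-normal noise.  Values are emitted on the log2 scale
#' so the de-logging/averaging step of the real pipeline is exercised.
#'
#' Each gene's noiseless mean is a logistic curve
#' `baseline + amplitude / (1 + exp(-steepness * (t - midpoint)))`.
#'
#' @param time_grid measurement times in minutes; default the 14-point
#'   grid `0, 5, ..., 30, 40, ..., 100`.
#' @param genes tibble with columns `gene`, `baseline`, `amplitude`
#'   (intensity units), `midpoint` (min), `steepness` (1/min).  The default
#'   covers the five network genes with operon amplitudes 1.2e4 (midpoint
#'   45 min, steepness 0.15/min), rsbU amplitude 2.3e3 and rsbP amplitude
#'   9e2 over small baselines, so the noiseless rsbU/rsbP peak ratio is
#'   about 2.5.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal replicate noise (default 0.1).
#' @param n_bio_reps,n_tech_reps biological and technical replicates
#'   (default 2 x 2).
#' @param seed integer seed; identical seeds give identical tables.
#' @return A list of class `synthetic_spec`.
#' @seealso [generate_profiles()]
#' @export
synthetic_spec <- function(time_grid = c(0, 5, 10, 15, 20, 25, 30, 40,
                                         50, 60, 70, 80, 90, 100),
                           genes = NULL,
                           noise_cv = 0.1,
                           n_bio_reps = 2L,
                           n_tech_reps = 2L,
                           seed = 1L) {
  if (is.null(genes)) {
    genes <- tibble::tibble(
      gene = c("sigB", "rsbW", "rsbV", "rsbU", "rsbP"),
      baseline = c(150, 150, 150, 200, 100),
      amplitude = c(1.2e4, 1.2e4, 1.2e4, 2.3e3, 9e2),
      midpoint = 45,
      steepness = 0.15
    )
  }
  if (is.unsorted(time_grid, strictly = TRUE)) {
    abort("`time_grid` must be strictly increasing.")
  }
  if (any(genes$amplitude < 0) || noise_cv < 0) {
    abort("Amplitudes and `noise_cv` must be non-negative.")
  }
  if (n_bio_reps < 1L || n_tech_reps < 1L) {
    abort("At least one biological and one technical replicate is required.")
  }
  structure(
    list(
      time_grid = as.numeric(time_grid), genes = genes,
      noise_cv = noise_cv, n_bio_reps = as.integer(n_bio_reps),
      n_tech_reps = as.integer(n_tech_reps), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", length(x$time_grid), " time points, ",
      nrow(x$genes), " genes, ", x$n_bio_reps, "x", x$n_tech_reps,
      " replicates, noise CV ", x$noise_cv, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Noiseless logistic mean of one gene at times t.
logistic_mean <- function(t, baseline, amplitude, midpoint, steepness) {
  baseline + amplitude / (1 + exp(-steepness * (t - midpoint)))
}

#' Generate replicated synthetic expression profiles
#'
#' Draws the replicated, noisy, log2-scale expression table described by a
#' [synthetic_spec()].  Replicate noise is multiplicative log-normal,
#' parameterised by its linear-scale coefficient of variation and centred
#' so the expected linear-scale value equals the logistic mean; it is
#' applied before the log2 transform, so replicates differ the way repeat
#' hybridisations do.
#'
#' @param spec a [synthetic_spec()].
#' @return tibble with columns `gene`, `replicate` (e.g. `"bio1_tech2"`),
#'   `time_min`, `value` (log2 intensity), ready for
#'   [delog_and_average()].
#' @examples
#' tab <- generate_profiles(synthetic_spec(seed = 42))
#' delog_and_average(tab)
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  # log-normal with unit mean and CV = noise_cv on the linear scale
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  reps <- expand.grid(bio = seq_len(spec$n_bio_reps),
                      tech = seq_len(spec$n_tech_reps))
  withr::with_seed(spec$seed, {
    out <- purrr::pmap(spec$genes, function(gene, baseline, amplitude,
                                            midpoint, steepness) {
      mu <- logistic_mean(spec$time_grid, baseline, amplitude, midpoint,
                          steepness)
      purrr::map2(reps$bio, reps$tech, function(b, te) {
        noise <- exp(rnorm(length(mu), mean = -sdlog^2 / 2, sd = sdlog))
        tibble::tibble(
          gene = gene,
          replicate = paste0("bio", b, "_tech", te),
          time_min = spec$time_grid,
          value = log2(mu * noise)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  out
}

#' One-call synthetic forcing set
#'
#' Convenience wrapper running the full front half of the pipeline on
#' synthetic data: generate replicated profiles, de-log and average them,
#' and build the forcing set.
#'
#' @param seed integer seed passed to [synthetic_spec()].
#' @param spec optional [synthetic_spec()] overriding `seed`.
#' @inheritParams build_forcing
#' @return A `forcing_set`.
#' @export
synthetic_forcing <- function(seed = 1L, spec = NULL, step = 1, window = 15) {
  spec <- spec %||% synthetic_spec(seed = seed)
  generate_profiles(spec) |>
    delog_and_average() |>
    build_forcing(step = step, window = window)
}
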