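#' Read expression time series from a delimited table
#'
#' Reads a tab- or comma-delimited table whose first row is a header, with a
#' `time_min` column (minutes) and one column per gene, and returns the
#' requested genes as a tidy long table.  This is the on-disk dialect used
#' throughout the package for measured or synthetic expression courses.
#'
#' @param path path to a `.tsv`/`.csv` (or any delimited) file.  The
#'   delimiter is sniffed from the header line (tab wins over comma).
#' @param gene_names character vector of gene columns to extract, e.g.
#'   `c("sigB", "rsbW", "rsbV", "rsbU", "rsbP")`.
#'
#' @return A tibble with columns `gene`, `time_min`, `value`, genes in
#'   request order and times sorted ascending within gene.
#' @seealso [write_series_table()], [delog_and_average()]
#' @export
read_series_table <- function(path, gene_names) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!"time_min" %in% names(tab)) {
    abort("Input table must have a 'time_min' column.")
  }
  missing <- setdiff(gene_names, names(tab))
  if (length(missing)) {
    abort(paste0("Gene column(s) not found in ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("time_min", gene_names)) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(paste0("Non-numeric value in column '", col, "', data row ",
                   bad %||% NA_integer_))
    }
  }
  times <- tab[["time_min"]]
  if (anyNA(times) || is.unsorted(times, strictly = TRUE)) {
    abort("Column 'time_min' must be strictly increasing (no duplicates).")
  }
  out <- tab |>
    dplyr::select(dplyr::all_of(c("time_min", gene_names))) |>
    tidyr::pivot_longer(-"time_min", names_to = "gene", values_to = "value") |>
    dplyr::mutate(gene = factor(.data$gene, levels = gene_names)) |>
    dplyr::arrange(.data$gene, .data$time_min) |>
    dplyr::mutate(gene = as.character(.data$gene)) |>
    dplyr::select("gene", "time_min", "value")
  validate_series(out)
  out
}

#' Write expression time series to a delimited table
#'
#' Inverse of [read_series_table()]: takes a long table of series and writes
#' the wide `time_min` + one-column-per-gene dialect.
#'
#' @param data tibble with columns `gene`, `time_min`, `value` (one value
#'   per gene and time; all genes on a common grid).
#' @param path output file; `.csv` extension selects comma, anything else tab.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(data, path) {
  validate_series(data)
  wide <- data |>
    dplyr::select("gene", "time_min", "value") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "value") |>
    dplyr::arrange(.data$time_min)
  if (anyNA(wide)) abort("Series do not share a common time grid.")
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(wide, path, delim = delim)
  invisible(path)
}

#' Undo the log transform and average replicates
#'
#' Microarray intensities are archived on the log2 scale and measured in
#' replicate.  This step exponentiates each replicate back to the linear
#' intensity scale and averages across replicates per gene and time point.
#' By default the mean is taken on the linear scale (an arithmetic mean of
#' intensities); `average = "log"` instead averages the log values before
#' exponentiating, which is the geometric mean of intensities.
#'
#' @param replicates tibble with columns `gene`, `replicate`, `time_min`,
#'   `value` where `value` is on the log scale.  All replicates of a gene
#'   must share the same time grid.
#' @param log_base base of the stored logarithm (default 2).
#' @param average `"linear"` (default) or `"log"`; see Details.
#' @return tibble with columns `gene`, `time_min`, `value` on the linear
#'   intensity scale; values are non-negative for any finite input.
#' @examples
#' reps <- tibble::tibble(
#'   gene = "sigB", replicate = rep(1:2, each = 3),
#'   time_min = rep(c(0, 5, 10), 2), value = rep(c(1, 3), each = 3)
#' )
#' delog_and_average(reps) # mean of 2 and 8 = 5
#' @export
delog_and_average <- function(replicates, log_base = 2,
                              average = c("linear", "log")) {
  average <- match.arg(average)
  need <- c("gene", "replicate", "time_min", "value")
  if (!all(need %in% names(replicates))) {
    abort(paste0("`replicates` needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(replicates) == 0L) abort("At least one replicate is required.")
  grids <- replicates |>
    dplyr::group_by(.data$gene, .data$replicate) |>
    dplyr::summarise(grid = paste(.data$time_min, collapse = ","),
                     .groups = "drop_last") |>
    dplyr::summarise(n = dplyr::n_distinct(.data$grid), .groups = "drop")
  if (any(grids$n > 1L)) {
    abort("Replicates of one gene must share an identical time grid.")
  }
  out <- replicates |>
    dplyr::group_by(.data$gene, .data$time_min) |>
    dplyr::summarise(
      value = if (average == "linear") {
        mean(log_base^.data$value)
      } else {
        log_base^mean(.data$value)
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene, .data$time_min)
  validate_series(out)
  out
}

# Shared validity checks for long series tables: strictly increasing times
# within gene, >= 2 points, finite values.
validate_series <- function(data, min_points = 2L) {
  need <- c("gene", "time_min", "value")
  if (!all(need %in% names(data))) {
    abort(paste0("Series table needs columns: ", paste(need, collapse = ", ")))
  }
  if (!is.numeric(data$time_min) || !is.numeric(data$value)) {
    abort("'time_min' and 'value' must be numeric.")
  }
  if (any(!is.finite(data$value))) abort("All series values must be finite.")
  by_gene <- split(data$time_min, data$gene)
  for (g in names(by_gene)) {
    t <- by_gene[[g]]
    if (length(t) < min_points) {
      abort(paste0("Series '", g, "' has fewer than ", min_points, " points."))
    }
    if (is.unsorted(t, strictly = TRUE)) {
      abort(paste0("Times of series '", g,
                   "' must be strictly increasing without duplicates."))
    }
  }
  invisible(data)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration with any of the keys `grid_step_min`,
#' `smooth_window_min`, `log_base` and a `constants` block of rate-constant
#' overrides, filling unspecified entries with package defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `grid_step_min`, `smooth_window_min`,
#'   `log_base` and `constants` (a [sigb_constants()] object).
#' @export
read_sigb_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("grid_step_min", "smooth_window_min", "log_base", "constants")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  list(
    grid_step_min = cfg$grid_step_min %||% 1,
    smooth_window_min = cfg$smooth_window_min %||% 15,
    log_base = cfg$log_base %||% 2,
    constants = do.call(sigb_constants, as.list(cfg$constants %||% list()))
  )
}
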