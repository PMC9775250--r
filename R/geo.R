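#' Extract network genes from a GEO series-matrix file
#'
#' Parses the table block of a GEO series-matrix file
#' (`!series_matrix_table_begin` ... `!series_matrix_table_end`, tab
#' delimited, `ID_REF` x sample columns) and returns the requested probes
#' as a tidy time-series table in the package's standard shape.  The loader
#' is offline plumbing for a locally saved extract; it never downloads.
#'
#' Samples sharing a time point are treated as replicates and averaged on
#' the linear scale; if `log_base` is given the stored values are
#' exponentiated first.
#'
#' @param path path to a (possibly truncated) series-matrix text file.
#' @param probe_map named character vector mapping probe `ID_REF`s to gene
#'   names, e.g. `c(BSU04730_at = "sigB")`.  Several probes may map to one
#'   gene; their values are averaged.
#' @param sample_times numeric vector of sampling times in minutes, either
#'   named by sample accession or unnamed and in column order.
#' @param log_base base of the stored log transform, or `NULL` (default)
#'   if the file already holds linear intensities.
#' @return tibble with columns `gene`, `time_min`, `value` (linear scale),
#'   ordered as in `probe_map`.
#' @export
read_geo_series_matrix <- function(path, probe_map, sample_times,
                                   log_base = NULL) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    abort("No series-matrix table block found in file.")
  }
  tab <- readr::read_tsv(I(lines[(begin + 1L):(end - 1L)]),
                         show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "ID_REF"
  samples <- names(tab)[-1]
  if (!is.null(names(sample_times)) && all(names(sample_times) != "")) {
    missing_s <- setdiff(samples, names(sample_times))
    if (length(missing_s)) {
      abort(paste0("No time given for sample(s): ",
                   paste(missing_s, collapse = ", ")))
    }
    times <- as.numeric(sample_times[samples])
  } else {
    if (length(sample_times) != length(samples)) {
      abort("`sample_times` must match the number of sample columns.")
    }
    times <- as.numeric(sample_times)
  }
  missing_p <- setdiff(names(probe_map), tab$ID_REF)
  if (length(missing_p)) {
    abort(paste0("Probe(s) not found: ", paste(missing_p, collapse = ", ")))
  }
  out <- tab |>
    dplyr::filter(.data$ID_REF %in% names(probe_map)) |>
    tidyr::pivot_longer(-"ID_REF", names_to = "sample",
                        values_to = "value") |>
    dplyr::mutate(
      gene = unname(probe_map[.data$ID_REF]),
      time_min = times[match(.data$sample, samples)],
      value = if (is.null(log_base)) .data$value else log_base^.data$value
    ) |>
    dplyr::group_by(.data$gene, .data$time_min) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(gene = factor(.data$gene, levels = unique(unname(probe_map)))) |>
    dplyr::arrange(.data$gene, .data$time_min) |>
    dplyr::mutate(gene = as.character(.data$gene))
  validate_series(out)
  out
}
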