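#' Kinetic rate constants of the SigB partner-switching network
#'
#' Builds the set of eleven mass-action rate constants governing the
#' partner-switching reactions: RsbW dimer (W2) binding of the
#' anti-anti-sigma factor RsbV (`k1p`/`k1m`, `k2p`/`k2m`), RsbV
#' phosphorylation by the RsbW kinase (`k3p`, `k4p`), SigB sequestration by
#' W2 (`k5p`/`k5m`), displacement of SigB from the W2.SigB complex by RsbV
#' (`k6p`/`k6m`) and dephosphorylation of RsbV-P by the phosphatases RsbU
#' and RsbP (`k7p`, shared by both).
#'
#' Defaults are the published estimates scaled to microarray intensity
#' units, so second-order constants carry units of per-intensity per-minute
#' (y^-1 min^-1) and first-order constants per-minute.  The baseline
#' dissociation-to-association ratio of the SigB/anti-sigma reaction is
#' `k5m / k5p = 0.3 / 6e-5 = 5000`.
#'
#' @param ... named overrides of individual constants, e.g.
#'   `sigb_constants(k5m = 3)`.  Unknown names are an error.
#'
#' @return A named numeric vector of class `sigb_constants` with elements
#'   `k1p, k1m, k2p, k2m, k3p, k4p, k5p, k5m, k6p, k6m, k7p`.
#' @examples
#' k <- sigb_constants()
#' unname(k["k5m"] / k["k5p"]) # 5000
#' tidy(k)
#' @export
sigb_constants <- function(...) {
  k <- c(
    k1p = 6e-5, k1m = 0.3,
    k2p = 6e-5, k2m = 0.3,
    k3p = 3, k4p = 3,
    k5p = 6e-5, k5m = 0.3,
    k6p = 3e-5, k6m = 3e-5,
    k7p = 3e-5
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(k))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0(
        "Unknown or unnamed rate constant(s): ",
        paste(bad, collapse = ", ")
      ))
    }
    k[names(dots)] <- as.numeric(dots)
  }
  if (any(!is.finite(k)) || any(k < 0)) {
    abort("All rate constants must be finite and non-negative.")
  }
  structure(k, class = "sigb_constants")
}

#' @export
print.sigb_constants <- function(x, ...) {
  cat("<sigb_constants>  (second-order in y^-1 min^-1, first-order in min^-1)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @describeIn sigb_constants one row per constant with its unit and the
#'   reaction it parameterises.
#' @param x a `sigb_constants` object.
#' @exportS3Method generics::tidy
tidy.sigb_constants <- function(x, ...) {
  second_order <- c("k1p", "k2p", "k5p", "k6p", "k6m", "k7p")
  reactions <- c(
    k1p = "W2 + V -> W2V", k1m = "W2V -> W2 + V",
    k2p = "W2V + V -> W2V2", k2m = "W2V2 -> W2V + V",
    k3p = "V -> VP (W2 kinase)", k4p = "W2V2 -> W2V + VP",
    k5p = "W2 + SigB -> W2SigB", k5m = "W2SigB -> W2 + SigB",
    k6p = "W2SigB + V -> W2V + SigB", k6m = "W2V + SigB -> W2SigB + V",
    k7p = "VP + RsbU/RsbP -> V"
  )
  tibble::tibble(
    constant = names(unclass(x)),
    value = as.numeric(x),
    unit = ifelse(names(unclass(x)) %in% second_order,
      "y^-1 min^-1", "min^-1"
    ),
    reaction = unname(reactions[names(unclass(x))])
  )
}
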