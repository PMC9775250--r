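# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

default_forcing <- function() {
  if (is.null(.fixtures$forcing)) {
    .fixtures$forcing <- synthetic_forcing(seed = 1)
  }
  .fixtures$forcing
}

baseline_trajectory <- function() {
  if (is.null(.fixtures$traj)) {
    .fixtures$traj <- run_simulation(default_forcing())
  }
  .fixtures$traj
}

network_genes <- c("sigB", "rsbW", "rsbV", "rsbU", "rsbP")

# Flat (constant-profile) forcing: all derivatives exactly zero after
# smoothing, phosphatase levels at the stated magnitudes.
constant_forcing <- function(sigB = 5000, rsbW = 5000, rsbV = 5000,
                             rsbU = 2500, rsbP = 1000) {
  grid <- c(0, 5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90, 100)
  vals <- c(sigB = sigB, rsbW = rsbW, rsbV = rsbV, rsbU = rsbU, rsbP = rsbP)
  raw <- tibble::tibble(
    gene = rep(names(vals), each = length(grid)),
    time_min = rep(grid, 5),
    value = rep(unname(vals), each = length(grid))
  )
  build_forcing(raw)
}

state_vec <- function(...) {
  s <- stats::setNames(numeric(7),
                       c("SigB_f", "W2_f", "V_f", "W2SigB", "W2V", "W2V2", "VP"))
  dots <- c(...)
  s[names(dots)] <- dots
  s
}
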