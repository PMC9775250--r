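# Independent oracles.
#
# stoich_rhs() re-derives the seven species derivatives from the reaction
# list itself -- a stoichiometry matrix times a propensity vector, plus the
# measured-total injections -- without sharing any code with the package's
# hand-coded right-hand side.  rk4_oracle() is a classical fixed-step
# Runge-Kutta integrator written directly on top of stoich_rhs().

# Species rows: SigB_f, W2_f, V_f, W2SigB, W2V, W2V2, VP.
# Reaction columns: the forward/reverse elementary reactions of the
# partner-switching scheme -- W2+V binding (1f/1r), W2V+V binding (2f/2r),
# kinase phosphorylation of free V (3) and within W2V2 (4), W2+SigB
# binding (5f/5r), displacement of SigB by V (6f/6r), dephosphorylation by
# RsbU (7) and RsbP (8).
.stoich <- matrix(
  c(
    #        1f  1r  2f  2r   3   4  5f  5r  6f  6r   7   8
    0,   0,  0,  0,   0,  0, -1, +1, +1, -1,  0,  0,  # SigB_f
    -1, +1,  0,  0,   0,  0, -1, +1,  0,  0,  0,  0,  # W2_f
    -1, +1, -1, +1,  -1,  0,  0,  0, -1, +1, +1, +1,  # V_f
    0,   0,  0,  0,   0,  0, +1, -1, -1, +1,  0,  0,  # W2SigB
    +1, -1, -1, +1,   0, +1,  0,  0, +1, -1,  0,  0,  # W2V
    0,   0, +1, -1,   0, -1,  0,  0,  0,  0,  0,  0,  # W2V2
    0,   0,  0,  0,  +1, +1,  0,  0,  0,  0, -1, -1   # VP
  ),
  nrow = 7, byrow = TRUE,
  dimnames = list(
    c("SigB_f", "W2_f", "V_f", "W2SigB", "W2V", "W2V2", "VP"),
    c("r1f", "r1r", "r2f", "r2r", "r3", "r4",
      "r5f", "r5r", "r6f", "r6r", "r7", "r8")
  )
)

stoich_rhs <- function(state, k, dS = 0, dAS = 0, dAAS = 0,
                       RsbU = 0, RsbP = 0) {
  v <- c(
    r1f = k[["k1p"]] * state[["W2_f"]] * state[["V_f"]],
    r1r = k[["k1m"]] * state[["W2V"]],
    r2f = k[["k2p"]] * state[["W2V"]] * state[["V_f"]],
    r2r = k[["k2m"]] * state[["W2V2"]],
    r3  = k[["k3p"]] * state[["W2_f"]] * state[["V_f"]],
    r4  = k[["k4p"]] * state[["W2V2"]],
    r5f = k[["k5p"]] * state[["W2_f"]] * state[["SigB_f"]],
    r5r = k[["k5m"]] * state[["W2SigB"]],
    r6f = k[["k6p"]] * state[["W2SigB"]] * state[["V_f"]],
    r6r = k[["k6m"]] * state[["W2V"]] * state[["SigB_f"]],
    r7  = k[["k7p"]] * state[["VP"]] * RsbU,
    r8  = k[["k7p"]] * state[["VP"]] * RsbP
  )
  inject <- c(SigB_f = dS, W2_f = dAS / 2, V_f = dAAS,
              W2SigB = 0, W2V = 0, W2V2 = 0, VP = 0)
  drop(.stoich %*% v) + inject
}

# Classical RK4 at fixed step dt, on the stoichiometry-oracle rhs with the
# forcing evaluated through the same piecewise-linear grid functions the
# solver sees.  Returns states at the requested output times.
rk4_oracle <- function(forcing, constants, t_end, dt, out_times) {
  k <- unclass(constants)
  funs <- forcing$funs
  f <- function(t, y) {
    stoich_rhs(y, k, dS = funs$dS(t), dAS = funs$dAS(t),
               dAAS = funs$dAAS(t), RsbU = funs$RsbU(t), RsbP = funs$RsbP(t))
  }
  y <- state_vec()
  n <- round(t_end / dt)
  out <- matrix(NA_real_, nrow = length(out_times), ncol = 7,
                dimnames = list(NULL, names(y)))
  oi <- 1L
  if (out_times[1] == 0) { out[1, ] <- y; oi <- 2L }
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tnow <- i * dt
    while (oi <= length(out_times) && out_times[oi] <= tnow + 1e-12) {
      out[oi, ] <- y
      oi <- oi + 1L
    }
  }
  out
}

# Exact integral of the solver's piecewise-linear forcing-derivative
# interpolant: the solver-consistent conservation target.
cumtrapz_target <- function(times, deriv) {
  h <- diff(times)
  c(0, cumsum(h * (head(deriv, -1) + tail(deriv, -1)) / 2))
}

random_state <- function() {
  state_vec(
    SigB_f = stats::runif(1, 0, 1e4), W2_f = stats::runif(1, 0, 1e4),
    V_f = stats::runif(1, 0, 1e4), W2SigB = stats::runif(1, 0, 1e4),
    W2V = stats::runif(1, 0, 1e4), W2V2 = stats::runif(1, 0, 1e4),
    VP = stats::runif(1, 0, 1e4)
  )
}
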