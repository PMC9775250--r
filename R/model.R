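#' Right-hand side of the forced partner-switching ODE system
#'
#' Computes the time-derivatives of the seven dynamical species of the SigB
#' network -- free sigma factor `SigB_f`, free anti-sigma dimer `W2_f`,
#' free anti-anti-sigma factor `V_f`, the complexes `W2SigB`, `W2V`,
#' `W2V2` and phosphorylated RsbV `VP` -- under mass-action kinetics, with
#' the measured totals entering through their time-derivatives and the
#' phosphatase levels entering the dephosphorylation term.
#'
#' The complexes obey pure mass action:
#' \deqn{d[W2SigB]/dt = k5p\,W2_f\,SigB_f - k5m\,W2SigB - k6p\,W2SigB\,V_f + k6m\,W2V\,SigB_f}
#' \deqn{d[W2V]/dt = k2m\,W2V2 - k2p\,W2V\,V_f + k4p\,W2V2 + k1p\,W2_f\,V_f - k1m\,W2V + k6p\,W2SigB\,V_f - k6m\,W2V\,SigB_f}
#' \deqn{d[W2V2]/dt = k2p\,W2V\,V_f - k2m\,W2V2 - k4p\,W2V2}
#' \deqn{d[VP]/dt = k3p\,W2_f\,V_f + k4p\,W2V2 - k7p\,VP\,(RsbP(t) + RsbU(t))}
#' while the free forms track the measured totals minus their complexed
#' shares, using the smoothed derivatives \eqn{dS/dt}, \eqn{dAS/dt},
#' \eqn{dAAS/dt} of the measured SigB, RsbW and RsbV profiles:
#' \deqn{d[SigB_f]/dt = dS/dt - d[W2SigB]/dt}
#' \deqn{d[W2_f]/dt = \tfrac12\,dAS/dt - d[W2V]/dt - d[W2V2]/dt - d[W2SigB]/dt}
#' \deqn{d[V_f]/dt = dAAS/dt - d[W2V]/dt - 2\,d[W2V2]/dt - d[VP]/dt}
#' The RsbW dimer is counted in dimer units, hence the factor 1/2 on the
#' measured monomer total and the factors 2 in [reconstruct_totals()].
#'
#' @param t time in minutes, within the forcing range.
#' @param state named numeric vector of the seven species (any order; names
#'   `SigB_f, W2_f, V_f, W2SigB, W2V, W2V2, VP`), finite.
#' @param forcing a `forcing_set` from [build_forcing()].
#' @param constants a [sigb_constants()] object.
#' @return Named numeric vector of the seven derivatives, intensity units
#'   per minute.
#' @export
sigb_rhs <- function(t, state, forcing, constants = sigb_constants()) {
  stopifnot(inherits(forcing, "forcing_set"))
  if (length(t) != 1L || t < forcing$t_start - 1e-9 ||
      t > forcing$t_end + 1e-9) {
    abort("`t` must be a single time within the forcing range.")
  }
  if (!all(.sigb_species %in% names(state))) {
    abort(paste0("`state` must name the species: ",
                 paste(.sigb_species, collapse = ", ")))
  }
  state <- state[.sigb_species]
  if (any(!is.finite(state))) abort("`state` must be finite.")
  f <- forcing_eval(forcing, t)
  rhs_core(
    state,
    constants,
    dS = f$dS, dAS = f$dAS, dAAS = f$dAAS,
    RsbU = f$RsbU, RsbP = f$RsbP
  )
}

# Unvalidated core, shared with the solver wrapper.  `state` must already
# be ordered as .sigb_species.
rhs_core <- function(state, k, dS, dAS, dAAS, RsbU, RsbP) {
  SigB_f <- state[[1]]; W2_f <- state[[2]]; V_f <- state[[3]]
  W2SigB <- state[[4]]; W2V <- state[[5]]; W2V2 <- state[[6]]
  VP <- state[[7]]

  dW2SigB <- k[["k5p"]] * W2_f * SigB_f - k[["k5m"]] * W2SigB -
    k[["k6p"]] * W2SigB * V_f + k[["k6m"]] * W2V * SigB_f
  dW2V <- k[["k2m"]] * W2V2 - k[["k2p"]] * W2V * V_f + k[["k4p"]] * W2V2 +
    k[["k1p"]] * W2_f * V_f - k[["k1m"]] * W2V +
    k[["k6p"]] * W2SigB * V_f - k[["k6m"]] * W2V * SigB_f
  dW2V2 <- k[["k2p"]] * W2V * V_f - k[["k2m"]] * W2V2 - k[["k4p"]] * W2V2
  dVP <- k[["k3p"]] * W2_f * V_f + k[["k4p"]] * W2V2 -
    k[["k7p"]] * VP * RsbP - k[["k7p"]] * VP * RsbU

  dSigB_f <- dS - dW2SigB
  dW2_f <- 0.5 * dAS - dW2V - dW2V2 - dW2SigB
  dV_f <- dAAS - dW2V - 2 * dW2V2 - dVP

  c(SigB_f = dSigB_f, W2_f = dW2_f, V_f = dV_f, W2SigB = dW2SigB,
    W2V = dW2V, W2V2 = dW2V2, VP = dVP)
}

#' Reconstruct measured totals from a model state
#'
#' The measured expression of each network gene is the sum of its free form
#' and every complex containing it:
#' \deqn{S = SigB_f + W2SigB}
#' \deqn{AS = 2\,W2_f + 2\,W2V + 2\,W2V2 + 2\,W2SigB}
#' \deqn{AAS = V_f + W2V + 2\,W2V2 + VP}
#' (RsbW counted as monomers, hence the factors of 2; `W2V2` carries two
#' RsbV copies).  With all-zero initial conditions these reconstructed
#' totals track the measured profiles relative to their value at time zero.
#'
#' @param state a named numeric vector of the seven species, or a data
#'   frame / tibble with one column per species (e.g. `tidy()` output
#'   pivoted wide, or `trajectory$states`).
#' @return A tibble with columns `S_model`, `AS_model`, `AAS_model` (one
#'   row per input state).
#' @export
reconstruct_totals <- function(state) {
  if (is.numeric(state)) state <- tibble::as_tibble(as.list(state))
  if (!all(.sigb_species %in% names(state))) {
    abort(paste0("`state` must provide the species: ",
                 paste(.sigb_species, collapse = ", ")))
  }
  tibble::tibble(
    S_model = state$SigB_f + state$W2SigB,
    AS_model = 2 * (state$W2_f + state$W2V + state$W2V2 + state$W2SigB),
    AAS_model = state$V_f + state$W2V + 2 * state$W2V2 + state$VP
  )
}
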