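test_that("zero forcing keeps the network at the zero fixed point", {
  fs <- constant_forcing(sigB = 0, rsbW = 0, rsbV = 0, rsbU = 0, rsbP = 0)
  traj <- run_simulation(fs)
  expect_lt(max(abs(as.matrix(traj$states[-1]))), 1e-12)
  # ratio undefined everywhere when nothing is free
  expect_true(all(is.na(summarize_free_fraction(traj)$total_to_free)))
})

test_that("simulation is deterministic and validates tolerances", {
  fs <- default_forcing()
  a <- run_simulation(fs)
  b <- run_simulation(fs)
  expect_identical(a$states, b$states)
  expect_identical(a$meta$config_hash, b$meta$config_hash)
  expect_error(run_simulation(fs, rel_tol = 0), "positive")
})

test_that("conservation holds to solver accuracy against the interpolated forcing", {
  traj <- baseline_trajectory()
  g <- traj$forcing$grid
  st <- traj$states
  sums <- list(
    S = st$SigB_f + st$W2SigB,
    AS = 2 * (st$W2_f + st$W2V + st$W2V2 + st$W2SigB),
    AAS = st$V_f + st$W2V + 2 * st$W2V2 + st$VP
  )
  for (sym in names(sums)) {
    target <- cumtrapz_target(g$time_min, g[[paste0("d", sym)]])
    bound <- 10 * max(traj$abs_tol, 1e-6 * max(abs(target)))
    expect_lt(max(abs(sums[[sym]] - target)), bound)
  }
})

test_that("the conservation target differs from grid totals only by the
           documented derivative-interpolation discretisation floor", {
  traj <- baseline_trajectory()
  g <- traj$forcing$grid
  for (sym in c("S", "AS", "AAS")) {
    target <- cumtrapz_target(g$time_min, g[[paste0("d", sym)]])
    gap <- max(abs(target - (g[[sym]] - g[[sym]][1])))
    expect_lt(gap / max(abs(g[[sym]] - g[[sym]][1])), 2e-3)
  }
  # and check_mass_balance reports exactly that combined error level
  mb <- check_mass_balance(traj)
  expect_lt(max(mb$rel_error), 2e-3)
})

test_that("adaptive solution matches a fixed-step RK4 at a stable step", {
  # explicit stability limit: the kinase term gives an eigenvalue of about
  # -k3p * W2_f ~ -7e3/min, so a fixed step must satisfy dt < 2.785/7e3
  traj <- baseline_trajectory()
  fs <- traj$forcing
  g <- fs$grid
  forcings <- list(
    cbind(g$time_min, g$RsbU), cbind(g$time_min, g$RsbP),
    cbind(g$time_min, g$dS), cbind(g$time_min, g$dAS),
    cbind(g$time_min, g$dAAS)
  )
  oracle <- deSolve::ode(
    state_vec(), seq(0, 100, by = 2e-4), func = "sigb_derivs",
    parms = as.numeric(unclass(sigb_constants())), dllname = "sigbswitch",
    initfunc = "sigb_initparms", initforc = "sigb_initforcs",
    forcings = forcings, fcontrol = list(method = "linear", rule = 2),
    method = "rk4"
  )
  at_grid <- oracle[oracle[, 1] %in% g$time_min, -1]
  m <- as.matrix(traj$states[, -1])
  peaks <- apply(abs(at_grid), 2, max)
  keep <- peaks > 1
  rel <- max(abs(m - at_grid)[, keep] /
               rep(peaks[keep], each = nrow(m)))
  expect_lt(rel, 1e-3)
})

test_that("an independent pure-R RK4 on the reaction oracle reproduces the
           early time course", {
  traj <- baseline_trajectory()
  out_times <- 0:6
  oracle <- rk4_oracle(traj$forcing, sigb_constants(), t_end = 6,
                       dt = 2.5e-4, out_times = out_times)
  m <- as.matrix(traj$states[traj$states$time_min %in% out_times, -1])
  scale <- pmax(apply(abs(oracle), 2, max), 1)
  rel <- max(abs(m - oracle) / rep(scale, each = nrow(m)))
  expect_lt(rel, 1e-3)
})

test_that("tightening the tolerance moves end states by at most an order of
           magnitude of the previous tolerance", {
  fs <- default_forcing()
  t1 <- run_simulation(fs, rel_tol = 1e-6)
  t2 <- run_simulation(fs, rel_tol = 5e-7)
  d <- abs(unlist(tail(t1$states, 1)[-1]) - unlist(tail(t2$states, 1)[-1]))
  peaks <- pmax(sapply(t1$states[-1], function(x) max(abs(x))), 1)
  expect_lt(max(d / peaks), 10 * 1e-6)
})

test_that("free-fraction summary reports total over free SigB", {
  base <- baseline_trajectory()
  # constructed identity: free SigB is exactly a quarter of the total
  quarter <- base
  quarter$states <- dplyr::mutate(base$states,
                                  SigB_f = base$forcing$grid$S / 4)
  ff <- summarize_free_fraction(quarter)
  expect_equal(ff$total_to_free, rep(4, nrow(ff)))
  expect_equal(attr(ff, "end_ratio"), 4)

  ff_base <- summarize_free_fraction(base)
  expect_true(attr(ff_base, "end_ratio") > 1) # free form strictly less
  expect_true(is.finite(attr(ff_base, "end_ratio")))
})

test_that("trajectory tidiers expose model species plus forcing", {
  traj <- baseline_trajectory()
  td <- tidy(traj)
  expect_setequal(
    unique(td$species),
    c("SigB_f", "W2_f", "V_f", "W2SigB", "W2V", "W2V2", "VP",
      "S_total", "AS_total", "AAS_total", "RsbU", "RsbP")
  )
  expect_equal(nrow(td), 12 * 101)
  gl <- glance(traj)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$total_to_free_sigb > 1)
  expect_lt(gl$max_rel_balance_error, 2e-3)
})
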