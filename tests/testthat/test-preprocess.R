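measured_grid <- c(0, 5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90, 100)

test_that("pchip interpolation densifies the measurement grid faithfully", {
  s <- tibble::tibble(gene = "sigB", time_min = measured_grid,
                      value = 100 + measured_grid^1.5)
  dense <- interpolate_series(s, step = 1)
  expect_equal(nrow(dense), 101L)
  expect_equal(dense$time_min, 0:100)
  # passes through every measured point
  expect_equal(dense$value[dense$time_min %in% measured_grid], s$value)

  const <- tibble::tibble(time_min = measured_grid, value = 7)
  expect_equal(interpolate_series(const)$value, rep(7, 101))

  ramp <- tibble::tibble(time_min = measured_grid, value = 2 * measured_grid)
  expect_equal(interpolate_series(ramp)$value, 2 * (0:100), tolerance = 1e-12)

  expect_error(interpolate_series(s, step = 0), "positive")
  expect_error(interpolate_series(s[1, , drop = FALSE]), "fewer than 2")
})

test_that("shape preservation keeps the interpolant inside the data range", {
  withr::with_seed(21, {
    for (i in 1:10) {
      vals <- cumsum(abs(rnorm(length(measured_grid), sd = 50))) # monotone
      s <- tibble::tibble(time_min = measured_grid, value = vals)
      dense <- interpolate_series(s)
      expect_gte(min(dense$value), min(vals) - 1e-9)
      expect_lte(max(dense$value), max(vals) + 1e-9)
      # monotone data stay monotone under pchip
      expect_true(all(diff(dense$value) >= -1e-9))
    }
  })
})

test_that("Gaussian smoothing matches direct convolution and preserves bounds", {
  n <- 61
  flat <- tibble::tibble(time_min = 0:(n - 1), value = rep(3, n))
  expect_equal(smooth_series(flat, window = 15)$value, rep(3, n))

  # unit impulse at an interior point vs explicitly computed kernel weights
  imp <- tibble::tibble(time_min = 0:(n - 1),
                        value = as.numeric(seq_len(n) == 31))
  sm <- smooth_series(imp, window = 15)
  sigma <- (15 - 1) / 5
  w <- exp(-0.5 * ((-7:7) / sigma)^2)
  w <- w / sum(w)
  expect_equal(sm$value[31 + (-7:7)], rev(w), tolerance = 1e-12)
  expect_equal(sm$value[31 + (-7:7)], w, tolerance = 1e-12) # symmetric
  expect_lt(sm$value[31], 1) # peak strictly reduced
  expect_gte(min(sm$value), 0)
  expect_lte(max(sm$value), 1)

  # one-sample window degenerates to the identity
  expect_equal(smooth_series(imp, window = 1)$value, imp$value,
               tolerance = 1e-12)
  expect_error(smooth_series(imp, window = 0.5), "at least one grid step")
})

test_that("smoothing preserves the mean of a periodic extension", {
  withr::with_seed(22, {
    block <- runif(30, 0, 100)
    x <- tibble::tibble(time_min = 0:89, value = rep(block, 3))
    sm <- smooth_series(x, window = 15)
    mid <- 31:60 # interior copy: kernel never truncates there
    expect_equal(mean(sm$value[mid]), mean(block), tolerance = 1e-6)
  })
})

test_that("finite differences are exact for polynomials up to degree two", {
  t <- 0:50
  expect_equal(differentiate_series(
    tibble::tibble(time_min = t, value = rep(4, 51)))$deriv, rep(0, 51))
  expect_equal(differentiate_series(
    tibble::tibble(time_min = t, value = 3 * t - 7))$deriv, rep(3, 51))
  expect_equal(differentiate_series(
    tibble::tibble(time_min = t, value = t^2))$deriv, 2 * t,
    tolerance = 1e-12)
  expect_error(differentiate_series(
    tibble::tibble(time_min = c(0, 1), value = c(1, 2))), "at least 3")
})

test_that("forcing construction composes interpolate, smooth, differentiate", {
  raw <- generate_profiles(synthetic_spec(seed = 5)) |> delog_and_average()
  fs <- build_forcing(raw, step = 1, window = 15)

  manual <- raw |>
    dplyr::filter(gene == "sigB") |>
    interpolate_series(step = 1) |>
    smooth_series(window = 15) |>
    differentiate_series()
  expect_equal(fs$grid$S, manual$value)
  expect_equal(fs$grid$dS, manual$deriv)
  expect_equal(fs$t_start, 0)
  expect_equal(fs$t_end, 100)

  expect_error(build_forcing(dplyr::filter(raw, gene != "rsbP")), "rsbP")
  expect_error(forcing_eval(fs, 150), "outside")
  expect_error(forcing_eval(fs, -1), "outside")
  at <- forcing_eval(fs, c(0, 50.5, 100))
  expect_equal(at$S[1], fs$grid$S[1])
  expect_equal(at$S[2], mean(fs$grid$S[51:52])) # piecewise linear
})

test_that("constant profiles give identically zero forcing derivatives", {
  fs <- constant_forcing()
  expect_equal(fs$grid$dS, rep(0, 101))
  expect_equal(fs$grid$dAS, rep(0, 101))
  expect_equal(fs$grid$dAAS, rep(0, 101))
})

test_that("derivatives of monotone series never oppose the trend", {
  withr::with_seed(23, {
    for (i in 1:10) {
      vals <- 100 + cumsum(abs(rnorm(length(measured_grid), sd = 200)))
      dense <- interpolate_series(
        tibble::tibble(time_min = measured_grid, value = vals))
      d <- differentiate_series(dense)$deriv
      interior <- 2:(length(d) - 1)
      expect_true(all(d[interior] >= -1e-9))
    }
  })
})
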