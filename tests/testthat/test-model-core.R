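# Closed-form steady-state quantities of the trans model and the
# exponential cis reference. The canonical parameter set D = 1, alpha = 6,
# S = 2 gives C = 6D/alpha = 1 and x0 = (2DC/S)^(1/3) = 1, so the profile
# is 1/(1+x)^2 with unit amplitude and unit cortical total.

test_that("canonical trans steady state has C = x0 = A = P_tot = 1", {
  p <- par_unit()
  s <- steady_state_summary(p)
  expect_equal(s$C, 1)
  expect_equal(s$x0, 1)
  expect_equal(s$amplitude, 1)
  expect_equal(s$total_cortical, 1)
  prof <- analytic_steady_state(p, grid_coarse())
  expect_equal(prof$values[1], 1)
  i <- which(prof$positions == 1)
  expect_equal(prof$values[i], 0.25)
})

test_that("summary identities hold across parameter sets", {
  for (D in c(0.5, 1, 2)) for (al in c(1, 6)) for (S in c(0.3, 2, 11)) {
    s <- steady_state_summary(model_params(D = D, alpha = al,
                                           source_strength = S))
    expect_equal(s$amplitude, s$C / s$x0^2)
    expect_equal(s$total_cortical, s$C / s$x0)
    expect_equal(s$total_cortical, sqrt(s$C * s$amplitude))
    # flux balance of the closed form: 2 D C / x0^3 = S
    expect_equal(2 * D * s$C / s$x0^3, S)
  }
})

test_that("amplitude scales as S^(2/3): eightfold source quadruples A", {
  p1 <- par_unit(S = 2)
  p8 <- par_unit(S = 16)
  expect_equal(steady_state_summary(p8)$amplitude,
               4 * steady_state_summary(p1)$amplitude)
  # and A * x0^2 = C is invariant under S
  expect_equal(steady_state_summary(p8)$amplitude *
                 steady_state_summary(p8)$x0^2,
               steady_state_summary(p1)$C)
})

test_that("numerical steady state confirms the S^(2/3) amplitude scaling", {
  g <- grid_fine()
  st <- solver_settings(rel_tol = 1e-8)
  A <- vapply(c(2, 16), function(S) {
    p <- par_unit(S = S, w = 0.03)
    fit_power_profile(solve_to_steady_state(p, g, st))$amplitude
  }, numeric(1))
  expect_equal(A[2] / A[1], 4, tolerance = 0.02)
})

test_that("zero source gives the zero profile and a degenerate summary", {
  p <- par_unit(S = 0)
  prof <- analytic_steady_state(p, grid_coarse())
  expect_true(all(prof$values == 0))
  expect_error(steady_state_summary(p), "degenerate")
})

test_that("invalid physical parameters are rejected", {
  expect_error(model_params(D = -1), "D must be positive")
  expect_error(model_params(alpha = 0), "alpha")
  expect_error(model_params(gamma = 2.5), "gamma")
  expect_error(model_params(kappa = c(0, 2, 1), model_kind = "detailed"),
               "kappa")
  expect_error(model_params(source_strength = -1), "source_strength")
})

test_that("decay length of the power-law profile follows the closed form", {
  expect_equal(decay_length_from_x0(1, 0.5), sqrt(2) - 1)
  # numerically solving C/(lambda+x0)^2 = f * C/x0^2 gives the same value
  f <- 0.37
  lam <- uniroot(function(l) 1 / (l + 1)^2 - f, c(0, 10), tol = 1e-12)$root
  expect_equal(decay_length_from_x0(1, f), lam, tolerance = 1e-8)
  # fraction -> 1 collapses the decay length onto the pole
  expect_lt(decay_length_from_x0(1, 0.999), 1e-3)
  expect_error(decay_length_from_x0(1, 1.2), "fraction")
  expect_error(decay_length_from_x0(-1, 0.5), "x0")
})

test_that("quadrupling the amplitude at fixed C halves x0 and lambda", {
  p1 <- par_unit(S = 2)
  s1 <- steady_state_summary(p1)
  # A = C/x0^2 and A4 = 4 A requires S scaled by 4^(3/2) = 8
  p4 <- par_unit(S = 16)
  s4 <- steady_state_summary(p4)
  expect_equal(s4$amplitude, 4 * s1$amplitude)
  expect_equal(s4$x0, s1$x0 / 2)
  expect_equal(s4$decay_length, s1$decay_length / 2)
})

test_that("threshold shift matches x0 (1 - k^(-1/3)) and is bounded by x0", {
  p <- par_unit()
  x0 <- steady_state_summary(p)$x0
  expect_equal(threshold_shift(p, 8, 0.1), x0 / 2)
  expect_equal(threshold_shift(p, 1, 0.1), 0)
  for (k in c(2, 10, 100, 1e6)) {
    dxk <- threshold_shift(p, k, 0.1)
    expect_gt(dxk, 0)
    expect_lt(dxk, x0)
  }
  expect_error(threshold_shift(p, 2, 5), "no crossing")
})

test_that("cis gradient is exponential with source-independent decay length", {
  g <- spatial_grid(7, dx = 0.01)
  profs <- lapply(c(0.5, 2, 8), function(S)
    cis_steady_state(model_params(D = 1, alpha = 1, source_strength = S,
                                  model_kind = "cis"), g))
  # lambda = sqrt(D/alpha) = 1: P(x + 1)/P(x) = 1/e at every x, for every S
  for (prof in profs) {
    i <- seq_len(length(g$positions) - 100)
    expect_equal(prof$values[i + 100] / prof$values[i],
                 rep(exp(-1), length(i)))
  }
  # measured decay lengths identical across the S sweep (slope 0 vs A)
  lam <- vapply(profs, function(prof)
    extract_pole_fit(prof$positions, prof$values, fraction = exp(-1),
                     amplitude_band = 0)$decay_length, numeric(1))
  expect_equal(lam, rep(1, 3), tolerance = 1e-3)
})

test_that("profile CSV and summary JSON round-trip", {
  p <- par_unit()
  prof <- analytic_steady_state(p, grid_coarse())
  path <- tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$positions, prof$positions)
  expect_equal(back$values, prof$values)
  js <- jsonlite::fromJSON(summary_to_json(steady_state_summary(p)))
  expect_named(js, c("amplitude", "x0", "decay_length", "total_cortical",
                     "C", "params"))
  expect_equal(js$amplitude, 1)
  expect_equal(js$params$model_kind, "trans")
})

test_that("gradient_profile validates its invariants", {
  expect_error(gradient_profile(c(0.5, 1), c(1, 1)), "increasing from 0")
  expect_error(gradient_profile(c(0, 1, 1), c(1, 1, 1)), "increasing")
  expect_error(gradient_profile(c(0, 1), c(-1, 1)), "non-negative")
  expect_error(gradient_profile(c(0, 1), c(1, 1),
                                species_values = matrix(1, 2, 2)),
               "sum to values")
})
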