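# Discretization identities of the rate functions and convergence of the
# steady-state integrator against the re-derived closed forms.

test_that("uniform-profile rates reduce to pure decay for each model kind", {
  g <- grid_coarse()
  cval <- 0.7
  state <- gradient_profile(g$positions, rep(cval, g$n_points))
  rate_of <- function(kind, ...) {
    p <- model_params(D = 1, alpha = 2, source_strength = 0,
                      model_kind = kind, ...)
    rhs_simplified(state, p, g)
  }
  expect_equal(rate_of("trans"), rep(-2 * cval^2, g$n_points))
  expect_equal(rate_of("cis"), rep(-2 * cval, g$n_points))
  # cluster with P* -> infinity reduces to cis (D(P) -> D0, flat profile)
  expect_equal(rate_of("cluster", cluster_Pstar = 1e9),
               rate_of("cis"))
})

test_that("combined model with h = 0 is the trans model at half D0", {
  g <- grid_coarse()
  # non-trivial smooth profile so the diffusion term is exercised
  v <- 1 + exp(-g$positions / 1.3) + 0.1 * cos(g$positions)
  state <- gradient_profile(g$positions, v)
  pc <- model_params(D = 1, alpha = 2, source_strength = 1,
                     model_kind = "combined", cluster_D0 = 1,
                     cluster_Pstar = 3, cluster_h = 0)
  pt <- model_params(D = 0.5, alpha = 2, source_strength = 1,
                     model_kind = "trans")
  expect_equal(rhs_simplified(state, pc, g), rhs_simplified(state, pt, g))
})

test_that("detailed-model phosphorylation terms conserve total protein", {
  g <- grid_coarse()
  set.seed(7)
  ns <- 7
  sp <- matrix(runif(g$n_points * ns, 0.1, 1), g$n_points, ns)
  sp <- sp * exp(-g$positions / 2)  # decaying, spatially varying
  state <- gradient_profile(g$positions, rowSums(sp), sp)
  p <- par_detailed(beta = 0.8, kappa = 0.5 * (0:6))
  R <- rhs_detailed(state, p, g)
  # summed rates = D lap(P) + S - sum_i kappa_i P_i exactly
  src <- source_profile(g, p$source_strength, p$source_width)
  lapP <- pomgrad:::laplacian_r(rowSums(sp), g$dx)
  expect_equal(rowSums(R), lapP + src - as.vector(sp %*% p$kappa),
               tolerance = 1e-12)
})

test_that("pure diffusion conserves mass and uniform ladder rates are mass-action", {
  g <- grid_coarse()
  set.seed(1)
  sp <- matrix(0, g$n_points, 2)
  sp[, 1] <- 1 + exp(-(g$positions - 3)^2)
  state <- gradient_profile(g$positions, rowSums(sp), sp)
  # beta = 0 (tiny), kappa = 0, S = 0: only diffusion; total mass is conserved
  p0 <- model_params(D = 1, beta = 1e-30, kappa = c(0, 1e-30),
                     source_strength = 0, model_kind = "detailed")
  p0$kappa <- c(0, 0)
  R <- rhs_detailed(state, p0, g)
  expect_lt(abs(trapz(g$positions, rowSums(R))), 1e-10)

  # uniform P_0 = c, N = 1, kappa_0 = 0: rate into state 1 is beta c^2
  cval <- 0.6
  sp2 <- cbind(rep(cval, g$n_points), rep(0, g$n_points))
  st2 <- gradient_profile(g$positions, rowSums(sp2), sp2)
  p1 <- model_params(D = 1, beta = 0.9, kappa = c(0, 1),
                     source_strength = 0, model_kind = "detailed")
  R2 <- rhs_detailed(st2, p1, g)
  expect_equal(R2[, 2], rep(0.9 * cval^2, g$n_points))
})

test_that("linearly increasing kappa gives the stated summed-rate identity", {
  g <- grid_coarse()
  set.seed(2)
  ns <- 5
  sp <- matrix(runif(g$n_points * ns), g$n_points, ns) *
    exp(-g$positions / 1.5)
  state <- gradient_profile(g$positions, rowSums(sp), sp)
  kap <- 0.4 * (0:(ns - 1))
  p <- model_params(D = 1, beta = 0.7, kappa = kap, source_strength = 1,
                    source_width = 0.2, model_kind = "detailed")
  R <- rhs_detailed(state, p, g)
  src <- source_profile(g, 1, 0.2)
  lapP <- pomgrad:::laplacian_r(rowSums(sp), g$dx)
  isum <- as.vector(sp %*% (0:(ns - 1)))
  expect_equal(rowSums(R), lapP + src - 0.4 * isum, tolerance = 1e-12)
})

test_that("zero source converges to the zero profile", {
  sol <- solve_to_steady_state(par_unit(S = 0), grid_coarse())
  expect_true(all(sol$values == 0))
})

test_that("numerical trans steady state matches the closed form", {
  p <- par_unit(S = 2, w = 0.025)
  g <- spatial_grid(20, dx = 0.02)
  sol <- solve_to_steady_state(p, g, solver_settings(rel_tol = 1e-8))
  an <- analytic_steady_state(p, g)
  reg <- g$positions >= 3 * p$source_width & g$positions <= g$length / 2
  expect_lt(max(abs(sol$values[reg] - an$values[reg]) / an$values[reg]),
            0.01)
  # the R rate function evaluates to ~0 on the compiled solver's fixed point
  r <- rhs_simplified(sol, p, g)
  expect_lt(max(abs(r)) / max(sol$values), 1e-6)
})

test_that("steady-state detachment balances influx", {
  for (kind in c("trans", "cis")) {
    p <- model_params(D = 1, alpha = 3, source_strength = 1.7,
                      source_width = 0.1, model_kind = kind)
    g <- spatial_grid(12, dx = 0.02)
    sol <- solve_to_steady_state(p, g, solver_settings(rel_tol = 1e-8))
    dec <- if (kind == "trans") 3 * sol$values^2 else 3 * sol$values
    expect_equal(trapz(g$positions, dec), 1.7, tolerance = 0.01)
  }
})

test_that("halving dx changes the steady amplitude by < 0.5%", {
  p <- par_unit(w = 0.1)
  A <- vapply(c(0.04, 0.02), function(dx) {
    solve_to_steady_state(p, spatial_grid(7, dx = dx))$values[1]
  }, numeric(1))
  expect_lt(abs(A[2] / A[1] - 1), 0.005)
})

test_that("narrowing the source band converges monotonically to the closed form", {
  g <- spatial_grid(14, dx = 0.01)
  an <- analytic_steady_state(par_unit(), g)
  reg <- g$positions >= 0.6 & g$positions <= 7
  devs <- vapply(c(0.2, 0.1, 0.05), function(w) {
    sol <- solve_to_steady_state(par_unit(w = w), g,
                                 solver_settings(rel_tol = 1e-8))
    max(abs(sol$values[reg] - an$values[reg]) / an$values[reg])
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("explicit and semi-implicit schemes agree", {
  p <- par_unit(w = 0.1)
  g <- grid_coarse()
  s_ex <- solve_to_steady_state(p, g, solver_settings(scheme = "explicit"))
  s_im <- solve_to_steady_state(p, g)
  expect_lt(max(abs(s_ex$values - s_im$values)) / max(s_im$values), 1e-4)
})

test_that("detailed steady profile is monotone away from the source", {
  g <- spatial_grid(7, dx = 0.02)
  p <- par_detailed(beta = 1, kappa = 0.5 * (0:6))
  sol <- solve_to_steady_state(p, g)
  tail_idx <- g$positions > 3 * p$source_width
  expect_true(all(diff(sol$values[tail_idx]) <= 1e-10))
  expect_equal(rowSums(sol$species_values), sol$values)
})

test_that("non-convergence raises an informative error", {
  p <- par_unit()
  expect_error(
    solve_to_steady_state(p, grid_coarse(),
                          solver_settings(max_time = 0.5, rel_tol = 1e-12)),
    "convergence error")
})

test_that("effective exponent is exact for degenerate detachment laws", {
  # quadratic decay d = alpha P^2 regressed directly: gamma = 2, R^2 = 1
  P <- 1 / (1 + seq(0, 5, 0.01))^2
  f <- pomgrad:::fit_gamma_loglog(P, 6 * P^2)
  expect_equal(f$gamma, 2, tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  # constant kappa: d = kappa P exactly, gamma = 1, R^2 = 1
  g <- spatial_grid(7, dx = 0.02)
  p <- par_detailed(beta = 1, kappa = 0.5 * (0:3))
  p$kappa <- rep(0.5, 4)
  fg <- fit_effective_gamma(p, g)
  expect_equal(fg$gamma, 1, tolerance = 1e-6)
  expect_equal(fg$r_squared, 1, tolerance = 1e-9)
})

test_that("strong trans-phosphorylation puts gamma in (1.5, 2]", {
  g <- spatial_grid(16, dx = 0.02)
  p <- calibrate_beta(par_detailed(), g, ratio = 5)
  fg <- fit_effective_gamma(p, g, profile = attr(p, "profile"))
  expect_gt(fg$gamma, 1.5)
  expect_lte(fg$gamma, 2)
  expect_gt(fg$r_squared, 0.95)
  # calibration hit its target: beta * A close to 5 * kappa
  A <- max(attr(p, "profile")$values)
  expect_equal(p$beta * A / 0.5, 5, tolerance = 0.05)
})

test_that("insufficient dynamic range is reported", {
  expect_error(pomgrad:::fit_gamma_loglog(rep(1, 5), rep(1, 5)),
               "insufficient range")
})
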