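# The quantification stage: smoothing, pole-fit extraction, batching,
# weighted log-log regression, ratio identity, CV-vs-distance and the
# exponential/power-law comparison.

test_that("moving-average smoothing preserves constants, ramps and integrals", {
  x <- seq(0, 4, 0.1)
  expect_equal(smooth_profile(rep(2, 41), 0.3, 0.1), rep(2, 41))
  # window equal to one pixel is the identity
  v <- rnorm(41)
  expect_equal(smooth_profile(v, 0.1, 0.1), v)
  # linear ramp unchanged in the interior
  ramp <- 2 + 3 * x
  sm <- smooth_profile(ramp, 0.5, 0.1)
  expect_equal(sm[3:39], ramp[3:39])
  # integral preserved within 2%
  prof <- 1 / (1 + x)^2
  expect_equal(trapz(x, smooth_profile(prof, 0.3, 0.1)), trapz(x, prof),
               tolerance = 0.02)
  expect_error(smooth_profile(v, 0.05, 0.1), "window")
  expect_error(smooth_profile(v, 100, 0.1), "window larger")
})

test_that("pole fits recover closed-form amplitudes and decay lengths", {
  x <- seq(0, 4, 0.01)
  # power-law profile, pole-value amplitude: lambda = sqrt(2) - 1
  f <- extract_pole_fit(x, 1 / (1 + x)^2, fraction = 0.5,
                        amplitude_band = 0)
  expect_equal(f$amplitude, 1)
  expect_equal(f$decay_length, sqrt(2) - 1, tolerance = 1e-3)
  expect_false(f$censored)
  # exponential profile at fraction 1/e: lambda = 1
  f2 <- extract_pole_fit(x, exp(-x), fraction = exp(-1), amplitude_band = 0)
  expect_equal(f2$decay_length, 1, tolerance = 1e-3)
  # all-background profile: zero amplitude, censored decay length
  f3 <- extract_pole_fit(x, rep(0.2, length(x)), background = 0.2)
  expect_equal(f3$amplitude, 0)
  expect_true(f3$censored)
})

test_that("batch partition sizes follow the 5% rule and conserve poles", {
  mk <- function(n) tibble::tibble(
    tea4_amplitude = runif(n), amplitude = runif(n) + 1,
    decay_length = runif(n) + 0.5, cortical_total = runif(n) + 1,
    censored = FALSE)
  set.seed(8)
  b388 <- bin_by_tea4(mk(388), 0.05)
  expect_equal(nrow(b388), 20)
  expect_true(all(b388$member_count %in% c(19, 20)))
  expect_equal(sum(b388$member_count), 388)
  # larger batches come first
  expect_true(all(diff(b388$member_count) <= 0))
  b100 <- bin_by_tea4(mk(100), 0.05)
  expect_true(all(b100$member_count == 5))
  # n = 20 at 5%: singleton batches get NA SEMs (equal-weight fallback)
  b20 <- bin_by_tea4(mk(20), 0.05)
  expect_equal(nrow(b20), 20)
  expect_true(all(is.na(b20$amplitude_sem)))
  expect_error(bin_by_tea4(mk(0)), "insufficient data")
})

test_that("batches are ordered blocks of the Tea4 axis", {
  set.seed(3)
  pf <- tibble::tibble(tea4_amplitude = runif(97), amplitude = runif(97) + 1,
                       decay_length = runif(97) + 0.5,
                       cortical_total = 1, censored = FALSE)
  b <- bin_by_tea4(pf, 0.05)
  expect_true(all(diff(b$tea4_mean) > 0))
})

test_that("weighted log-log regression is exact on power laws and applies weights", {
  x <- c(1, 2, 4, 8, 16, 32)
  f <- weighted_loglog_regression(x, 3 * x^(-1 / 2))
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(f$intercept, log10(3), tolerance = 1e-12)
  expect_true(f$ci_2se[1] <= f$slope && f$slope <= f$ci_2se[2])
  # an outlier with a huge SEM is effectively ignored
  y <- 3 * x^(-1 / 2)
  y[6] <- 10 * y[6]
  sem <- rep(0.001 * y[1], 6)
  sem[6] <- 1e6
  fw <- weighted_loglog_regression(x, y, sem)
  expect_equal(fw$slope, -0.5, tolerance = 1e-3)
  # degenerate SEMs fall back to equal weights with a warning
  expect_warning(weighted_loglog_regression(x, y, rep(0, 6)), "equal weights")
  expect_error(weighted_loglog_regression(c(-1, 2, 3), c(1, 2, 3)),
               "domain error")
  expect_error(weighted_loglog_regression(1:2, 1:2), "insufficient data")
})

test_that("ratio regression slope equals the amplitude slope minus one", {
  set.seed(12)
  fits <- tibble::tibble(tea4_amplitude = exp(rnorm(50)),
                         amplitude = exp(rnorm(50)) + 0.5)
  fa <- weighted_loglog_regression(fits$tea4_amplitude, fits$amplitude)
  fr <- ratio_regression(fits)
  expect_equal(fr$slope, fa$slope - 1, tolerance = 1e-10)
  # proportional data: ratio slope exactly zero
  prop <- tibble::tibble(tea4_amplitude = exp(rnorm(20)))
  prop$amplitude <- 3 * prop$tea4_amplitude
  expect_equal(ratio_regression(prop)$slope, 0, tolerance = 1e-12)
})

test_that("CV is zero for identical profiles and constant for scaled exponentials", {
  x <- seq(0, 4, 0.1)
  mk_table <- function(amps) {
    rows <- lapply(seq_along(amps), function(i)
      tibble::tibble(cell_id = i, pole_id = 1, position_um = x,
                     pom1 = amps[i] * exp(-x), tea4 = amps[i]))
    out <- do.call(rbind, rows)
    class(out) <- c("profile_table", class(out))
    out
  }
  cv_id <- cv_vs_distance(mk_table(rep(2, 12)))
  expect_true(all(cv_id$cv == 0))
  # multiplicative family: SD/mean independent of position
  set.seed(4)
  cv_sc <- cv_vs_distance(mk_table(exp(rnorm(40, 0, 0.3))))
  expect_lt(diff(range(cv_sc$cv)), 1e-10)
  expect_error(cv_vs_distance(mk_table(rep(1, 4))), "insufficient data")
})

test_that("trans-model families lose relative variability away from the pole", {
  tab <- sample_population(population_spec(seed = 17))
  spec <- attr(tab, "spec")
  cv <- cv_vs_distance(tab, background = spec$background)
  i0 <- which(cv$position_um == 0)
  i2 <- which(cv$position_um == 2)
  expect_lt(cv$cv[i2], cv$cv[i0])
})

test_that("self-generated profiles are recovered by their own model family", {
  x <- seq(0, 2, 0.05)
  pw <- compare_exponential_powerlaw(x, 2 / (x + 1.2)^2)
  expect_lt(pw$power_law$rms, 1e-8)
  expect_equal(pw$power_law$x0, 1.2, tolerance = 1e-6)
  ex <- compare_exponential_powerlaw(x, 1.5 * exp(-x / 0.8))
  expect_lt(ex$exponential$rms, 1e-8)
  expect_equal(ex$exponential$lambda, 0.8, tolerance = 1e-6)
})

test_that("noisy trans profiles fit comparably well with both families", {
  set.seed(23)
  tab <- sample_population(population_spec(n_cells = 8, seed = 23))
  spec <- attr(tab, "spec")
  one <- tab[tab$cell_id == 1 & tab$pole_id == 1, ]
  cmp <- compare_exponential_powerlaw(one$position_um,
                                      one$pom1 - spec$background,
                                      range = c(0, 2))
  expect_gt(cmp$rms_ratio, 0.5)
  expect_lt(cmp$rms_ratio, 2)
})

test_that("Bartlett comparison matches the closed-form statistic", {
  set.seed(31)
  a <- rnorm(100, sd = 2)
  b <- rnorm(100, sd = 1)
  res <- bartlett_compare(a, b)
  # independent closed form for two groups
  k <- 2; n <- c(100, 100); v <- c(var(a), var(b))
  sp2 <- sum((n - 1) * v) / (sum(n) - k)
  stat <- ((sum(n) - k) * log(sp2) - sum((n - 1) * log(v))) /
    (1 + (sum(1 / (n - 1)) - 1 / (sum(n) - k)) / (3 * (k - 1)))
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)   # fourfold variance ratio at n = 100
  # identical samples: statistic 0, p = 1
  same <- bartlett_compare(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(bartlett_compare(a[1:2], b), "insufficient data")
})

test_that("population analysis is self-consistent", {
  tab <- sample_population(population_spec(n_cells = 40, seed = 19))
  an <- analyze_population(tab)
  expect_equal(sum(an$batches$member_count), nrow(an$pole_fits))
  expect_equal(nrow(an$pole_fits), 160)
  # the ratio identity carries through the batch regressions
  expect_equal(an$regressions$ratio_vs_tea4$slope,
               an$regressions$pom1_vs_tea4$slope - 1, tolerance = 0.1)
})
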