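#' Smooth a profile with a centered moving average
#'
#' Edge bins are truncated (partial windows), so profile length is
#' preserved and the integral changes by at most a couple of percent.
#'
#' @param values Numeric profile values.
#' @param window Smoothing window in um.
#' @param pixel_size Sampling interval in um.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(values, window = 0.3, pixel_size = 0.1) {
  if (window < pixel_size)
    stop("invalid parameter: window must be >= pixel_size", call. = FALSE)
  k <- 2 * floor(window / (2 * pixel_size)) + 1  # odd pixel count
  if (k >= 2 * length(values))
    stop("invalid parameter: window larger than profile extent", call. = FALSE)
  if (k == 1) return(values)
  as.numeric(zoo::rollapply(zoo::zoo(values), width = k, FUN = mean,
                            partial = TRUE, align = "center"))
}

#' Extract pole quantities from a single smoothed profile
#'
#' Amplitude is the mean of the background-subtracted profile over the
#' first `amplitude_band` um; the decay length is the linearly interpolated
#' position where the background-subtracted profile first drops to
#' `fraction` of that amplitude; the cortical total is the trapezoidal
#' integral of the background-subtracted profile. Profiles that never
#' cross the fraction within range get `censored = TRUE` (and are excluded
#' from downstream regressions, but counted).
#'
#' @param positions Arclength coordinates (um), ascending from 0.
#' @param values Smoothed profile values.
#' @param fraction Decay-length threshold fraction in (0, 1).
#' @param background Additive background to subtract.
#' @param amplitude_band Pole band (um) over which the amplitude is
#'   averaged.
#' @return List with `amplitude`, `decay_length`, `cortical_total`,
#'   `censored`.
#' @examples
#' x <- seq(0, 4, 0.01)
#' extract_pole_fit(x, 1 / (1 + x)^2)$decay_length  # about sqrt(2) - 1
#' @export
extract_pole_fit <- function(positions, values, fraction = 0.5,
                             background = 0, amplitude_band = 0.3) {
  stopifnot(length(positions) == length(values), background >= 0)
  if (fraction <= 0 || fraction >= 1)
    stop("invalid parameter: fraction must lie in (0, 1)", call. = FALSE)
  v <- values - background
  amp <- mean(v[positions <= positions[1] + amplitude_band + 1e-9])
  thr <- fraction * amp
  censored <- TRUE
  lambda <- NA_real_
  if (amp > 0) {
    below <- which(v <= thr)
    below <- below[below > 1]
    if (length(below)) {
      i <- below[1]
      # linear interpolation between the straddling samples
      x1 <- positions[i - 1]; x2 <- positions[i]
      y1 <- v[i - 1]; y2 <- v[i]
      lambda <- if (y1 == y2) x2 else x1 + (y1 - thr) * (x2 - x1) / (y1 - y2)
      censored <- FALSE
    }
  }
  list(amplitude = amp, decay_length = lambda,
       cortical_total = trapz(positions, v), censored = censored)
}

#' Partition poles into contiguous batches by Tea4 amplitude
#'
#' Poles are sorted by Tea4 amplitude (ascending) and split into
#' `ceiling(1/batch_fraction)` contiguous batches whose sizes differ by at
#' most one, larger batches first. Per-batch means and standard errors of
#' the pole quantities are computed; batches of a single pole get `NA`
#' standard errors (flagged downstream by the equal-weight fallback).
#'
#' @param pole_fits A data frame with one row per pole carrying at least
#'   `tea4_amplitude`, `amplitude`, `decay_length`, `cortical_total` and
#'   `censored` (as produced by [analyze_population()]).
#' @param batch_fraction Fraction of poles per batch (default 0.05, i.e.
#'   5% batches: 388 poles give 20 batches of 19 or 20).
#' @return A tibble of class `batch_profiles`, one row per batch:
#'   `member_count`, `amplitude_mean/sem`, `decay_length_mean/sem`,
#'   `tea4_mean/sem`, `cortical_mean/sem`, `censored_members`.
#' @export
bin_by_tea4 <- function(pole_fits, batch_fraction = 0.05) {
  if (nrow(pole_fits) == 0)
    stop("insufficient data: empty pole table", call. = FALSE)
  if (batch_fraction <= 0 || batch_fraction > 1)
    stop("invalid parameter: batch_fraction must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(pole_fits$tea4_amplitude)))
    stop("every pole needs a tea4_amplitude", call. = FALSE)
  ord <- order(pole_fits$tea4_amplitude)
  n <- length(ord)
  nb <- ceiling(1 / batch_fraction)
  nb <- min(nb, n)
  base <- n %/% nb
  extra <- n %% nb
  sizes <- c(rep(base + 1L, extra), rep(base, nb - extra))  # larger first
  idx <- rep(seq_len(nb), times = sizes)
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  rows <- lapply(seq_len(nb), function(b) {
    d <- pole_fits[ord[idx == b], ]
    lam <- d$decay_length[!d$censored]
    tibble::tibble(
      batch = b, member_count = nrow(d),
      amplitude_mean = mean(d$amplitude), amplitude_sem = sem(d$amplitude),
      decay_length_mean = if (length(lam)) mean(lam) else NA_real_,
      decay_length_sem = sem(lam),
      tea4_mean = mean(d$tea4_amplitude), tea4_sem = sem(d$tea4_amplitude),
      cortical_mean = mean(d$cortical_total), cortical_sem = sem(d$cortical_total),
      censored_members = sum(d$censored))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("batch_profiles", class(out))
  out
}

#' Inverse-variance-weighted log-log regression
#'
#' Weighted least squares of `log10(y)` on `log10(x)`; each point's weight
#' is the inverse variance of its log10 mean, with
#' `var(log10 y) = (sem / (y ln 10))^2`. When standard errors are missing
#' or zero the fit falls back to equal weights (with a warning). All
#' logarithms are base 10.
#'
#' @param x,y Positive values.
#' @param y_sem Optional standard errors of `y` (same length).
#' @return Object of class `loglog_fit`: `slope`, `slope_se`, `intercept`,
#'   `weights`, `ci_2se` (slope +/- 2 SE), `p_value` (for slope = 0),
#'   `r_squared`, `n`.
#' @examples
#' f <- weighted_loglog_regression(1:10, 3 * (1:10)^-0.5)
#' f$slope  # -0.5
#' @export
weighted_loglog_regression <- function(x, y, y_sem = NULL) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(y_sem)) y_sem <- y_sem[keep]
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0) || any(y <= 0))
    stop(sprintf("domain error: nonpositive values at points %s",
                 paste(which(x <= 0 | y <= 0), collapse = ", ")),
         call. = FALSE)
  if (length(x) < 3)
    stop("insufficient data: need at least 3 points", call. = FALSE)
  w <- NULL
  if (!is.null(y_sem)) {
    if (any(!is.finite(y_sem)) || any(y_sem <= 0)) {
      warning("missing or zero SEMs: falling back to equal weights")
    } else {
      w <- (y * log(10) / y_sem)^2
    }
  }
  lx <- log10(x); ly <- log10(y)
  fit <- if (is.null(w)) lm(ly ~ lx) else lm(ly ~ lx, weights = w)
  # noiseless model sweeps legitimately produce perfect fits; summary.lm's
  # warning about them is not informative here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  structure(list(slope = slope, slope_se = se,
                 intercept = unname(coef(fit)[1]),
                 weights = if (is.null(w)) rep(1, length(x)) else w,
                 ci_2se = c(slope - 2 * se, slope + 2 * se),
                 p_value = sm$coefficients[2, 4],
                 r_squared = sm$r.squared, n = length(x)),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "<loglog_fit> slope %.4f +/- %.4f (2SE band [%.4f, %.4f]), R^2 %.3f, p %.3g, n %d\n",
    x$slope, x$slope_se, x$ci_2se[1], x$ci_2se[2], x$r_squared, x$p_value,
    x$n))
  invisible(x)
}

#' Regression of the Pom1/Tea4 ratio on Tea4
#'
#' Fits `log10(amplitude / tea4_amplitude)` against `log10(tea4_amplitude)`.
#' With equal weights the slope algebraically equals the Pom1-vs-Tea4
#' amplitude slope minus one; a negative slope is the signature of
#' sub-linear (buffered) scaling of the gradient amplitude with its
#' source, a positive slope the signature of the traffic-jam (cluster)
#' alternative.
#'
#' @param fits A data frame with `amplitude` and `tea4_amplitude` columns
#'   (per pole or per batch; for batches pass `amplitude_mean`/`tea4_mean`
#'   renamed accordingly, or use the columns of [bin_by_tea4()] directly
#'   via `analyze_population`).
#' @param y_sem Optional SEMs of the ratio for weighting.
#' @return A `loglog_fit`.
#' @export
ratio_regression <- function(fits, y_sem = NULL) {
  a <- if ("amplitude" %in% names(fits)) fits$amplitude else fits$amplitude_mean
  t <- if ("tea4_amplitude" %in% names(fits)) fits$tea4_amplitude else fits$tea4_mean
  weighted_loglog_regression(t, a / t, y_sem)
}

#' Coefficient of variation of Pom1 across poles, per position
#'
#' CV(x) = SD/mean of the background-subtracted Pom1 intensity across
#' poles at each sampled position. For trans-model populations with
#' variable source strength the CV decreases away from the pole: profiles
#' converge toward the source-independent far-field form, which is what
#' buffering looks like position-wise.
#'
#' @param table A `profile_table` (positions must align across poles).
#' @param background Additive background to subtract.
#' @return Tibble with `position_um`, `mean`, `sd`, `cv`, `n`.
#' @export
cv_vs_distance <- function(table, background = 0) {
  polelist <- pole_split(table)
  if (length(polelist) < 10)
    stop("insufficient data: need at least 10 poles", call. = FALSE)
  pos <- polelist[[1]]$position_um
  same <- vapply(polelist, function(d)
    length(d$position_um) == length(pos) && all(d$position_um == pos),
    logical(1))
  if (!all(same))
    stop("alignment error: positions differ across poles", call. = FALSE)
  m <- vapply(polelist, function(d) d$pom1 - background,
              numeric(length(pos)))
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  tibble::tibble(position_um = pos, mean = mu, sd = s, cv = s / mu,
                 n = ncol(m))
}

#' Compare exponential and power-law fits of one profile
#'
#' Least-squares fits of \eqn{A e^{-x/\lambda}} and \eqn{C/(x+x_0)^2} over
#' a configured range. Individual noisy profiles constrain the functional
#' form only weakly — both families fit comparably well — which is why
#' model discrimination must come from population-level scaling, not
#' profile shape.
#'
#' @param positions,values Background-subtracted profile (positive over the
#'   fit range).
#' @param range Length-2 fit window in um.
#' @return List with `exponential` (A, lambda, rms), `power_law` (C, x0,
#'   rms), `rms_ratio` (exponential/power-law) and `failed` flags.
#' @export
compare_exponential_powerlaw <- function(positions, values,
                                         range = c(0, 2)) {
  keep <- positions >= range[1] & positions <= range[2] & values > 0
  x <- positions[keep]; y <- values[keep]
  if (length(x) < 5)
    stop("insufficient data: fewer than 5 positive points in range",
         call. = FALSE)
  out <- list(exponential = NULL, power_law = NULL, rms_ratio = NA_real_,
              failed = character(0))
  rms <- function(r) sqrt(mean(r^2))
  # exponential: log-linear start
  lf <- lm(log(y) ~ x)
  st_exp <- list(A = exp(coef(lf)[[1]]), lambda = max(-1 / coef(lf)[[2]], 0.05))
  fit_e <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-x / lambda), start = st_exp,
                      lower = c(1e-12, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit_e)) out$failed <- c(out$failed, "exponential")
  else out$exponential <- list(A = coef(fit_e)[["A"]],
                               lambda = coef(fit_e)[["lambda"]],
                               rms = rms(resid(fit_e)))
  # power law: start from amplitude and exponential length scale
  st_pow <- list(C = y[1] * (st_exp$lambda * 2.414)^2,
                 x0 = st_exp$lambda * 2.414)
  fit_p <- tryCatch(
    minpack.lm::nlsLM(y ~ C / (x + x0)^2, start = st_pow,
                      lower = c(1e-12, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit_p)) out$failed <- c(out$failed, "power_law")
  else out$power_law <- list(C = coef(fit_p)[["C"]], x0 = coef(fit_p)[["x0"]],
                             rms = rms(resid(fit_p)))
  if (!is.null(out$exponential) && !is.null(out$power_law))
    out$rms_ratio <- out$exponential$rms / out$power_law$rms
  out
}

#' Bartlett test for equal variance of two log-amplitude samples
#'
#' On the log scale, variance measures relative variability, so this is
#' the test of whether one species' pole levels fluctuate more, in
#' relative terms, than another's.
#'
#' @param log_a,log_b Numeric samples (already log-transformed), each of
#'   length >= 3.
#' @return List with `statistic`, `p_value`, `df` (1 for two groups) and
#'   the two sample variances.
#' @export
bartlett_compare <- function(log_a, log_b) {
  if (length(log_a) < 3 || length(log_b) < 3)
    stop("insufficient data: each sample needs n >= 3", call. = FALSE)
  if (var(log_a) == 0 && var(log_b) == 0)
    stop("degenerate test: both samples have zero variance", call. = FALSE)
  bt <- stats::bartlett.test(list(log_a, log_b))
  list(statistic = unname(bt$statistic), p_value = bt$p.value,
       df = unname(bt$parameter),
       variances = c(var(log_a), var(log_b)))
}

#' Full quantification of a profile population
#'
#' Runs the measurement pipeline on a table of paired Pom1/Tea4 cortical
#' profiles: per-pole smoothing, background subtraction, amplitude /
#' decay-length / cortical-total extraction for both channels, 5%-batch
#' averaging along the Tea4 amplitude axis, and the inverse-variance
#' weighted log-log regressions that quantify the gradient's two buffering
#' properties (amplitude-decay-length anticorrelation; sub-linear Pom1
#' scaling with Tea4), plus the amplitude-vs-cortical-total scaling and
#' the Pom1/Tea4 ratio regression.
#'
#' @param table A `profile_table`.
#' @param fraction Decay-length threshold fraction.
#' @param window Smoothing window (um).
#' @param amplitude_band Pole band for the amplitude (um).
#' @param batch_fraction Batch size as a fraction of poles.
#' @param background `NULL` for the per-cell minimum of the smoothed
#'   profile (estimated separately per channel), or a constant override.
#'   For tables produced by [sample_population()] the generator's constant
#'   background is recorded in the spec and used automatically.
#' @param per_pole Also regress on per-pole values (besides batch means).
#' @return Object of class `gradient_analysis`: `pole_fits`, `batches`,
#'   `regressions` (named `loglog_fit`s: `lambda_vs_amplitude`,
#'   `pom1_vs_tea4`, `amplitude_vs_cortical`, `ratio_vs_tea4`), censoring
#'   counts and the settings used.
#' @export
analyze_population <- function(table, fraction = 0.5, window = 0.3,
                               amplitude_band = 0.3, batch_fraction = 0.05,
                               background = NULL, per_pole = FALSE) {
  spec <- attr(table, "spec")
  if (is.null(background)) {
    if (!is.null(spec)) background <- spec$background
    else if (!is.null(attr(table, "background")))
      background <- attr(table, "background")
  }
  polelist <- pole_split(table)
  if (length(polelist) < 2)
    stop("insufficient data: need at least 2 poles", call. = FALSE)
  pixel <- diff(polelist[[1]]$position_um)[1]
  cellid <- vapply(strsplit(names(polelist), ".", fixed = TRUE), `[`,
                   character(1), 1)

  sm_p <- lapply(polelist, function(d) smooth_profile(d$pom1, window, pixel))
  sm_t <- lapply(polelist, function(d) smooth_profile(d$tea4, window, pixel))

  bg_for <- function(smlist) {
    if (!is.null(background)) {
      setNames(rep(background, length(unique(cellid))), unique(cellid))
    } else {
      mins <- vapply(smlist, min, numeric(1))
      tapply(mins, cellid, min)
    }
  }
  bg_p <- bg_for(sm_p)
  bg_t <- bg_for(sm_t)

  rows <- lapply(seq_along(polelist), function(i) {
    d <- polelist[[i]]
    fp <- extract_pole_fit(d$position_um, sm_p[[i]], fraction,
                           bg_p[[cellid[i]]], amplitude_band)
    ft <- extract_pole_fit(d$position_um, sm_t[[i]], fraction,
                           bg_t[[cellid[i]]], amplitude_band)
    tibble::tibble(cell_id = cellid[i],
                   pole = names(polelist)[i],
                   amplitude = fp$amplitude, decay_length = fp$decay_length,
                   cortical_total = fp$cortical_total,
                   censored = fp$censored,
                   tea4_amplitude = ft$amplitude)
  })
  pole_fits <- do.call(rbind, rows)

  batches <- bin_by_tea4(pole_fits, batch_fraction)
  ok <- !is.na(batches$decay_length_mean)
  regressions <- list(
    lambda_vs_amplitude = weighted_loglog_regression(
      batches$amplitude_mean[ok], batches$decay_length_mean[ok],
      batches$decay_length_sem[ok]),
    pom1_vs_tea4 = weighted_loglog_regression(
      batches$tea4_mean, batches$amplitude_mean, batches$amplitude_sem),
    amplitude_vs_cortical = weighted_loglog_regression(
      batches$cortical_mean, batches$amplitude_mean, batches$amplitude_sem),
    ratio_vs_tea4 = ratio_regression(
      tibble::tibble(amplitude = batches$amplitude_mean,
                     tea4_amplitude = batches$tea4_mean)))
  if (per_pole) {
    keep <- !pole_fits$censored
    regressions$lambda_vs_amplitude_poles <- weighted_loglog_regression(
      pole_fits$amplitude[keep], pole_fits$decay_length[keep])
    regressions$pom1_vs_tea4_poles <- weighted_loglog_regression(
      pole_fits$tea4_amplitude, pole_fits$amplitude)
  }
  structure(list(pole_fits = pole_fits, batches = batches,
                 regressions = regressions,
                 n_censored = sum(pole_fits$censored),
                 settings = list(fraction = fraction, window = window,
                                 amplitude_band = amplitude_band,
                                 batch_fraction = batch_fraction,
                                 background = background)),
            class = "gradient_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gradient_analysis <- function(x, ...) {
  r <- x$regressions
  cat("<gradient_analysis>", nrow(x$pole_fits), "poles,",
      nrow(x$batches), "batches,", x$n_censored, "censored decay lengths\n")
  cat(sprintf("  decay length vs amplitude : slope %.3f +/- %.3f (model: -1/2)\n",
              r$lambda_vs_amplitude$slope, r$lambda_vs_amplitude$slope_se))
  cat(sprintf("  Pom1 vs Tea4 amplitude    : slope %.3f +/- %.3f (model: 2/3)\n",
              r$pom1_vs_tea4$slope, r$pom1_vs_tea4$slope_se))
  cat(sprintf("  amplitude vs cortical total: slope %.3f +/- %.3f (model: 2)\n",
              r$amplitude_vs_cortical$slope, r$amplitude_vs_cortical$slope_se))
  cat(sprintf("  Pom1/Tea4 ratio vs Tea4   : slope %.3f (negative = buffered)\n",
              r$ratio_vs_tea4$slope))
  invisible(x)
}
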