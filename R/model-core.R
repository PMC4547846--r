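#' Closed-form steady state of the trans-phosphorylation gradient
#'
#' The simplified model with intermolecular (trans) auto-phosphorylation,
#' \deqn{\partial_t P = D \partial_x^2 P - \alpha P^2 + S \delta(x),}
#' has, on the half-line with a point influx S at the pole, the power-law
#' steady state \deqn{P(x) = C/(x + x_0)^2, \quad C = 6D/\alpha,} where the
#' length scale \eqn{x_0} is fixed by flux balance
#' \eqn{2DC/x_0^3 = S}. The profile decays as a power of the distance from
#' the source, in contrast to the exponential profile of the cis model
#' (see [cis_steady_state()]).
#'
#' @param params A [model_params()] with `model_kind = "trans"`.
#' @param grid A [spatial_grid()].
#' @return A [gradient_profile()] with the steady state sampled on the grid.
#' @examples
#' p <- model_params(D = 1, alpha = 6, source_strength = 2)  # C = 1, x0 = 1
#' prof <- analytic_steady_state(p, spatial_grid(7, dx = 0.05))
#' prof$values[1]    # amplitude 1
#' @export
analytic_steady_state <- function(params, grid) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "spatial_grid"))
  if (params$model_kind != "trans")
    stop("analytic_steady_state applies to the trans model; see cis_steady_state",
         call. = FALSE)
  if (params$source_strength == 0)
    return(gradient_profile(grid$positions, rep(0, grid$n_points)))
  s <- steady_state_summary(params)
  gradient_profile(grid$positions, s$C / (grid$positions + s$x0)^2)
}

#' Pole-level summary of the trans-model steady state
#'
#' Computes the mutually consistent closed-form quantities of the power-law
#' steady state: prefactor \eqn{C = 6D/\alpha}, length scale
#' \eqn{x_0 = (12 D^2 / (\alpha S))^{1/3}}, amplitude \eqn{A = C/x_0^2},
#' total cortical protein \eqn{P_{tot} = C/x_0} (so
#' \eqn{P_{tot} = \sqrt{C A}}, the 1/2 power law between amplitude and
#' overall cortical signal), and the decay length at the given fraction.
#'
#' @inheritParams analytic_steady_state
#' @param fraction Fraction of the amplitude defining the decay length
#'   (default half-maximum).
#' @return Object of class `steady_state_summary` with fields `amplitude`,
#'   `x0`, `decay_length`, `total_cortical`, `C` and a `params` echo.
#' @examples
#' steady_state_summary(model_params(D = 1, alpha = 6, source_strength = 2))
#' @export
steady_state_summary <- function(params, fraction = 0.5) {
  stopifnot(inherits(params, "model_params"))
  if (params$model_kind != "trans")
    stop("steady_state_summary applies to the trans model", call. = FALSE)
  if (params$source_strength <= 0)
    stop("degenerate summary: an all-zero profile has no amplitude (S = 0)",
         call. = FALSE)
  C <- 6 * params$D / params$alpha
  x0 <- (2 * params$D * C / params$source_strength)^(1 / 3)
  structure(list(amplitude = C / x0^2, x0 = x0,
                 decay_length = decay_length_from_x0(x0, fraction),
                 total_cortical = C / x0, C = C, fraction = fraction,
                 params = params),
            class = "steady_state_summary")
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat(sprintf(
    "<steady_state_summary> A = %.4g, x0 = %.4g um, lambda = %.4g um (fraction %g),\n  P_tot = %.4g, C = %.4g\n",
    x$amplitude, x$x0, x$decay_length, x$fraction, x$total_cortical, x$C))
  invisible(x)
}

#' Serialize a steady-state summary to JSON
#'
#' @param x A `steady_state_summary`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
summary_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "steady_state_summary"))
  obj <- list(amplitude = x$amplitude, x0 = x$x0,
              decay_length = x$decay_length, total_cortical = x$total_cortical,
              C = x$C,
              params = x$params[c("D", "alpha", "gamma", "beta", "kappa",
                                  "source_strength", "source_width",
                                  "model_kind")])
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Decay length of the power-law profile at a threshold fraction
#'
#' The decay length \eqn{\lambda} is the distance at which the concentration
#' drops to `fraction` of the amplitude. For \eqn{P = C/(x+x_0)^2},
#' \eqn{\lambda = x_0 (fraction^{-1/2} - 1)}; it is proportional to
#' \eqn{x_0}, hence \eqn{\lambda \propto A^{-1/2}} at fixed C — the
#' amplitude-decay-length anticorrelation with log-log slope -1/2.
#'
#' @param x0 Length scale of the power-law profile (um), > 0.
#' @param fraction Threshold fraction in (0, 1).
#' @return Decay length in um.
#' @examples
#' decay_length_from_x0(1, 0.5)  # sqrt(2) - 1
#' @export
decay_length_from_x0 <- function(x0, fraction = 0.5) {
  if (any(x0 <= 0)) stop("invalid parameter: x0 must be > 0", call. = FALSE)
  if (any(fraction <= 0 | fraction >= 1))
    stop("invalid parameter: fraction must lie in (0, 1)", call. = FALSE)
  x0 * (fraction^(-1 / 2) - 1)
}

#' Shift of a threshold position under a fold-change of the source
#'
#' For the trans model, increasing the influx S by a factor k moves the
#' position where the profile crosses a fixed concentration threshold by
#' \deqn{\Delta x = x_0 (1 - k^{-1/3}),} independent of the threshold and
#' always less than \eqn{x_0}: positional information downstream of the
#' gradient is buffered against source fluctuations.
#'
#' @inheritParams analytic_steady_state
#' @param k Fold-change of the source strength (> 0).
#' @param threshold Threshold concentration; must lie below the amplitude of
#'   both the original and the scaled gradient (the closed form does not
#'   depend on it, but a crossing must exist for the displacement to be
#'   meaningful).
#' @return Displacement of the threshold position (um, positive toward the
#'   cell middle for k > 1).
#' @examples
#' p <- model_params(D = 1, alpha = 6, source_strength = 2)
#' threshold_shift(p, k = 8, threshold = 0.1)  # x0 / 2
#' @export
threshold_shift <- function(params, k, threshold) {
  stopifnot(inherits(params, "model_params"), k > 0)
  s1 <- steady_state_summary(params)
  p2 <- params
  p2$source_strength <- params$source_strength * k
  s2 <- steady_state_summary(p2)
  if (threshold >= min(s1$amplitude, s2$amplitude))
    stop("no crossing: threshold must lie below both gradient amplitudes",
         call. = FALSE)
  s1$x0 * (1 - k^(-1 / 3))
}

#' Numerically locate the threshold-position shift between two steady states
#'
#' Companion check to the closed-form [threshold_shift()]: solves the trans
#' model at S and at k S, locates the interpolated positions where each
#' numerical profile crosses the threshold, and returns their difference.
#' The source band is narrowed to a tenth of the smaller gradient length
#' scale (and the grid refined accordingly) so both solutions sit in the
#' point-flux regime the closed form describes.
#'
#' @inheritParams threshold_shift
#' @param settings A [solver_settings()].
#' @param max_dx Grid-spacing cap (um).
#' @return List with `shift`, the two crossing positions, `x0` of the
#'   unscaled gradient and the `source_width`/`dx` used.
#' @export
threshold_shift_numeric <- function(params, k, threshold,
                                    settings = solver_settings(),
                                    max_dx = 0.01) {
  stopifnot(params$model_kind == "trans", k > 0)
  s1 <- steady_state_summary(params)
  p2 <- params
  p2$source_strength <- params$source_strength * k
  s2 <- steady_state_summary(p2)
  if (threshold >= min(s1$amplitude, s2$amplitude))
    stop("no crossing: threshold must lie below both gradient amplitudes",
         call. = FALSE)
  w <- min(params$source_width, s1$x0 / 10, s2$x0 / 10)
  dx <- min(max_dx, w / 2.5)
  L <- max(2 * sqrt(s1$C / threshold), 5 * s1$x0, 2)
  grid <- spatial_grid(L, dx = dx)
  params$source_width <- w
  p2$source_width <- w
  crossing <- function(sol) {
    i <- which(sol$values < threshold)[1]
    if (is.na(i) || i < 2)
      stop("no crossing located on the numerical profile", call. = FALSE)
    x1 <- sol$positions[i - 1]; x2 <- sol$positions[i]
    y1 <- sol$values[i - 1]; y2 <- sol$values[i]
    x1 + (y1 - threshold) * (x2 - x1) / (y1 - y2)
  }
  c1 <- crossing(solve_to_steady_state(params, grid, settings))
  c2 <- crossing(solve_to_steady_state(p2, grid, settings))
  list(shift = c2 - c1, crossing_base = c1, crossing_scaled = c2,
       x0 = s1$x0, source_width = w, dx = dx)
}

#' Exponential steady state of the cis-phosphorylation model
#'
#' With intramolecular (cis) phosphorylation the decay term is linear,
#' \eqn{-\alpha P}, and the steady state under a point influx S is the
#' exponential \eqn{A e^{-x/\lambda}} with \eqn{\lambda = \sqrt{D/\alpha}}
#' and \eqn{A = S/\sqrt{D \alpha}}. The decay length is independent of the
#' source strength: this is the unbuffered reference gradient.
#'
#' @param params A [model_params()] with `model_kind = "cis"`.
#' @param grid A [spatial_grid()].
#' @return A [gradient_profile()].
#' @export
cis_steady_state <- function(params, grid) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "spatial_grid"))
  if (params$model_kind != "cis")
    stop("cis_steady_state requires model_kind = 'cis'", call. = FALSE)
  lambda <- sqrt(params$D / params$alpha)
  A <- params$source_strength / sqrt(params$D * params$alpha)
  gradient_profile(grid$positions, A * exp(-grid$positions / lambda))
}

#' Fit the outer power-law form to a numerical trans steady state
#'
#' Numerical steady states use a narrow source band rather than a point
#' flux, so the first fraction of a micrometre is flattened relative to the
#' closed form. Away from the band the solution is exactly
#' \eqn{C/(x + x_0)^2}; this routine recovers \eqn{(C, x_0)} by
#' least squares on log-concentration over `x_range`, profiled over
#' \eqn{x_0} (C has a closed-form solution given \eqn{x_0}). Pole
#' quantities (amplitude, half-line cortical total) read off a band-source
#' solution should come from these fitted parameters.
#'
#' @param profile A [gradient_profile()] from the trans (or combined) model.
#' @param x_range Length-2 fit window in um; choose the lower end beyond
#'   about 3 source widths and the upper end clear of the far boundary.
#' @param fraction Decay-length fraction passed through to the summary.
#' @return A list with `C`, `x0`, `amplitude`, `decay_length`,
#'   `total_cortical` (half-line integral C/x0) and `rms_log_resid`.
#' @export
fit_power_profile <- function(profile, x_range = c(0.3, 3), fraction = 0.5) {
  stopifnot(inherits(profile, "gradient_profile"))
  keep <- profile$positions >= x_range[1] & profile$positions <= x_range[2] &
    profile$values > 0
  if (sum(keep) < 10)
    stop("insufficient range: fewer than 10 usable nodes in fit window",
         call. = FALSE)
  x <- profile$positions[keep]
  ly <- log(profile$values[keep])
  obj <- function(x0) {
    lC <- mean(ly + 2 * log(x + x0))
    sum((ly - lC + 2 * log(x + x0))^2)
  }
  opt <- stats::optimize(obj, interval = c(1e-4, 50))
  x0 <- opt$minimum
  C <- exp(mean(ly + 2 * log(x + x0)))
  list(C = C, x0 = x0, amplitude = C / x0^2,
       decay_length = decay_length_from_x0(x0, fraction),
       total_cortical = C / x0,
       rms_log_resid = sqrt(opt$objective / sum(keep)))
}
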