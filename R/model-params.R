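#' Physical parameters of a cortical gradient model
#'
#' Bundles the constants of the membrane-bound kinase gradient models. The
#' same container serves the simplified trans- and cis-phosphorylation
#' models, the cluster-based model with concentration-dependent diffusion,
#' the combined model, and the detailed multi-state phosphorylation model.
#'
#' Concentrations are in arbitrary fluorescence intensity units (GFP signal
#' is linear in protein concentration, so no molar units are ever attached);
#' lengths in micrometres, time in minutes.
#'
#' @param D Lateral diffusion coefficient on the membrane (um^2/min).
#' @param alpha Effective detachment coefficient. For `trans`/`combined`
#'   this multiplies the quadratic decay term \eqn{\alpha P^2}
#'   (intensity^-1 min^-1); for `cis`/`cluster` the linear term
#'   \eqn{\alpha P} (min^-1).
#' @param gamma Effective decay exponent of the coarse-grained multi-state
#'   model; must lie in (1, 2]. Only used for bookkeeping/reporting: the
#'   simplified solvers implement the integer cases gamma = 2 (trans) and
#'   gamma = 1 (cis).
#' @param beta Intermolecular phosphorylation rate of the detailed model
#'   (intensity^-1 min^-1).
#' @param kappa Numeric vector of per-state detachment rates
#'   \eqn{\kappa_0 \dots \kappa_N} (min^-1) for the detailed model;
#'   must be non-decreasing, strictly increasing from state 1 on. The
#'   default models a kinase with 6 membrane-affinity phospho-sites,
#'   fully dephosphorylated molecules not detaching, and per-state rates
#'   increasing linearly.
#' @param source_strength Total influx S delivered at the pole
#'   (intensity um / min).
#' @param source_width Spatial extent (um) of the half-Gaussian source band
#'   standing in for the Tea4 cap; closed forms treat the source as a point
#'   flux at x = 0.
#' @param model_kind One of `"trans"`, `"cis"`, `"cluster"`, `"combined"`,
#'   `"detailed"`.
#' @param cluster_D0,cluster_Pstar,cluster_h Parameters of the decreasing
#'   diffusion law \eqn{D(P) = D_0 / (1 + (P/P^*)^h)} used by the cluster
#'   and combined models.
#'
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(D = 1, alpha = 6, source_strength = 2)
#' steady_state_summary(p)
#' @export
model_params <- function(D = 1, alpha = 6, gamma = 2, beta = 1,
                         kappa = 0.5 * (0:6), source_strength = 2,
                         source_width = 0.3,
                         model_kind = c("trans", "cis", "cluster", "combined",
                                        "detailed"),
                         cluster_D0 = D, cluster_Pstar = 3, cluster_h = 2) {
  model_kind <- match.arg(model_kind)
  stopifnot(is.numeric(D), length(D) == 1, is.numeric(source_strength),
            length(source_strength) == 1)
  if (!is.finite(D) || D <= 0)
    stop("invalid parameter: D must be positive", call. = FALSE)
  if (model_kind %in% c("trans", "cis", "combined", "cluster") &&
      (!is.finite(alpha) || alpha <= 0))
    stop("invalid parameter: alpha must be positive for the simplified models",
         call. = FALSE)
  if (!is.finite(gamma) || gamma <= 1 || gamma > 2)
    stop("invalid parameter: gamma must lie in (1, 2]", call. = FALSE)
  if (source_strength < 0)
    stop("invalid parameter: source_strength must be >= 0", call. = FALSE)
  if (source_width <= 0)
    stop("invalid parameter: source_width must be > 0", call. = FALSE)
  if (model_kind == "detailed") {
    if (length(kappa) < 2)
      stop("invalid parameter: detailed model needs at least one phospho-state (N >= 1)",
           call. = FALSE)
    if (any(diff(kappa) < 0) || any(diff(kappa[-1]) <= 0))
      stop("invalid parameter: kappa must be non-decreasing, strictly increasing from state 1",
           call. = FALSE)
    if (!is.finite(beta) || beta <= 0)
      stop("invalid parameter: beta must be positive", call. = FALSE)
  }
  if (model_kind %in% c("cluster", "combined")) {
    if (cluster_D0 <= 0 || cluster_Pstar <= 0 || cluster_h < 0)
      stop("invalid parameter: cluster diffusion law needs D0, Pstar > 0 and h >= 0",
           call. = FALSE)
  }
  structure(list(D = D, alpha = alpha, gamma = gamma, beta = beta,
                 kappa = kappa, source_strength = source_strength,
                 source_width = source_width, model_kind = model_kind,
                 cluster_D0 = cluster_D0, cluster_Pstar = cluster_Pstar,
                 cluster_h = cluster_h),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>", x$model_kind, "model\n")
  cat(sprintf("  D = %g um^2/min, alpha = %g, S = %g (width %g um)\n",
              x$D, x$alpha, x$source_strength, x$source_width))
  if (x$model_kind == "detailed")
    cat(sprintf("  beta = %g, kappa = %s\n", x$beta,
                paste(signif(x$kappa, 3), collapse = ", ")))
  if (x$model_kind %in% c("cluster", "combined"))
    cat(sprintf("  D(P) = %g/(1+(P/%g)^%g)\n", x$cluster_D0, x$cluster_Pstar,
                x$cluster_h))
  invisible(x)
}

#' Discretized half-line domain
#'
#' Uniform grid on `[0, length]` measuring arclength from the pole tip.
#' Provide either `n_points` or `dx`.
#'
#' @param length Domain size L in um (default 7, about half a cell length).
#' @param n_points Number of nodes (>= 50).
#' @param dx Node spacing in um (alternative to `n_points`).
#' @return Object of class `spatial_grid` with fields `length`, `n_points`,
#'   `dx` and `positions`.
#' @examples
#' g <- spatial_grid(7, dx = 0.01)
#' g$n_points
#' @export
spatial_grid <- function(length = 7, n_points = NULL, dx = NULL) {
  stopifnot(length > 0)
  if (is.null(n_points)) {
    if (is.null(dx)) dx <- 0.02
    n_points <- round(length / dx) + 1L
  }
  n_points <- as.integer(n_points)
  if (n_points < 50)
    stop("invalid parameter: grid needs at least 50 nodes", call. = FALSE)
  dx <- length / (n_points - 1L)
  structure(list(length = length, n_points = n_points, dx = dx,
                 positions = seq(0, length, length.out = n_points)),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<spatial_grid> L = %g um, %d nodes, dx = %g um\n",
              x$length, x$n_points, x$dx))
  invisible(x)
}

#' Numerical settings for steady-state integration
#'
#' @param dt Time step (min). `NULL` selects a stability-bounded step
#'   automatically from the scheme and an amplitude estimate.
#' @param rel_tol Convergence threshold: maximum node-wise rate of change
#'   divided by the profile maximum must fall below this (1/min).
#' @param max_time Cap on simulated time (min).
#' @param scheme `"semi_implicit"` (implicit diffusion, explicit reaction;
#'   default) or `"explicit"` Euler.
#' @param check_every Steps between convergence checks.
#' @return Object of class `solver_settings`.
#' @export
solver_settings <- function(dt = NULL, rel_tol = 1e-6, max_time = 5000,
                            scheme = c("semi_implicit", "explicit"),
                            check_every = 200L) {
  scheme <- match.arg(scheme)
  if (rel_tol <= 0) stop("invalid parameter: rel_tol must be > 0", call. = FALSE)
  if (!is.null(dt) && dt <= 0)
    stop("invalid parameter: dt must be > 0", call. = FALSE)
  structure(list(dt = dt, rel_tol = rel_tol, max_time = max_time,
                 scheme = scheme, check_every = as.integer(check_every)),
            class = "solver_settings")
}
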