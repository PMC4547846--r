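#' Discretized source density
#'
#' Half-Gaussian band centred at the pole tip, mimicking the Tea4 cap:
#' \eqn{s(x) \propto e^{-x^2/(2 w^2)}}, normalized so its trapezoidal
#' integral equals the total influx `source_strength`. As the width shrinks
#' the numerical solution converges to the point-flux closed forms.
#'
#' @param grid A [spatial_grid()].
#' @param source_strength Total influx S (intensity um / min).
#' @param source_width Band width w (um).
#' @return Numeric vector of source density per node (intensity / min).
#' @export
source_profile <- function(grid, source_strength, source_width) {
  s <- exp(-grid$positions^2 / (2 * source_width^2))
  s * source_strength / trapz(grid$positions, s)
}

kind_code <- function(kind)
  c(trans = 0L, cis = 1L, cluster = 2L, combined = 3L)[[kind]]

# R reference implementation of the zero-flux Laplacian (ghost reflection),
# mirroring the compiled discretization exactly
laplacian_r <- function(P, dx) {
  n <- length(P)
  c(2 * (P[2] - P[1]),
    P[-c(1, 2)] - 2 * P[-c(1, n)] + P[-c(n - 1, n)],
    2 * (P[n - 1] - P[n])) / dx^2
}

cluster_diffusivity <- function(P, params)
  params$cluster_D0 / (1 + (P / params$cluster_Pstar)^params$cluster_h)

divflux_r <- function(P, Df, dx) {
  n <- length(P)
  flux <- Df * diff(P) / dx           # face fluxes, length n-1
  c(2 * flux[1], diff(flux), -2 * flux[n - 1]) / dx
}

#' Rate of change of the simplified gradient models
#'
#' Right-hand side of the four one-field models on the discretized domain
#' (zero-flux boundaries):
#' trans \eqn{D\partial_x^2 P - \alpha P^2 + S(x)};
#' cis \eqn{D\partial_x^2 P - \alpha P + S(x)};
#' cluster \eqn{\partial_x(D(P)\partial_x P) - \alpha P + S(x)};
#' combined \eqn{\partial_x(D(P)\partial_x P) - \alpha P^2 + S(x)},
#' with the flux-form discretization of the concentration-dependent
#' diffusion law \eqn{D(P) = D_0/(1 + (P/P^*)^h)}.
#'
#' This is the reference (R) discretization; the compiled integrator in
#' [solve_to_steady_state()] implements the same formulas.
#'
#' @param state A [gradient_profile()] holding the current concentration.
#' @param params A [model_params()] with a simplified `model_kind`.
#' @param grid The [spatial_grid()] matching `state`.
#' @return Numeric vector of \eqn{\partial P/\partial t} per node.
#' @export
rhs_simplified <- function(state, params, grid) {
  stopifnot(inherits(state, "gradient_profile"),
            inherits(params, "model_params"))
  if (!params$model_kind %in% c("trans", "cis", "cluster", "combined"))
    stop("configuration error: rhs_simplified needs a simplified model_kind",
         call. = FALSE)
  P <- state$values
  if (length(P) != grid$n_points)
    stop("configuration error: state/grid dimension mismatch", call. = FALSE)
  src <- source_profile(grid, params$source_strength, params$source_width)
  dif <- if (params$model_kind %in% c("cluster", "combined")) {
    Pm <- (P[-1] + P[-length(P)]) / 2
    divflux_r(P, cluster_diffusivity(Pm, params), grid$dx)
  } else {
    params$D * laplacian_r(P, grid$dx)
  }
  dec <- if (params$model_kind %in% c("trans", "combined"))
    params$alpha * P^2 else params$alpha * P
  dif - dec + src
}

#' Rate of change of the detailed multi-state model
#'
#' Per-phospho-state dynamics: unphosphorylated protein is delivered by the
#' source and consumed by trans-phosphorylation at rate \eqn{\beta P};
#' intermediate states are fed from below and phosphorylated onward; the
#' top state only detaches. State i detaches at rate \eqn{\kappa_i}. The
#' phosphorylation terms only move mass between states, so the summed rates
#' equal \eqn{D\partial_x^2 P + S(x) - \sum_i \kappa_i P_i} exactly.
#'
#' @param state A [gradient_profile()] with `species_values` (N+1 columns).
#' @param params A [model_params()] with `model_kind = "detailed"`.
#' @param grid The matching [spatial_grid()].
#' @return Matrix of per-state rates, same shape as `species_values`.
#' @export
rhs_detailed <- function(state, params, grid) {
  stopifnot(inherits(state, "gradient_profile"))
  if (params$model_kind != "detailed")
    stop("configuration error: rhs_detailed needs model_kind = 'detailed'",
         call. = FALSE)
  Pm <- state$species_values
  if (is.null(Pm))
    stop("configuration error: state must carry species_values", call. = FALSE)
  if (ncol(Pm) != length(params$kappa))
    stop("configuration error: species/kappa dimension mismatch", call. = FALSE)
  if (nrow(Pm) != grid$n_points)
    stop("configuration error: state/grid dimension mismatch", call. = FALSE)
  src <- source_profile(grid, params$source_strength, params$source_width)
  tot <- rowSums(Pm)
  ns <- ncol(Pm)
  R <- apply(Pm, 2, laplacian_r, dx = grid$dx) * params$D
  bp <- params$beta * tot
  R[, 1] <- R[, 1] + src - bp * Pm[, 1] - params$kappa[1] * Pm[, 1]
  if (ns > 2)
    for (i in 2:(ns - 1))
      R[, i] <- R[, i] + bp * (Pm[, i - 1] - Pm[, i]) - params$kappa[i] * Pm[, i]
  R[, ns] <- R[, ns] + bp * Pm[, ns - 1] - params$kappa[ns] * Pm[, ns]
  R
}

# crude amplitude estimate used only to bound the explicit-reaction time step
estimate_amplitude <- function(params) {
  S <- max(params$source_strength, 1e-12)
  A_trans <- function(al) {
    C <- 6 * params$D / al
    C / (2 * params$D * C / S)^(2 / 3)
  }
  switch(params$model_kind,
         trans = A_trans(params$alpha),
         cis = S / sqrt(params$D * params$alpha),
         cluster = 4 * S / sqrt(params$cluster_D0 * params$alpha),
         combined = 2 * A_trans(params$alpha),
         detailed = A_trans(max(params$beta, 1e-6)))
}

default_dt <- function(params, grid, scheme) {
  A <- estimate_amplitude(params)
  Dmax <- max(params$D, params$cluster_D0)
  if (scheme == "explicit") {
    rate <- switch(params$model_kind,
                   trans = , combined = params$alpha * A,
                   cis = , cluster = params$alpha,
                   detailed = params$beta * A + max(params$kappa))
    return(min(0.2 / max(rate, 1e-9), 0.4 * grid$dx^2 / (2 * Dmax)))
  }
  # semi-implicit: losses are implicit, so dt only sets the convergence
  # pace; detailed-model gain terms are explicit, so stay below their scale
  if (params$model_kind == "detailed")
    min(0.2, 0.5 / max(params$beta * A, max(params$kappa), 1e-9))
  else 0.2
}

#' Integrate a gradient model to steady state
#'
#' Runs the compiled finite-difference integrator until the maximum
#' node-wise rate of change, relative to the profile maximum, falls below
#' `rel_tol`. Zero-flux boundaries; the source enters as the half-Gaussian
#' band of [source_profile()]. On numerical blow-up the time step is halved
#' and the integration restarted (up to four times) before a stability
#' error is raised.
#'
#' @param params A [model_params()] of any `model_kind`.
#' @param grid A [spatial_grid()].
#' @param settings A [solver_settings()].
#' @param init Optional initial [gradient_profile()] (zero by default).
#' @return A [gradient_profile()] (with `species_values` for the detailed
#'   model) carrying attributes `residual`, `sim_time`, `steps`, `dt`,
#'   `scheme` and a `residual_log` data frame.
#' @examples
#' p <- model_params(D = 1, alpha = 6, source_strength = 2, source_width = 0.1)
#' sol <- solve_to_steady_state(p, spatial_grid(7, dx = 0.05))
#' attr(sol, "residual")
#' @export
solve_to_steady_state <- function(params, grid, settings = solver_settings(),
                                  init = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "spatial_grid"),
            inherits(settings, "solver_settings"))
  src <- source_profile(grid, params$source_strength, params$source_width)
  scheme_code <- if (settings$scheme == "explicit") 0L else 1L
  dt <- if (is.null(settings$dt)) default_dt(params, grid, settings$scheme)
        else settings$dt

  detailed <- params$model_kind == "detailed"
  if (detailed) {
    ns <- length(params$kappa)
    init_m <- if (is.null(init)) matrix(0, grid$n_points, ns)
              else init$species_values
    if (is.null(init_m) || ncol(init_m) != ns)
      stop("configuration error: init must carry N+1 species columns",
           call. = FALSE)
  } else {
    init_v <- if (is.null(init)) rep(0, grid$n_points) else init$values
    if (length(init_v) != grid$n_points)
      stop("configuration error: init/grid dimension mismatch", call. = FALSE)
  }

  for (attempt in 1:5) {
    res <- if (detailed) {
      .cpp_solve_detailed(init_m, grid$dx, params$D, params$beta,
                          params$kappa, src, dt, settings$rel_tol,
                          settings$max_time, scheme_code,
                          settings$check_every)
    } else {
      .cpp_solve_simplified(init_v, grid$dx, params$D, params$alpha,
                            kind_code(params$model_kind), src, dt,
                            settings$rel_tol, settings$max_time, scheme_code,
                            params$cluster_D0, params$cluster_Pstar,
                            params$cluster_h, settings$check_every)
    }
    if (!res$unstable) break
    dt <- dt / 2
  }
  if (res$unstable)
    stop("stability error: integration blew up; use a smaller dt",
         call. = FALSE)
  if (!res$converged)
    stop(sprintf(
      "convergence error: residual %.3g > rel_tol %.3g at max_time %g min",
      res$residual, settings$rel_tol, settings$max_time), call. = FALSE)

  prof <- if (detailed) {
    sp <- res$species
    gradient_profile(grid$positions, rowSums(sp), sp)
  } else {
    gradient_profile(grid$positions, pmax(res$values, 0))
  }
  attr(prof, "residual") <- res$residual
  attr(prof, "sim_time") <- res$time
  attr(prof, "steps") <- res$steps
  attr(prof, "dt") <- dt
  attr(prof, "scheme") <- settings$scheme
  attr(prof, "residual_log") <- data.frame(time = res$residual_time,
                                           residual = res$residual_value)
  prof
}

#' Detachment-flux density of a detailed-model state
#'
#' @param profile A [gradient_profile()] with `species_values`.
#' @param kappa Per-state detachment rates.
#' @return Numeric vector \eqn{d(x) = \sum_i \kappa_i P_i(x)}.
#' @export
detachment_density <- function(profile, kappa) {
  stopifnot(!is.null(profile$species_values),
            ncol(profile$species_values) == length(kappa))
  as.vector(profile$species_values %*% kappa)
}

# log-log regression of detachment density on total concentration
fit_gamma_loglog <- function(P, d, min_frac = 0.01) {
  keep <- P > min_frac * max(P) & d > 0
  if (sum(keep) < 10)
    stop("insufficient range: fewer than 10 usable nodes", call. = FALSE)
  f <- lm(log10(d[keep]) ~ log10(P[keep]))
  # degenerate detachment laws give exact power laws; the perfect-fit
  # warning from summary.lm is expected there
  list(gamma = unname(coef(f)[2]),
       r_squared = suppressWarnings(summary(f)$r.squared),
       n = sum(keep))
}

#' Effective decay exponent of the detailed model
#'
#' Solves the detailed N-state model to steady state and regresses the log
#' detachment-flux density \eqn{d(x) = \sum_i \kappa_i P_i} on the log
#' total concentration \eqn{P(x)} over nodes where P exceeds `min_frac` of
#' the amplitude. The slope is the effective exponent \eqn{\gamma} of the
#' coarse-grained decay term \eqn{\alpha_\gamma P^\gamma}. When the
#' per-state detachment rate grows at least linearly with the number of
#' phosphorylated residues and phosphorylation is strong, \eqn{\gamma}
#' lies in (1.5, 2]; degenerate constant rates give \eqn{\gamma = 1}.
#'
#' @param params A detailed-model [model_params()].
#' @param grid A [spatial_grid()].
#' @param settings A [solver_settings()].
#' @param min_frac Amplitude fraction below which nodes are dropped.
#' @param profile Optional pre-computed steady state (skips the solve).
#' @return List with `gamma`, `r_squared`, `n` (nodes used) and the
#'   steady-state `profile`.
#' @export
fit_effective_gamma <- function(params, grid, settings = solver_settings(),
                                min_frac = 0.01, profile = NULL) {
  if (is.null(profile))
    profile <- solve_to_steady_state(params, grid, settings)
  d <- detachment_density(profile, params$kappa)
  out <- fit_gamma_loglog(profile$values, d, min_frac)
  out$profile <- profile
  out
}

#' Choose the phosphorylation rate for a target pole phosphorylation level
#'
#' Iterates the detailed-model solve so that \eqn{\beta A \approx
#' ratio \cdot \kappa} at the pole, where \eqn{\kappa} is the per-state
#' detachment increment. The fixed point is stable because the amplitude
#' depends only weakly (about the -1/3 power) on \eqn{\beta}.
#'
#' @param params A detailed-model [model_params()]; its `beta` is the
#'   starting guess.
#' @param grid,settings Passed to [solve_to_steady_state()].
#' @param ratio Target \eqn{\beta A / \kappa}.
#' @param kappa_unit Rate increment \eqn{\kappa}; defaults to the first
#'   positive difference of `params$kappa`.
#' @param iterations Fixed-point iterations (2-3 suffice).
#' @return `params` with calibrated `beta`; the last solved profile is
#'   attached as attribute `profile`.
#' @export
calibrate_beta <- function(params, grid, settings = solver_settings(),
                           ratio = 5, kappa_unit = NULL, iterations = 3) {
  stopifnot(params$model_kind == "detailed")
  if (is.null(kappa_unit)) kappa_unit <- max(diff(params$kappa)[1], 1e-9)
  prof <- NULL
  for (i in seq_len(iterations)) {
    prof <- solve_to_steady_state(params, grid, settings)
    A <- max(prof$values)
    beta_new <- ratio * kappa_unit / A
    if (abs(beta_new - params$beta) < 1e-3 * params$beta && i > 1) {
      params$beta <- beta_new
      break
    }
    params$beta <- beta_new
  }
  attr(params, "profile") <- solve_to_steady_state(params, grid, settings)
  params
}
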