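# shared fixtures: canonical parameter sets and small grids
par_unit <- function(S = 2, w = 0.05)
  model_params(D = 1, alpha = 6, source_strength = S, source_width = w)

grid_coarse <- function(L = 7) spatial_grid(L, dx = 0.05)
grid_fine <- function(L = 7) spatial_grid(L, dx = 0.01)

# small detailed-model configuration used across solver tests
par_detailed <- function(beta = 1, kappa = 0.5 * (0:6), S = 2, w = 0.1)
  model_params(D = 1, beta = beta, kappa = kappa, source_strength = S,
               source_width = w, model_kind = "detailed")

small_population <- function(seed = 1, n_cells = 12, ...)
  sample_population(population_spec(n_cells = n_cells, seed = seed, ...))
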