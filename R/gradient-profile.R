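#' Concentration profile along the cortex
#'
#' A steady-state (or measured) concentration as a function of arclength
#' from the pole tip. For the detailed multi-state model,
#' `species_values` holds the per-phospho-state concentrations whose row
#' sums equal `values`.
#'
#' @param positions Strictly increasing arclength coordinates (um), starting
#'   at 0.
#' @param values Non-negative concentrations (intensity units).
#' @param species_values Optional matrix (length(positions) x N+1) of
#'   per-state concentrations.
#' @return Object of class `gradient_profile`.
#' @export
gradient_profile <- function(positions, values, species_values = NULL) {
  stopifnot(length(positions) == length(values))
  if (positions[1] != 0 || any(diff(positions) <= 0))
    stop("positions must be strictly increasing from 0", call. = FALSE)
  if (any(values < -1e-9 * max(abs(values), 1)))
    stop("values must be non-negative", call. = FALSE)
  if (!is.null(species_values)) {
    species_values <- as.matrix(species_values)
    if (nrow(species_values) != length(positions))
      stop("species_values must have one row per position", call. = FALSE)
    tot <- rowSums(species_values)
    if (max(abs(tot - values)) > 1e-6 * max(values, 1))
      stop("species_values must sum to values", call. = FALSE)
  }
  structure(list(positions = positions, values = values,
                 species_values = species_values),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("<gradient_profile> %d nodes on [0, %g] um, P(0) = %.4g, max = %.4g\n",
              length(x$positions), max(x$positions), x$values[1], max(x$values)))
  if (!is.null(x$species_values))
    cat(sprintf("  %d phospho-states\n", ncol(x$species_values)))
  invisible(x)
}

#' @export
as.data.frame.gradient_profile <- function(x, ...) {
  df <- data.frame(position_um = x$positions, value = x$values)
  if (!is.null(x$species_values)) {
    sp <- as.data.frame(x$species_values)
    names(sp) <- paste0("state_", seq_len(ncol(sp)) - 1L)
    df <- cbind(df, sp)
  }
  df
}

#' Write / read a gradient profile as two-column CSV
#'
#' Columns `position_um`, `value` (plus `state_i` columns when per-state
#' concentrations are present).
#'
#' @param profile A `gradient_profile`.
#' @param path File path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   returns a `gradient_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path)
  sp <- grep("^state_", names(df), value = TRUE)
  gradient_profile(df$position_um, df$value,
                   if (length(sp)) as.matrix(df[sp]) else NULL)
}

# trapezoidal integral of a sampled profile
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
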