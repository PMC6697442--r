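#' Construct a set of gLV model parameters
#'
#' Bundles the parameters of a discrete-time stochastic generalized
#' Lotka-Volterra (gLV) model for `S` species: per-capita growth rates
#' `r_i` (1/h), the interaction matrix `a[i, j]` (effect of species `j`
#' ON species `i`, 1/(h * CFU/ml)), binary edge indicators `z[i, j]`,
#' and per-species process-noise variances `v_w[i]` ((CFU/ml)^2 per hour).
#' Optional higher-order terms add, for each species `i`, a 3rd-order
#' coefficient multiplying the product of all other species' abundances
#' and a 4th-order coefficient multiplying the product of all abundances.
#'
#' Diagonal indicators are fixed to 1: self-limitation is always part of
#' the model, so the 12 candidate edges of a 4-species community are the
#' off-diagonal pairs only.
#'
#' @param species character vector of unique species labels (length >= 2).
#' @param growth_rates numeric vector `r_i`, one per species (1/h).
#' @param interaction_matrix S x S numeric matrix `a[i, j]`; row = target.
#' @param indicator_matrix S x S binary matrix `z[i, j]`; diagonal forced
#'   to 1. Defaults to 1 wherever `interaction_matrix` is nonzero (and on
#'   the diagonal).
#' @param process_noise_var numeric vector `v_w[i] > 0`, one per species.
#' @param higher_order `NULL` (pairwise model) or a list with numeric
#'   vectors `a3`, `a4` and binary vectors `z3`, `z4`, one entry per
#'   species.
#' @return An object of class `glv_params`.
#' @export
glv_params <- function(species, growth_rates, interaction_matrix,
                       indicator_matrix = NULL,
                       process_noise_var = rep(0, length(species)),
                       higher_order = NULL) {
  species <- as.character(species)
  S <- length(species)
  if (S < 2L) stop("need at least 2 species", call. = FALSE)
  if (anyDuplicated(species)) stop("species labels must be unique", call. = FALSE)
  growth_rates <- as.numeric(growth_rates)
  if (length(growth_rates) != S) {
    stop("growth_rates must have one entry per species", call. = FALSE)
  }
  interaction_matrix <- as.matrix(interaction_matrix)
  if (!all(dim(interaction_matrix) == c(S, S))) {
    stop("interaction_matrix must be ", S, " x ", S, call. = FALSE)
  }
  if (is.null(indicator_matrix)) {
    indicator_matrix <- (interaction_matrix != 0) * 1
  }
  indicator_matrix <- as.matrix(indicator_matrix)
  if (!all(dim(indicator_matrix) == c(S, S))) {
    stop("indicator_matrix must be ", S, " x ", S, call. = FALSE)
  }
  if (!all(indicator_matrix %in% c(0, 1))) {
    stop("indicators must be 0 or 1", call. = FALSE)
  }
  diag(indicator_matrix) <- 1
  process_noise_var <- as.numeric(process_noise_var)
  if (length(process_noise_var) == 1L) {
    process_noise_var <- rep(process_noise_var, S)
  }
  if (length(process_noise_var) != S || any(process_noise_var < 0)) {
    stop("process_noise_var must be a nonnegative vector of length S",
         call. = FALSE)
  }
  if (!is.null(higher_order)) {
    need <- c("a3", "a4", "z3", "z4")
    if (!all(need %in% names(higher_order))) {
      stop("higher_order needs fields a3, a4, z3, z4", call. = FALSE)
    }
    higher_order <- lapply(higher_order[need], function(v) {
      v <- as.numeric(v)
      if (length(v) != S) stop("higher-order terms need one entry per species",
                               call. = FALSE)
      v
    })
    if (!all(c(higher_order$z3, higher_order$z4) %in% c(0, 1))) {
      stop("higher-order indicators must be 0 or 1", call. = FALSE)
    }
  }
  dimnames(interaction_matrix) <- list(species, species)
  dimnames(indicator_matrix) <- list(species, species)
  names(growth_rates) <- species
  names(process_noise_var) <- species
  structure(
    list(species = species,
         growth_rates = growth_rates,
         interaction_matrix = interaction_matrix,
         indicator_matrix = indicator_matrix,
         process_noise_var = process_noise_var,
         higher_order = higher_order),
    class = "glv_params"
  )
}

#' @export
print.glv_params <- function(x, ...) {
  S <- length(x$species)
  cat(sprintf("gLV parameters: %d species (%s)\n", S,
              paste(x$species, collapse = ", ")))
  cat("growth rates (1/h):\n")
  print(signif(x$growth_rates, 3))
  cat("interaction matrix a[i,j] * z[i,j] (row = target):\n")
  print(signif(x$interaction_matrix * x$indicator_matrix, 3))
  if (!is.null(x$higher_order)) cat("higher-order terms enabled\n")
  invisible(x)
}

n_species <- function(params) length(params$species)

#' Per-capita growth rates at a community state
#'
#' Evaluates `rate_i = r_i + sum_j a[i,j] z[i,j] x_j`, plus the
#' higher-order terms `z3_i a3_i prod_{j != i} x_j` and
#' `z4_i a4_i prod_j x_j` when the model carries them. Edges with
#' indicator 0 are removed exactly.
#'
#' @param params a [glv_params()] object.
#' @param state numeric abundance vector (CFU/ml), length S, finite, >= 0.
#' @return numeric vector of per-capita rates (1/h), length S.
#' @export
per_capita_growth <- function(params, state) {
  S <- n_species(params)
  state <- as.numeric(state)
  if (length(state) != S) {
    stop(sprintf("state has length %d, expected %d", length(state), S),
         call. = FALSE)
  }
  if (any(!is.finite(state))) stop("state must be finite", call. = FALSE)
  if (any(state < 0)) stop("state must be nonnegative", call. = FALSE)
  rate <- params$growth_rates +
    drop((params$interaction_matrix * params$indicator_matrix) %*% state)
  if (!is.null(params$higher_order)) {
    ho <- params$higher_order
    prod_all <- prod(state)
    # prod over j != i; avoid 0/0 when some abundance is zero
    prod_others <- vapply(seq_len(S), function(i) prod(state[-i]), numeric(1))
    rate <- rate + ho$z3 * ho$a3 * prod_others + ho$z4 * ho$a4 * prod_all
  }
  unname(rate)
}

#' One Euler step of the discrete-time gLV map
#'
#' `x' = x + x * rate(x) * delta_t + noise_increment`, clamped at 0.
#' Abundances are concentrations, so any negative value produced by the
#' additive noise is truncated to zero.
#'
#' @param params a [glv_params()] object.
#' @param state abundance vector at time k.
#' @param delta_t time step (hours), >= 0.
#' @param noise_increment additive noise vector (all zeros for the
#'   deterministic map).
#' @return abundance vector at time k + 1.
#' @export
glv_step <- function(params, state, delta_t,
                     noise_increment = rep(0, length(state))) {
  if (length(delta_t) != 1L || !is.finite(delta_t) || delta_t < 0) {
    stop("delta_t must be a single nonnegative number", call. = FALSE)
  }
  noise_increment <- as.numeric(noise_increment)
  if (length(noise_increment) != n_species(params)) {
    stop("noise_increment has wrong length", call. = FALSE)
  }
  rate <- per_capita_growth(params, state)
  pmax(state + state * rate * delta_t + noise_increment, 0)
}

#' Simulate a gLV trajectory on a time grid
#'
#' Iterates [glv_step()] over `time_grid`. In stochastic mode the noise
#' increment between grid points `k` and `k+1` is drawn as
#' `Normal(0, v_w[i] * delta_k)` per species (Brownian-increment
#' convention). With `substeps > 1` each grid interval is subdivided for
#' the forward simulation and only grid-point states are returned; the
#' per-substep noise variance is scaled accordingly.
#'
#' @param params a [glv_params()] object.
#' @param initial_state abundance vector at `time_grid[1]` (CFU/ml).
#' @param time_grid strictly increasing numeric vector of times (hours).
#' @param stochastic draw process noise? Uses the current R RNG state;
#'   call `set.seed()` (or pass `seed`) for reproducibility.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so identical calls give bitwise-identical trajectories.
#' @param substeps integer >= 1; Euler substeps per grid interval.
#' @param condition_label,replicate_id metadata carried on the result.
#' @return A `glv_trajectory`: list with `times`, `abundances`
#'   (time x species matrix), `condition_label`, `replicate_id`.
#' @export
glv_simulate <- function(params, initial_state, time_grid,
                         stochastic = FALSE, seed = NULL, substeps = 1L,
                         condition_label = "C1", replicate_id = 1L) {
  S <- n_species(params)
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 2L || any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  initial_state <- as.numeric(initial_state)
  if (length(initial_state) != S || any(initial_state < 0)) {
    stop("initial_state must be a nonnegative vector of length S",
         call. = FALSE)
  }
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("substeps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  Tn <- length(time_grid)
  x <- matrix(NA_real_, Tn, S, dimnames = list(NULL, params$species))
  x[1, ] <- initial_state
  state <- initial_state
  sd_unit <- sqrt(params$process_noise_var)
  for (k in seq_len(Tn - 1L)) {
    dt <- (time_grid[k + 1L] - time_grid[k]) / substeps
    for (s in seq_len(substeps)) {
      noise <- if (stochastic) stats::rnorm(S, 0, sd_unit * sqrt(dt)) else rep(0, S)
      state <- glv_step(params, state, dt, noise)
      if (any(!is.finite(state))) {
        stop(sprintf("non-finite abundance at t = %.3g h (step %d): model blow-up",
                     time_grid[k] + s * dt, k), call. = FALSE)
      }
    }
    x[k + 1L, ] <- state
  }
  new_trajectory(time_grid, x, condition_label, replicate_id)
}

new_trajectory <- function(times, abundances, condition_label, replicate_id,
                           censored = NULL) {
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(abundances), ncol(abundances))
  }
  structure(
    list(times = times, abundances = abundances,
         condition_label = condition_label,
         replicate_id = replicate_id,
         censored = censored),
    class = "glv_trajectory"
  )
}

#' @export
print.glv_trajectory <- function(x, ...) {
  cat(sprintf("gLV trajectory [%s, rep %s]: %d time points, %d species\n",
              x$condition_label, x$replicate_id, length(x$times),
              ncol(x$abundances)))
  invisible(x)
}

#' @export
as.data.frame.glv_trajectory <- function(x, ...) {
  S <- ncol(x$abundances)
  Tn <- length(x$times)
  data.frame(
    condition = rep(x$condition_label, Tn * S),
    replicate = rep(x$replicate_id, Tn * S),
    time_h = rep(x$times, each = S),
    species = rep(colnames(x$abundances), times = Tn),
    abundance_cfu_per_ml = as.vector(t(x$abundances)),
    censored = as.vector(t(x$censored)),
    stringsAsFactors = FALSE
  )
}

#' Single-species gLV equilibrium (carrying capacity)
#'
#' For one self-limited species the gLV fixed point is `K = -r / a_self`.
#'
#' @param r growth rate (> 0, 1/h).
#' @param a_self self-interaction coefficient (< 0).
#' @return the carrying capacity, CFU/ml.
#' @export
equilibrium_single_species <- function(r, a_self) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  if (any(a_self >= 0)) {
    stop("a_self must be negative for a finite equilibrium", call. = FALSE)
  }
  -r / a_self
}

#' Write / read gLV parameters as YAML
#'
#' Serializes a [glv_params()] object with explicit species ordering so a
#' round trip restores it exactly.
#'
#' @param params a `glv_params` object.
#' @param path file path.
#' @return `read_glv_params` returns a `glv_params` object;
#'   `write_glv_params` returns `path` invisibly.
#' @export
write_glv_params <- function(params, path) {
  doc <- list(
    species = as.list(params$species),
    growth_rates = as.list(unname(params$growth_rates)),
    interaction_matrix = apply(params$interaction_matrix, 1, as.list,
                               simplify = FALSE),
    indicator_matrix = apply(params$indicator_matrix, 1, as.list,
                             simplify = FALSE),
    process_noise_var = as.list(unname(params$process_noise_var))
  )
  if (!is.null(params$higher_order)) {
    doc$higher_order <- lapply(params$higher_order, as.list)
  }
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' @rdname write_glv_params
#' @export
read_glv_params <- function(path) {
  doc <- yaml::read_yaml(path)
  S <- length(doc$species)
  glv_params(
    species = unlist(doc$species),
    growth_rates = unlist(doc$growth_rates),
    interaction_matrix = matrix(unlist(doc$interaction_matrix), S, S,
                                byrow = TRUE),
    indicator_matrix = matrix(unlist(doc$indicator_matrix), S, S,
                              byrow = TRUE),
    process_noise_var = unlist(doc$process_noise_var),
    higher_order = if (!is.null(doc$higher_order)) {
      lapply(doc$higher_order, unlist)
    }
  )
}
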