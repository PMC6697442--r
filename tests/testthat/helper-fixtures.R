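# Shared fixtures: small two-species systems and an independent
# grid-quadrature oracle for spike-and-slab marginal likelihoods.

two_species_params <- function(process_noise_var = c(1e8, 1e8)) {
  glv_params(c("A", "B"), c(0.40, 0.30),
             matrix(c(-4e-10, -1.5e-10,
                      0,     -3e-10), 2, 2, byrow = TRUE),
             process_noise_var = process_noise_var)
}

# two conditions (equal inoculum + knockdown of A) x 6 time points
two_species_design <- function(seed = 101, stochastic = TRUE,
                               params = two_species_params(),
                               times = c(0, 2, 5, 9, 14, 20)) {
  set.seed(seed)
  trajs <- list(
    glv_simulate(params, c(1e6, 1e6), times, stochastic = stochastic,
                 condition_label = "C1"),
    glv_simulate(params, c(1e5, 1e6), times, stochastic = stochastic,
                 condition_label = "C2")
  )
  build_design(trajectory_set(trajs))
}

# single-species toy design with an explicit covariate column for the
# growth rate and a zeroed self-interaction column (so closed-form
# 1-parameter posteriors apply)
make_toy_design <- function(X, y) {
  X2 <- matrix(c(as.numeric(X), rep(0, length(X))), ncol = 2)
  structure(list(
    species = "A", S = 1L, p = 2L, col_type = c("r", "a"),
    col_partner = c(NA_integer_, 1L), higher_order = FALSE,
    free = matrix(FALSE, 2, 1),
    per_species = list(A = list(y = y, X = X2, n = length(y),
                                G = crossprod(X2),
                                cy = drop(crossprod(X2, y)),
                                yy = sum(y^2)))),
    class = "glv_design_matrix")
}

# wrap a bare abundance vector into a one-species trajectory (for
# measurement-noise statistics on many i.i.d. values)
new_traj_matrix <- function(values) {
  ssglv:::new_trajectory(seq_along(values),
                         matrix(values, ncol = 1,
                                dimnames = list(NULL, "A")),
                         "C1", 1L)
}

# Independent oracle: marginal likelihood of one species' regression rows
# with the included coefficients integrated out by brute-force midpoint
# quadrature on a grid centered at the ordinary least-squares solution
# (base-R qr algebra only; no shared code with the sampler).
quad_marginal <- function(X, y, incl, pvar, vw, npts = 71, width = 12) {
  Xi <- X[, incl, drop = FALSE]
  qrf <- qr(Xi)
  bhat <- qr.coef(qrf, y)
  Vhat <- chol2inv(qr.R(qrf)) * vw
  sds <- sqrt(pmin(diag(Vhat), pvar[incl]))
  grids <- lapply(seq_along(bhat), function(k)
    seq(bhat[k] - width * sds[k], bhat[k] + width * sds[k],
        length.out = npts))
  gd <- as.matrix(expand.grid(grids))
  resid2 <- colSums((y - Xi %*% t(gd))^2)
  ll <- -0.5 * length(y) * log(2 * pi * vw) - 0.5 * resid2 / vw
  lp <- colSums(dnorm(t(gd), 0, sqrt(pvar[incl]), log = TRUE))
  cell <- prod(vapply(grids, function(g) g[2] - g[1], numeric(1)))
  m <- max(ll + lp)
  m + log(sum(exp(ll + lp - m))) + log(cell)
}

# exact posterior inclusion probability of one free column by enumeration
quad_inclusion <- function(design, i, free_col, pvar, vw,
                           pi_edge = 0.5) {
  d <- design$per_species[[i]]
  incl1 <- rep(TRUE, design$p)
  incl0 <- incl1
  incl0[free_col] <- FALSE
  m1 <- quad_marginal(d$X, d$y, incl1, pvar, vw)
  m0 <- quad_marginal(d$X, d$y, incl0, pvar, vw)
  1 / (1 + exp(m0 - m1) * (1 - pi_edge) / pi_edge)
}
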