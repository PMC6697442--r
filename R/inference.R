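#' Prior hyperparameters for the spike-and-slab gLV model
#'
#' The hierarchy places `r_i | v_r ~ Normal(0, v_r)`,
#' `a_{i,j} | v_a ~ Normal(0, v_a)` (shared across all interaction and
#' higher-order coefficients), `z_{i,j} ~ Bernoulli(edge_prior_prob)` on
#' off-diagonal edges, and scaled inverse-chi-squared priors
#' `Inv-chi^2(eta, theta)` on the variances `v_r`, `v_a` and the
#' per-species process-noise variances `v_w[i]`. Defaults are the diffuse
#' settings `eta = 0.1` throughout with `theta_r = 0.01`,
#' `theta_a = 1e-14`, `theta_w = 1e4`, and edge prior probability `0.5`
#' (maximum prior uncertainty about each edge). These scales presume
#' abundances on the raw CFU/ml scale.
#'
#' @param eta_r,theta_r shape and scale for `v_r`.
#' @param eta_a,theta_a shape and scale for `v_a`.
#' @param eta_w,theta_w shape and scale for each `v_w[i]`.
#' @param edge_prior_prob prior inclusion probability of each edge,
#'   in (0, 1).
#' @return a `glv_priors` list.
#' @export
prior_hyperparameters <- function(eta_r = 0.1, theta_r = 0.01,
                                  eta_a = 0.1, theta_a = 1e-14,
                                  eta_w = 0.1, theta_w = 1e4,
                                  edge_prior_prob = 0.5) {
  vals <- c(eta_r, theta_r, eta_a, theta_a, eta_w, theta_w)
  if (any(vals <= 0)) stop("eta and theta must all be > 0", call. = FALSE)
  if (edge_prior_prob <= 0 || edge_prior_prob >= 1) {
    stop("edge_prior_prob must be in (0, 1)", call. = FALSE)
  }
  structure(list(eta_r = eta_r, theta_r = theta_r,
                 eta_a = eta_a, theta_a = theta_a,
                 eta_w = eta_w, theta_w = theta_w,
                 edge_prior_prob = edge_prior_prob),
            class = "glv_priors")
}

#' MCMC configuration
#'
#' @param iterations total Gibbs sweeps (default 5000).
#' @param burn_in sweeps discarded from the front (default 1000).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param higher_order include 3rd/4th-order interaction terms?
#' @param engine `"compiled"` (C++ kernel) or `"R"` (reference
#'   implementation of the identical updates).
#' @param fix_variances `NULL`, or a list with `v_r`, `v_a`, `v_w`
#'   (vector) to hold the variance parameters fixed instead of sampling
#'   them (used for exact enumeration cross-checks).
#' @return a `glv_mcmc_config` list.
#' @export
mcmc_config <- function(iterations = 5000L, burn_in = 1000L, seed = NULL,
                        higher_order = FALSE,
                        engine = c("compiled", "R"),
                        fix_variances = NULL) {
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (burn_in >= iterations) stop("burn_in must be < iterations", call. = FALSE)
  if (burn_in < 0) stop("burn_in must be >= 0", call. = FALSE)
  structure(list(iterations = iterations, burn_in = burn_in, seed = seed,
                 higher_order = isTRUE(higher_order),
                 engine = match.arg(engine),
                 fix_variances = fix_variances),
            class = "glv_mcmc_config")
}

#' Build the per-species regression design from trajectories
#'
#' Rearranges the discrete-time gLV update so that, for species `i`, each
#' consecutive observation pair `(k, k+1)` contributes one Gaussian
#' regression row: the response is the abundance increment and the
#' covariates are `x_{k,i} dt` (growth-rate column) and
#' `x_{k,i} x_{k,j} dt` (one column per interaction coefficient), with
#' residual variance `v_w[i] dt`. Rows and responses are stored divided
#' by `sqrt(dt)` so the residual variance is a constant `v_w[i]` per row.
#' With `higher_order = TRUE` two product columns are appended:
#' `x_{k,i} dt prod_{j != i} x_{k,j}` and `x_{k,i} dt prod_j x_{k,j}`.
#'
#' Observed abundances are plugged in as the latent states (process-noise
#' -only likelihood); rows whose source `x_{k,i}` is censored or
#' nonpositive, or whose response `x_{k+1,i}` is censored, are excluded
#' under the default floor policy.
#'
#' @param trajectories a `glv_trajectory_set`, or list of
#'   `glv_trajectory` objects sharing one species ordering.
#' @param higher_order add the two product columns?
#' @param floor_policy `"exclude"` (drop censored rows, default) or
#'   `"keep"`.
#' @param species optional explicit species ordering.
#' @return a `glv_design_matrix` object (per-species scaled responses,
#'   covariate matrices, and column metadata).
#' @export
build_design <- function(trajectories, higher_order = FALSE,
                         floor_policy = c("exclude", "keep"),
                         species = NULL) {
  floor_policy <- match.arg(floor_policy)
  if (inherits(trajectories, "glv_trajectory_set") ||
      is.data.frame(trajectories)) {
    trajectories <- split_trajectories(trajectories, species = species)
  }
  species <- colnames(trajectories[[1]]$abundances)
  S <- length(species)
  p <- 1L + S + if (higher_order) 2L else 0L
  col_type <- c("r", rep("a", S), if (higher_order) c("ho3", "ho4"))
  col_partner <- c(NA_integer_, seq_len(S),
                   if (higher_order) c(NA_integer_, NA_integer_))

  per_species <- vector("list", S)
  for (i in seq_len(S)) {
    ys <- list(); Xs <- list()
    for (tr in trajectories) {
      x <- tr$abundances
      cens <- tr$censored
      Tn <- length(tr$times)
      if (Tn < 2L) stop("each trajectory needs >= 2 time points", call. = FALSE)
      dt <- diff(tr$times)
      keep <- x[-Tn, i] > 0
      if (floor_policy == "exclude") {
        keep <- keep & !cens[-Tn, i] & !cens[-1, i]
      }
      if (!any(keep)) next
      ks <- which(keep)
      sq <- sqrt(dt[ks])
      xi <- unname(x[ks, i])
      y <- (unname(x[ks + 1L, i]) - xi) / sq
      X <- matrix(0, length(ks), p)
      X[, 1] <- xi * sq
      for (j in seq_len(S)) X[, 1L + j] <- xi * x[ks, j] * sq
      if (higher_order) {
        prod_all <- apply(x[ks, , drop = FALSE], 1, prod)
        prod_others <- prod_all / ifelse(xi > 0, xi, 1)
        X[, p - 1L] <- xi * prod_others * sq
        X[, p] <- xi * prod_all * sq
      }
      ys[[length(ys) + 1L]] <- y
      Xs[[length(Xs) + 1L]] <- X
    }
    if (!length(ys)) {
      stop("all rows censored or empty for species ", species[i],
           call. = FALSE)
    }
    y <- unlist(ys)
    X <- do.call(rbind, Xs)
    per_species[[i]] <- list(y = y, X = X, n = length(y),
                             G = crossprod(X), cy = drop(crossprod(X, y)),
                             yy = sum(y^2))
  }
  names(per_species) <- species
  # free (indicator-updatable) columns per species: off-diagonal edges + ho
  free <- matrix(FALSE, p, S)
  for (i in seq_len(S)) {
    free[, i] <- col_type == "a" & col_partner != i
    free[is.na(col_partner) & col_type != "r", i] <- TRUE
  }
  structure(list(species = species, S = S, p = p,
                 col_type = col_type, col_partner = col_partner,
                 higher_order = higher_order, free = free,
                 per_species = per_species),
            class = "glv_design_matrix")
}

#' @export
print.glv_design_matrix <- function(x, ...) {
  n <- vapply(x$per_species, function(d) d$n, numeric(1))
  cat(sprintf("gLV regression design: %d species, %d columns, rows per species: %s\n",
              x$S, x$p, paste(n, collapse = ", ")))
  invisible(x)
}

prior_var_by_col <- function(design, v_r, v_a) {
  ifelse(design$col_type == "r", v_r, v_a)
}

# log marginal likelihood of species i's rows with coefficients for the
# included columns integrated over their Normal(0, pvar) priors
marg_loglik <- function(d, idx, pvar, v_w) {
  n <- d$n
  base <- -0.5 * n * log(2 * pi * v_w) - 0.5 * d$yy / v_w
  if (!length(idx)) return(base)
  sv <- sqrt(pvar[idx])
  A <- diag(length(idx)) + (sv %o% sv) * d$G[idx, idx, drop = FALSE] / v_w
  b <- sv * d$cy[idx] / v_w
  L <- chol(A)  # upper triangular
  u <- backsolve(L, b, transpose = TRUE)
  base - sum(log(diag(L))) + 0.5 * sum(u^2)
}

# draw included coefficients from their Gaussian full conditional;
# returns full-length beta with excluded entries drawn from the prior
draw_beta <- function(d, incl, pvar, v_w) {
  p <- length(pvar)
  beta <- stats::rnorm(p, 0, sqrt(pvar))
  idx <- which(incl)
  if (length(idx)) {
    sv <- sqrt(pvar[idx])
    A <- diag(length(idx)) + (sv %o% sv) * d$G[idx, idx, drop = FALSE] / v_w
    b <- sv * d$cy[idx] / v_w
    L <- chol(A)
    u <- backsolve(L, b, transpose = TRUE)
    gm <- backsolve(L, u)
    gam <- gm + backsolve(L, stats::rnorm(length(idx)))
    beta[idx] <- sv * gam
  }
  beta
}

included_cols <- function(design, i, z_row) {
  incl <- rep(TRUE, design$p)
  incl[design$free[, i]] <- z_row[design$free[, i]] > 0
  incl
}

#' Draw gLV coefficients from their Gaussian full conditional
#'
#' Given fixed indicators and variances, the coefficients of each
#' species' included columns have a conjugate Gaussian posterior
#' (Bayesian linear regression); excluded coefficients do not enter the
#' likelihood and are drawn from their `Normal(0, v)` prior. Uses the
#' current R RNG state.
#'
#' @param design a [build_design()] object.
#' @param z S x S indicator matrix (diagonal treated as 1). For
#'   higher-order designs, a list `list(z = matrix, z3 = vec, z4 = vec)`.
#' @param v_r,v_a,v_w variances (`v_w` a per-species vector, recycled
#'   from a scalar).
#' @return list with `r` (vector), `a` (S x S matrix), and `a3`, `a4`
#'   when the design has higher-order columns.
#' @export
sample_coefficients <- function(design, z, v_r, v_a, v_w) {
  st <- as_indicator_state(design, z)
  v_w <- rep_len(v_w, design$S)
  pvar <- prior_var_by_col(design, v_r, v_a)
  S <- design$S
  r <- numeric(S)
  a <- matrix(0, S, S, dimnames = list(design$species, design$species))
  a3 <- a4 <- numeric(S)
  for (i in seq_len(S)) {
    incl <- included_cols(design, i, st[, i])
    beta <- draw_beta(design$per_species[[i]], incl, pvar, v_w[i])
    r[i] <- beta[1]
    a[i, ] <- beta[1L + seq_len(S)]
    if (design$higher_order) {
      a3[i] <- beta[design$p - 1L]
      a4[i] <- beta[design$p]
    }
  }
  out <- list(r = stats::setNames(r, design$species), a = a)
  if (design$higher_order) { out$a3 <- a3; out$a4 <- a4 }
  out
}

# normalize user-facing z (matrix or list) to the p x S column-state form
as_indicator_state <- function(design, z) {
  S <- design$S
  if (is.list(z) && !is.matrix(z)) {
    zm <- z$z; z3 <- z$z3; z4 <- z$z4
  } else {
    zm <- z; z3 <- rep(1, S); z4 <- rep(1, S)
  }
  st <- matrix(1, design$p, S)
  for (i in seq_len(S)) {
    st[1L + seq_len(S), i] <- zm[i, ]
    st[1L + i, i] <- 1
    if (design$higher_order) {
      st[design$p - 1L, i] <- z3[i]
      st[design$p, i] <- z4[i]
    }
  }
  st
}

state_to_z <- function(design, st) {
  S <- design$S
  zm <- matrix(1, S, S, dimnames = list(design$species, design$species))
  for (i in seq_len(S)) zm[i, ] <- st[1L + seq_len(S), i]
  diag(zm) <- 1
  out <- list(z = zm)
  if (design$higher_order) {
    out$z3 <- st[design$p - 1L, ]
    out$z4 <- st[design$p, ]
  }
  out
}

#' Collapsed Gibbs update of the edge indicators
#'
#' Updates each off-diagonal (and higher-order) indicator in turn with
#' its coefficient integrated out analytically: the inclusion odds are
#' the ratio of the two marginal likelihoods (edge in / edge out, other
#' indicators held at their current values) times the prior odds.
#' Diagonal indicators stay fixed at 1.
#'
#' @inheritParams sample_coefficients
#' @param edge_prior_prob prior inclusion probability.
#' @return updated indicators, in the same shape as `z` (matrix, or list
#'   with `z`, `z3`, `z4` for higher-order designs).
#' @export
sample_indicators <- function(design, v_r, v_a, v_w, z,
                              edge_prior_prob = 0.5) {
  st <- as_indicator_state(design, z)
  v_w <- rep_len(v_w, design$S)
  pvar <- prior_var_by_col(design, v_r, v_a)
  lpo <- log(edge_prior_prob) - log1p(-edge_prior_prob)
  for (i in seq_len(design$S)) {
    d <- design$per_species[[i]]
    for (c in which(design$free[, i])) {
      st[c, i] <- 1
      m1 <- marg_loglik(d, which(included_cols(design, i, st[, i])), pvar, v_w[i])
      st[c, i] <- 0
      m0 <- marg_loglik(d, which(included_cols(design, i, st[, i])), pvar, v_w[i])
      p1 <- stats::plogis(m1 - m0 + lpo)
      st[c, i] <- as.numeric(stats::runif(1) < p1)
    }
  }
  out <- state_to_z(design, st)
  if (is.matrix(z)) out$z else out
}

rinvchisq <- function(nu, tau2) nu * tau2 / stats::rchisq(1, df = nu)

#' Conjugate update of the variance parameters
#'
#' Scaled inverse-chi-squared conjugacy: with prior `Inv-chi^2(eta,
#' theta)` and `n` Gaussian contributions with sum of squares `SS`, the
#' posterior is `Inv-chi^2(eta + n, (eta theta + SS) / (eta + n))`.
#' `v_r` collects the S growth rates, `v_a` all interaction (and
#' higher-order) coefficients including excluded ones (which are prior
#' draws), and each `v_w[i]` the dt-standardized residuals of species i's
#' included columns.
#'
#' @inheritParams sample_coefficients
#' @param coefs a coefficient draw as returned by
#'   [sample_coefficients()].
#' @param priors a [prior_hyperparameters()] object.
#' @return list with scalars `v_r`, `v_a` and vector `v_w`.
#' @export
sample_variances <- function(design, coefs, z, priors) {
  st <- as_indicator_state(design, z)
  S <- design$S
  ss_r <- sum(coefs$r^2)
  a_all <- as.vector(coefs$a)
  if (design$higher_order) a_all <- c(a_all, coefs$a3, coefs$a4)
  ss_a <- sum(a_all^2)
  n_a <- length(a_all)
  v_r <- rinvchisq(priors$eta_r + S,
                   (priors$eta_r * priors$theta_r + ss_r) / (priors$eta_r + S))
  v_a <- rinvchisq(priors$eta_a + n_a,
                   (priors$eta_a * priors$theta_a + ss_a) / (priors$eta_a + n_a))
  v_w <- numeric(S)
  for (i in seq_len(S)) {
    d <- design$per_species[[i]]
    beta <- c(coefs$r[i], coefs$a[i, ],
              if (design$higher_order) c(coefs$a3[i], coefs$a4[i]))
    beta_eff <- beta * included_cols(design, i, st[, i])
    ss <- d$yy - 2 * sum(beta_eff * d$cy) +
      drop(beta_eff %*% d$G %*% beta_eff)
    ss <- max(ss, 0)
    v_w[i] <- rinvchisq(priors$eta_w + d$n,
                        (priors$eta_w * priors$theta_w + ss) /
                          (priors$eta_w + d$n))
  }
  list(v_r = v_r, v_a = v_a, v_w = v_w)
}

ridge_init <- function(design) {
  lapply(design$per_species, function(d) {
    # column-equilibrated ridge solve: raw CFU/ml covariates span ~9
    # orders of magnitude across columns
    sc <- sqrt(diag(d$G))
    sc[sc <= 0] <- 1
    Gs <- d$G / (sc %o% sc)
    u <- solve(Gs + diag(1e-6, nrow(Gs)), d$cy / sc)
    drop(u / sc)
  })
}

#' Run the spike-and-slab gLV Gibbs sampler
#'
#' Systematic-scan Gibbs over, per sweep: the edge indicators (collapsed,
#' coefficients integrated out), the coefficients given the indicators,
#' and the variance parameters. Deterministic initialization: all
#' indicators on, coefficients from a ridge-regularized least-squares
#' fit, `v_r` and `v_a` at their prior scales and `v_w` at the ridge
#' residual variance.
#'
#' @param design a [build_design()] object.
#' @param priors a [prior_hyperparameters()] object.
#' @param config a [mcmc_config()] object.
#' @return a `glv_posterior`: retained draws of `r` (draws x S), `a` and
#'   `z` (draws x S^2, column-major `a[i,j]`), `v_r`, `v_a`, `v_w`
#'   (draws x S), plus `a3`, `a4`, `z3`, `z4` for higher-order runs, and
#'   the config/priors/species metadata.
#' @export
run_mcmc <- function(design, priors = prior_hyperparameters(),
                     config = mcmc_config()) {
  stopifnot(inherits(design, "glv_design_matrix"))
  if (config$higher_order && !design$higher_order) {
    stop("config requests higher-order terms but the design has no product columns",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  fixv <- config$fix_variances
  init_beta <- ridge_init(design)
  init_vw <- vapply(seq_len(design$S), function(i) {
    d <- design$per_species[[i]]
    b <- init_beta[[i]]
    max((d$yy - 2 * sum(b * d$cy) + drop(b %*% d$G %*% b)) / max(d$n, 1),
        priors$theta_w)
  }, numeric(1))

  if (config$engine == "compiled") {
    draws <- gibbs_kernel(
      lapply(design$per_species, function(d) d$G),
      lapply(design$per_species, function(d) d$cy),
      vapply(design$per_species, function(d) d$yy, numeric(1)),
      vapply(design$per_species, function(d) as.numeric(d$n), numeric(1)),
      design$free * 1L,
      as.integer(design$col_type == "r"),
      c(priors$eta_r, priors$theta_r, priors$eta_a, priors$theta_a,
        priors$eta_w, priors$theta_w, priors$edge_prior_prob),
      config$iterations, config$burn_in,
      !is.null(fixv),
      if (is.null(fixv)) priors$theta_r else fixv$v_r,
      if (is.null(fixv)) priors$theta_a else fixv$v_a,
      if (is.null(fixv)) init_vw else rep_len(fixv$v_w, design$S),
      do.call(cbind, init_beta)
    )
  } else {
    draws <- gibbs_r_engine(design, priors, config, init_beta, init_vw)
  }
  build_posterior(design, priors, config, draws)
}

gibbs_r_engine <- function(design, priors, config, init_beta, init_vw) {
  S <- design$S; p <- design$p
  fixv <- config$fix_variances
  v_r <- if (is.null(fixv)) priors$theta_r else fixv$v_r
  v_a <- if (is.null(fixv)) priors$theta_a else fixv$v_a
  v_w <- if (is.null(fixv)) init_vw else rep_len(fixv$v_w, S)
  z0 <- state_to_z(design, matrix(1, p, S))
  n_keep <- config$iterations - config$burn_in
  out <- list(r = matrix(NA_real_, n_keep, S),
              a = matrix(NA_real_, n_keep, S * S),
              z = matrix(NA_real_, n_keep, S * S),
              v_r = numeric(n_keep), v_a = numeric(n_keep),
              v_w = matrix(NA_real_, n_keep, S))
  if (design$higher_order) {
    out$a3 <- out$z3 <- out$a4 <- out$z4 <- matrix(NA_real_, n_keep, S)
  }
  zz <- if (design$higher_order) z0 else z0$z
  for (it in seq_len(config$iterations)) {
    zz <- sample_indicators(design, v_r, v_a, v_w, zz,
                            priors$edge_prior_prob)
    coefs <- sample_coefficients(design, zz, v_r, v_a, v_w)
    if (is.null(fixv)) {
      vs <- sample_variances(design, coefs, zz, priors)
      v_r <- vs$v_r; v_a <- vs$v_a; v_w <- vs$v_w
    }
    if (it > config$burn_in) {
      k <- it - config$burn_in
      out$r[k, ] <- coefs$r
      out$a[k, ] <- as.vector(coefs$a)
      zmat <- if (is.matrix(zz)) zz else zz$z
      out$z[k, ] <- as.vector(zmat)
      out$v_r[k] <- v_r; out$v_a[k] <- v_a; out$v_w[k, ] <- v_w
      if (design$higher_order) {
        out$a3[k, ] <- coefs$a3; out$a4[k, ] <- coefs$a4
        out$z3[k, ] <- zz$z3; out$z4[k, ] <- zz$z4
      }
    }
  }
  out
}

build_posterior <- function(design, priors, config, draws) {
  structure(
    c(draws,
      list(species = design$species, higher_order = design$higher_order,
           priors = priors, config = config)),
    class = "glv_posterior"
  )
}

#' @export
print.glv_posterior <- function(x, ...) {
  cat(sprintf("gLV posterior: %d retained draws, %d species%s\n",
              nrow(x$r), length(x$species),
              if (x$higher_order) ", higher-order terms" else ""))
  invisible(x)
}

#' Per-edge Bayes factors from posterior inclusion frequencies
#'
#' `BF = [p / (1 - p)] / [pi / (1 - pi)]` where `p` is the fraction of
#' retained draws in which the edge indicator was 1 and `pi` the prior
#' inclusion probability. An edge included in every retained draw has an
#' infinite Bayes factor (flagged in the `infinite` column); an edge
#' never included has BF 0. With `pseudo_count = TRUE` a Jeffreys-style
#' estimator `(k + 0.5) / (n - k + 0.5)` replaces the raw posterior odds
#' (finite values convenient for plotting).
#'
#' @param samples a `glv_posterior`.
#' @param edge_prior_prob prior inclusion probability (default from the
#'   run's priors).
#' @param pseudo_count use the pseudo-count odds estimator?
#' @return data frame with columns `source`, `target`, `order`,
#'   `inclusion_prob`, `bayes_factor`, `infinite`.
#' @export
bayes_factors <- function(samples, edge_prior_prob = NULL,
                          pseudo_count = FALSE) {
  if (is.null(edge_prior_prob)) {
    edge_prior_prob <- samples$priors$edge_prior_prob
  }
  S <- length(samples$species)
  n <- nrow(samples$z)
  prior_odds <- edge_prior_prob / (1 - edge_prior_prob)
  odds <- function(k) {
    if (pseudo_count) return((k + 0.5) / (n - k + 0.5))
    p <- k / n
    ifelse(p == 1, Inf, p / (1 - p))
  }
  rows <- list()
  for (j in seq_len(S)) for (i in seq_len(S)) {
    if (i == j) next
    k <- sum(samples$z[, (j - 1L) * S + i])
    rows[[length(rows) + 1L]] <- data.frame(
      source = samples$species[j], target = samples$species[i],
      order = 2L, inclusion_prob = k / n,
      bayes_factor = odds(k) / prior_odds,
      infinite = k == n, stringsAsFactors = FALSE)
  }
  if (samples$higher_order) {
    for (ord in c(3L, 4L)) {
      zm <- samples[[paste0("z", ord)]]
      for (i in seq_len(S)) {
        k <- sum(zm[, i])
        rows[[length(rows) + 1L]] <- data.frame(
          source = sprintf("order%d", ord), target = samples$species[i],
          order = ord, inclusion_prob = k / n,
          bayes_factor = odds(k) / prior_odds,
          infinite = k == n, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize the inferred interaction network
#'
#' Per candidate edge: the Bayes factor, the conventional evidence
#' category (`none` for BF < 3, `substantial` for BF in [3, 10],
#' `strong` for BF > 10), the posterior mean coefficient conditional on
#' inclusion, and its sign. Edges never included report `NA` strength.
#'
#' @param samples a `glv_posterior`.
#' @param bf optional precomputed [bayes_factors()] table.
#' @return a `glv_network_summary` data frame: `source`, `target`,
#'   `order`, `inclusion_prob`, `bayes_factor`, `infinite`, `evidence`,
#'   `mean_strength`, `sign`.
#' @export
summarize_network <- function(samples, bf = NULL) {
  if (is.null(bf)) bf <- bayes_factors(samples)
  S <- length(samples$species)
  cond_mean <- function(coef_draws, z_draws) {
    k <- sum(z_draws)
    if (k == 0) return(NA_real_)
    sum(coef_draws[z_draws > 0]) / k
  }
  strength <- numeric(nrow(bf))
  for (row in seq_len(nrow(bf))) {
    i <- match(bf$target[row], samples$species)
    if (bf$order[row] == 2L) {
      j <- match(bf$source[row], samples$species)
      col <- (j - 1L) * S + i
      strength[row] <- cond_mean(samples$a[, col], samples$z[, col])
    } else {
      ord <- bf$order[row]
      strength[row] <- cond_mean(samples[[paste0("a", ord)]][, i],
                                 samples[[paste0("z", ord)]][, i])
    }
  }
  # none < 3, substantial in [3, 10], strong > 10 (infinite BF is strong)
  bf$evidence <- ifelse(bf$bayes_factor < 3, "none",
                        ifelse(bf$bayes_factor <= 10, "substantial",
                               "strong"))
  bf$mean_strength <- strength
  bf$sign <- sign(strength)
  class(bf) <- c("glv_network_summary", "data.frame")
  bf
}
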