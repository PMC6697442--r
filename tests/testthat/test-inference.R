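test_that("design rows and covariates match the hand linearization", {
  # 2 species, 2 time points: one row per species with hand-checked entries
  x <- matrix(c(1e6, 2e6,
                3e6, 5e6), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  tr <- ssglv:::new_trajectory(c(0, 2), x, "C1", 1L)
  d <- build_design(list(tr))
  sq <- sqrt(2)
  # species A: response (3e6 - 1e6)/sqrt(2); covariates x_A*sqrt(dt),
  # x_A*x_A*sqrt(dt), x_A*x_B*sqrt(dt)
  expect_equal(d$per_species$A$y, 2e6 / sq)
  expect_equal(drop(d$per_species$A$X), c(1e6 * sq, 1e12 * sq, 2e12 * sq))
  expect_equal(d$per_species$B$y, 3e6 / sq)
  expect_equal(drop(d$per_species$B$X), c(2e6 * sq, 2e12 * sq, 4e12 * sq))
  expect_equal(d$p, 3L)  # no product columns without higher_order

  # T points -> T-1 rows per species when nothing is censored
  tr8 <- glv_simulate(two_species_params(), c(1e6, 1e6), seq(0, 21, 3))
  d8 <- build_design(list(tr8))
  expect_true(all(vapply(d8$per_species, function(s) s$n, 1) == 7))
})

test_that("higher-order designs append the two product columns", {
  tr <- glv_simulate(two_species_params(), c(1e6, 2e6), c(0, 2, 4))
  d <- build_design(list(tr), higher_order = TRUE)
  expect_equal(d$p, 5L)
  x <- tr$abundances
  sq <- sqrt(2)
  # species A at the first step: prod_{j != A} x_j = x_B, prod_j = x_A x_B
  expect_equal(d$per_species$A$X[1, 4], unname(x[1, 1] * x[1, 2]) * sq)
  expect_equal(d$per_species$A$X[1, 5],
               unname(x[1, 1] * x[1, 1] * x[1, 2]) * sq)
})

test_that("censored rows are excluded from the design", {
  x <- matrix(c(1e6, 1e6,
                1e3, 2e6,
                5e5, 4e6,
                9e5, 8e6), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  cens <- matrix(FALSE, 4, 2); cens[2, 1] <- TRUE
  tr <- ssglv:::new_trajectory(c(0, 2, 4, 6), x, "C1", 1L, cens)
  d <- build_design(list(tr))
  # species A loses the two rows touching its censored point, B keeps all
  expect_equal(d$per_species$A$n, 1L)
  expect_equal(d$per_species$B$n, 3L)
  # keep policy retains every row with positive source abundance
  d_keep <- build_design(list(tr), floor_policy = "keep")
  expect_equal(d_keep$per_species$A$n, 3L)
  # a fully censored species is an error
  cens_all <- matrix(c(TRUE, FALSE), 4, 2)
  tr_bad <- ssglv:::new_trajectory(c(0, 2, 4, 6), x, "C1", 1L, cens_all)
  expect_error(build_design(list(tr_bad)), "censored")
})

test_that("coefficient draws follow the conjugate Gaussian posterior", {
  # 1-parameter toy design: y = X b + noise, closed-form posterior
  X <- c(1, 2, 3, 4)
  y <- c(1.1, 1.9, 3.2, 3.9)
  vw <- 0.25; vb <- 4
  d <- make_toy_design(X, y)
  prec <- sum(X^2) / vw + 1 / vb
  post_mean <- (sum(X * y) / vw) / prec
  post_var <- 1 / prec
  set.seed(1)
  draws <- replicate(20000, sample_coefficients(d, matrix(1, 1, 1),
                                                v_r = vb, v_a = 1,
                                                v_w = vw)$r)
  expect_equal(mean(draws), post_mean,
               tolerance = 3 * sqrt(post_var / 20000) / abs(post_mean))
  expect_equal(var(draws), post_var, tolerance = 0.05)
})

test_that("empty designs and masked columns fall back to the prior", {
  # no rows: draws are prior draws
  d0 <- make_toy_design(numeric(0), numeric(0))
  set.seed(2)
  draws <- replicate(5000, sample_coefficients(d0, matrix(1, 1, 1),
                                               v_r = 0.04, v_a = 1,
                                               v_w = 1)$r)
  expect_equal(mean(draws), 0, tolerance = 3 * 0.2 / sqrt(5000))
  expect_equal(sd(draws), 0.2, tolerance = 0.02)

  # masked edge: draws independent of the data (prior spread)
  design <- two_species_design(seed = 101)
  z_off <- matrix(c(1, 0, 0, 1), 2, 2)
  set.seed(3)
  va <- 1e-18
  aa <- replicate(3000, sample_coefficients(design, z_off, v_r = 0.25,
                                            v_a = va, v_w = 1e9)$a[1, 2])
  expect_equal(sd(aa), sqrt(va), tolerance = 0.06)
  expect_equal(mean(aa), 0, tolerance = 3 * sqrt(va / 3000))
})

test_that("a zero covariate column keeps its prior inclusion probability", {
  design <- two_species_design(seed = 101)
  # zero out the free column of species A (edge B -> A)
  design$per_species$A$X[, 3] <- 0
  design$per_species$A$G <- crossprod(design$per_species$A$X)
  design$per_species$A$cy <- drop(crossprod(design$per_species$A$X,
                                            design$per_species$A$y))
  set.seed(4)
  z <- matrix(1, 2, 2)
  hits <- replicate(4000, sample_indicators(design, 0.25, 1e-18, c(1e9, 1e9),
                                            z, edge_prior_prob = 0.3)[1, 2])
  expect_equal(mean(hits), 0.3, tolerance = 3 * sqrt(0.3 * 0.7 / 4000))
})

test_that("variance updates match scaled-inverse-chi-squared conjugacy", {
  design <- two_species_design(seed = 101)
  priors <- prior_hyperparameters()
  coefs <- list(r = c(0.4, 0.3),
                a = matrix(c(-4e-10, -1.5e-10, 0, -3e-10), 2, 2,
                           byrow = TRUE))
  # v_w for species A: posterior mean nu* tau*^2 / (nu* - 2) with the
  # residual sum of squares computed independently from the raw rows
  dA <- design$per_species$A
  beta <- c(coefs$r[1], coefs$a[1, ])
  ss <- sum((dA$y - dA$X %*% beta)^2)
  nu <- priors$eta_w + dA$n
  tau2 <- (priors$eta_w * priors$theta_w + ss) / nu
  set.seed(5)
  vw <- replicate(20000, sample_variances(design, coefs, matrix(1, 2, 2),
                                          priors)$v_w[1])
  expect_equal(mean(vw), nu * tau2 / (nu - 2),
               tolerance = 3 * sd(vw) / sqrt(20000) / (nu * tau2 / (nu - 2)))

  # doubling the coefficients quadruples the sum-of-squares contribution
  coefs2 <- list(r = 2 * coefs$r, a = 2 * coefs$a)
  set.seed(6); m1 <- mean(replicate(5000, sample_variances(design, coefs,
                            matrix(1, 2, 2), priors)$v_a))
  set.seed(6); m2 <- mean(replicate(5000, sample_variances(design, coefs2,
                            matrix(1, 2, 2), priors)$v_a))
  ss1 <- priors$eta_a * priors$theta_a + sum(coefs$a^2)
  ss2 <- priors$eta_a * priors$theta_a + sum((2 * coefs$a)^2)
  expect_equal(m2 / m1, ss2 / ss1, tolerance = 0.05)
})

test_that("default run keeps 4000 draws and is seed-reproducible", {
  design <- two_species_design(seed = 101)
  f1 <- run_mcmc(design, config = mcmc_config(seed = 21))
  expect_equal(nrow(f1$r), 4000L)
  expect_equal(nrow(f1$z), 4000L)
  f2 <- run_mcmc(design, config = mcmc_config(seed = 21))
  expect_identical(f1$r, f2$r)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$v_w, f2$v_w)
})

test_that("a strong true interaction is detected essentially always", {
  # dense sampling, low noise, strong edge B -> A
  params <- glv_params(c("A", "B"), c(0.40, 0.30),
                       matrix(c(-4e-10, -3e-10, 0, -3e-10), 2, 2,
                              byrow = TRUE),
                       process_noise_var = c(1e6, 1e6))
  set.seed(31)
  trajs <- list(
    glv_simulate(params, c(1e6, 1e6), seq(0, 24, 2), stochastic = TRUE,
                 condition_label = "C1"),
    glv_simulate(params, c(1e5, 1e6), seq(0, 24, 2), stochastic = TRUE,
                 condition_label = "C2"))
  fit <- run_mcmc(build_design(trajectory_set(trajs)),
                  config = mcmc_config(seed = 31))
  bf <- bayes_factors(fit)
  expect_gt(bf$inclusion_prob[bf$source == "B" & bf$target == "A"], 0.99)
})

test_that("compiled and R engines agree distributionally", {
  design <- two_species_design(seed = 101)
  fR <- run_mcmc(design, config = mcmc_config(3000, 500, seed = 41,
                                              engine = "R"))
  fC <- run_mcmc(design, config = mcmc_config(12000, 1000, seed = 42))
  expect_equal(colMeans(fR$z), colMeans(fC$z), tolerance = 0.05)
  expect_equal(colMeans(fR$r), colMeans(fC$r), tolerance = 0.02)
  expect_equal(colMeans(fR$v_w) / colMeans(fC$v_w), c(1, 1),
               tolerance = 0.25)
})

test_that("bayes factors transform inclusion frequencies correctly", {
  fake <- structure(list(
    species = c("A", "B"), higher_order = FALSE,
    priors = prior_hyperparameters(),
    z = cbind(rep(1, 10), c(rep(1, 5), rep(0, 5)),
              c(rep(1, 9), 0), rep(0, 10)),
    a = matrix(rnorm(40), 10, 4)), class = "glv_posterior")
  # columns (j-1)*S+i: col2 = edge A->B (p=0.5), col3 = edge B->A (p=0.9)
  bf <- bayes_factors(fake, edge_prior_prob = 0.5)
  expect_equal(bf$bayes_factor[bf$source == "A" & bf$target == "B"], 1)
  expect_equal(bf$bayes_factor[bf$source == "B" & bf$target == "A"], 9)
  # monotone in inclusion frequency; equals 1 at the prior
  p_seq <- seq(0.05, 0.95, 0.05)
  bfs <- (p_seq / (1 - p_seq)) / 1
  expect_true(all(diff(bfs) > 0))

  # endpoint conventions: always included -> infinite, never -> zero
  fake$z[, 2] <- 1
  fake$z[, 3] <- 0
  bf2 <- bayes_factors(fake)
  expect_true(is.infinite(bf2$bayes_factor[bf2$source == "A" &
                                             bf2$target == "B"]))
  expect_true(bf2$infinite[bf2$source == "A" & bf2$target == "B"])
  expect_equal(bf2$bayes_factor[bf2$source == "B" & bf2$target == "A"],
               0)
  # pseudo-count estimator stays finite
  bf3 <- bayes_factors(fake, pseudo_count = TRUE)
  expect_true(all(is.finite(bf3$bayes_factor)))
})

test_that("evidence categories follow the 3/10 thresholds", {
  fake <- structure(list(
    species = c("A", "B"), higher_order = FALSE,
    priors = prior_hyperparameters(),
    z = cbind(rep(1, 40), c(rep(1, 30), rep(0, 10)),
              c(rep(1, 37), rep(0, 3)), rep(1, 40)),
    a = matrix(1, 40, 4)), class = "glv_posterior")
  s <- summarize_network(fake)
  # p = 0.75 -> BF 3 (substantial, boundary); p = 0.925 -> BF ~12.3 (strong)
  expect_equal(s$evidence[s$source == "A" & s$target == "B"], "substantial")
  expect_equal(s$evidence[s$source == "B" & s$target == "A"], "strong")
  expect_equal(s$bayes_factor[s$source == "A" & s$target == "B"], 3)
  # conditional-on-inclusion mean strength and sign
  expect_equal(s$mean_strength[s$source == "A" & s$target == "B"], 1)
  expect_equal(s$sign[s$source == "A" & s$target == "B"], 1)
})

test_that("network summaries flag never-included edges as undefined", {
  fake <- structure(list(
    species = c("A", "B"), higher_order = FALSE,
    priors = prior_hyperparameters(),
    z = cbind(rep(1, 10), rep(0, 10), rep(1, 10), rep(1, 10)),
    a = matrix(2, 10, 4)), class = "glv_posterior")
  s <- summarize_network(fake)
  expect_true(is.na(s$mean_strength[s$source == "A" & s$target == "B"]))
  expect_equal(s$evidence[s$source == "A" & s$target == "B"], "none")
})
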