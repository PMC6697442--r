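test_that("knockdown design has S+1 conditions with the right inocula", {
  for (S in 2:6) {
    sp <- paste0("sp", seq_len(S))
    des <- make_knockdown_design(sp, baseline_inoculum = 1e6,
                                 knockdown_factor = 10)
    expect_length(des$conditions, S + 1L)
    expect_true(all(unlist(des$conditions) > 0))
    for (i in seq_len(S)) {
      inoc <- des$conditions[[i + 1L]]
      expect_equal(unname(inoc[i]), 1e5)
      expect_equal(unname(inoc[-i]), rep(1e6, S - 1L))
    }
  }
  # factor 1: all conditions identical
  des1 <- make_knockdown_design(c("A", "B"), knockdown_factor = 1)
  expect_true(all(vapply(des1$conditions,
                         function(v) all(v == des1$conditions[[1]]),
                         logical(1))))
  expect_error(make_knockdown_design(character(0)), "empty")
})

test_that("design construction is idempotent and order-stable", {
  sp <- c("Ec", "ST", "BT", "BF")
  d1 <- make_knockdown_design(sp)
  d2 <- make_knockdown_design(sp)
  expect_identical(d1, d2)
  expect_identical(names(d1$conditions[[1]]), sp)
})

test_that("wild-type preset is all-antagonistic and seed-stable", {
  p <- preset_wt_network(7)
  offdiag <- p$interaction_matrix[row(p$interaction_matrix) !=
                                    col(p$interaction_matrix)]
  expect_true(all(offdiag <= 0))
  expect_true(all(diag(p$interaction_matrix) < 0))
  expect_true(all(p$growth_rates > 0))
  expect_identical(preset_wt_network(7), p)
  expect_false(identical(preset_wt_network(8)$growth_rates,
                         p$growth_rates))
  # 7 of the 12 candidate edges present
  z <- p$indicator_matrix
  expect_equal(sum(z[row(z) != col(z)]), 7)
})

test_that("engineered preset has the two cross-feeding edges and scaled rates", {
  wt <- preset_wt_network(7)
  en <- preset_engineered_network(7)
  ae <- en$interaction_matrix
  pos <- which(ae > 0 & row(ae) != col(ae), arr.ind = TRUE)
  expect_equal(nrow(pos), 2L)
  expect_setequal(paste(rownames(ae)[pos[, 1]], colnames(ae)[pos[, 2]]),
                  c("Ec BF", "ST BF"))
  expect_equal(mean(en$growth_rates), mean(wt$growth_rates) / 3,
               tolerance = 0.1)
  # carrying capacities ~1.5 orders of magnitude below wild type
  k_wt <- equilibrium_single_species(wt$growth_rates,
                                     diag(wt$interaction_matrix))
  k_en <- equilibrium_single_species(en$growth_rates,
                                     diag(en$interaction_matrix))
  expect_equal(unname(log10(k_wt / k_en)), rep(1.5, 4), tolerance = 0.05)
})

test_that("engineered community is >= 10-fold below wild type at 24 h", {
  des <- make_knockdown_design(preset_species <- preset_wt_network(1)$species,
                               sampling_times = c(0, 2, 4, 7, 11, 16, 21, 24))
  tot24 <- vapply(list(preset_wt_network(1), preset_engineered_network(1)),
                  function(p) {
                    tr <- glv_simulate(p, des$conditions$C1,
                                       des$sampling_times)
                    sum(tr$abundances[8, ])
                  }, numeric(1))
  expect_gte(tot24[1] / tot24[2], 10)
})

test_that("engineered preset ends the batch culture more even than wild type", {
  ev_final <- vapply(list(preset_wt_network(1), preset_engineered_network(1)),
                     function(p) {
                       des <- make_knockdown_design(p$species)
                       tr <- glv_simulate(p, des$conditions$C1,
                                          des$sampling_times)
                       pielou_evenness(tr$abundances[nrow(tr$abundances), ])
                     }, numeric(1))
  expect_gt(ev_final[2], ev_final[1])
  expect_equal(ev_final[1], 0.950, tolerance = 1e-3)
  expect_equal(ev_final[2], 0.981, tolerance = 1e-3)
})

test_that("knocked species in the engineered preset ends closer to baseline", {
  # deterministic logR at the final time, per knockdown condition
  for (kd in 2:5) {
    lr <- vapply(list(preset_wt_network(1), preset_engineered_network(1)),
                 function(p) {
                   des <- make_knockdown_design(p$species)
                   base <- glv_simulate(p, des$conditions$C1,
                                        des$sampling_times)
                   down <- glv_simulate(p, des$conditions[[kd]],
                                        des$sampling_times)
                   l <- log_fold_ratio(down, base)
                   sp <- p$species[kd - 1]
                   utils::tail(l$logR[l$species == sp], 1)
                 }, numeric(1))
    expect_lt(abs(lr[2]), abs(lr[1]))
  }
})

test_that("measurement noise has the configured CV and respects the floor", {
  tr <- glv_simulate(two_species_params(), c(1e6, 1e6), c(0, 1))
  # cv = 0, floor = 0 is the identity
  same <- apply_measurement_noise(tr, noise_model(0, 0), seed = 1)
  expect_identical(same$abundances, tr$abundances)
  expect_true(!any(same$censored))
  # empirical CV over 10,000 draws within 5% of the configured value
  flat <- new_traj_matrix(rep(1e6, 10000))
  noisy <- apply_measurement_noise(flat, noise_model(0.2, 0), seed = 2)
  emp_cv <- sd(noisy$abundances) / mean(noisy$abundances)
  expect_equal(emp_cv, 0.2, tolerance = 0.05)
  expect_equal(mean(noisy$abundances), 1e6, tolerance = 0.02)
  # censoring: nothing below the floor, censored values flagged
  low <- new_traj_matrix(rep(1.1e3, 1000))
  cens <- apply_measurement_noise(low, noise_model(0.5, 1e3), seed = 3)
  expect_true(all(cens$abundances >= 1e3))
  expect_true(any(cens$censored))
  expect_true(all(cens$abundances[cens$censored] == 1e3))
})

test_that("generated datasets have the expected shape and reproduce bitwise", {
  p <- preset_wt_network(2)
  des <- make_knockdown_design(p$species)
  gd <- generate_dataset(p, des, noise_model(), seed = 5)
  expect_equal(nrow(gd$dataset), 5 * 3 * 8 * 4)
  # ground-truth record regenerates the identical dataset
  again <- regenerate_dataset(gd$truth)
  expect_identical(as.data.frame(gd$dataset), as.data.frame(again))
  # byte-identical TSV under the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_trajectories(gd$dataset, f1)
  write_trajectories(generate_dataset(p, des, noise_model(), seed = 5)$dataset, f2)
  expect_identical(readLines(f1), readLines(f2))
  # zero noise, deterministic: dataset equals the deterministic simulation
  quiet <- glv_params(p$species, p$growth_rates, p$interaction_matrix,
                      p$indicator_matrix, process_noise_var = rep(0, 4))
  gd0 <- generate_dataset(quiet, des, noise_model(0, 0), seed = 5,
                          stochastic = FALSE)
  det <- glv_simulate(quiet, des$conditions$C1, des$sampling_times)
  sub <- as.data.frame(gd0$dataset)
  sub <- sub[sub$condition == "C1" & sub$replicate == 1, ]
  expect_equal(sub$abundance_cfu_per_ml, as.vector(t(det$abundances)))
})

test_that("ground-truth YAML round trip regenerates the dataset", {
  p <- preset_engineered_network(4)
  des <- make_knockdown_design(p$species, replicates = 2L)
  gd <- generate_dataset(p, des, noise_model(), seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(gd$truth, path)
  truth2 <- read_ground_truth(path)
  expect_identical(as.data.frame(regenerate_dataset(truth2)),
                   as.data.frame(gd$dataset))
})
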