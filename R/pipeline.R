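#' One-call network inference from a trajectory table
#'
#' Convenience wrapper: builds the regression design, runs the
#' spike-and-slab Gibbs sampler and summarizes the edge evidence.
#'
#' @param trajectories a `glv_trajectory_set` (or tidy data frame / list
#'   of `glv_trajectory`).
#' @param priors a [prior_hyperparameters()] object.
#' @param config a [mcmc_config()] object.
#' @param species optional explicit species ordering.
#' @return list with `samples` (a `glv_posterior`) and `summary` (a
#'   `glv_network_summary`).
#' @export
infer_network <- function(trajectories, priors = prior_hyperparameters(),
                          config = mcmc_config(), species = NULL) {
  design <- build_design(trajectories, higher_order = config$higher_order,
                         species = species)
  samples <- run_mcmc(design, priors, config)
  list(samples = samples, summary = summarize_network(samples))
}

#' Score an inferred network against the ground truth
#'
#' Compares a network summary with the generating parameters: detection
#' rate of true edges at the strong-evidence threshold (BF > 10, with
#' infinite BF counting as detected), false-edge rate of absent edges at
#' the substantial-evidence threshold (BF > 3), sign accuracy among
#' detected edges (BF > 3), and the RMSE between conditional posterior
#' mean coefficients and truth over the true edges. When a dataset is
#' supplied, the evenness trajectory of its baseline condition is
#' compared (mean absolute difference) with the noiseless deterministic
#' evenness trajectory implied by the ground truth.
#'
#' @param truth a `glv_ground_truth` record (or a bare `glv_params`
#'   object).
#' @param summary a [summarize_network()] table.
#' @param dataset optional `glv_trajectory_set` used for the evenness
#'   comparison (requires a full ground-truth record).
#' @return a `glv_recovery_report` list.
#' @export
evaluate_recovery <- function(truth, summary, dataset = NULL) {
  params <- if (inherits(truth, "glv_ground_truth")) truth$params else truth
  species <- params$species
  pair <- summary[summary$order == 2L, , drop = FALSE]
  if (!setequal(unique(c(pair$source, pair$target)), species)) {
    stop("species sets of truth and summary differ", call. = FALSE)
  }
  i <- match(pair$target, species)
  j <- match(pair$source, species)
  true_z <- params$indicator_matrix[cbind(i, j)] == 1 &
    params$interaction_matrix[cbind(i, j)] != 0
  true_a <- params$interaction_matrix[cbind(i, j)]
  bf <- pair$bayes_factor

  detected <- bf > 3
  strong <- bf > 10
  sign_ok <- sign(pair$mean_strength) == sign(true_a)
  per_edge <- data.frame(
    source = pair$source, target = pair$target,
    true_edge = true_z, true_coef = true_a,
    bayes_factor = bf, evidence = pair$evidence,
    inferred_sign = sign(pair$mean_strength),
    sign_match = ifelse(detected & true_z, sign_ok, NA),
    stringsAsFactors = FALSE
  )
  detection_rate <- if (any(true_z)) mean(strong[true_z]) else NA_real_
  false_edge_rate <- if (any(!true_z)) mean(detected[!true_z]) else 0
  det_true <- detected & true_z
  sign_accuracy <- if (any(det_true)) mean(sign_ok[det_true]) else NA_real_
  coef_rmse <- if (any(true_z)) {
    err <- pair$mean_strength[true_z] - true_a[true_z]
    sqrt(mean(err[!is.na(err)]^2))
  } else NA_real_

  evenness_mad <- NA_real_
  if (!is.null(dataset) && inherits(truth, "glv_ground_truth")) {
    des <- truth$design
    base_label <- names(des$conditions)[1]
    det <- glv_simulate(params, des$conditions[[base_label]],
                        des$sampling_times, stochastic = FALSE,
                        substeps = truth$substeps)
    ev_true <- apply(det$abundances, 1, pielou_evenness)
    df <- as.data.frame(dataset)
    df <- df[df$condition == base_label, ]
    obs <- logr_median_table(df)
    ev_obs <- apply(obs, 1, pielou_evenness)
    evenness_mad <- mean(abs(ev_true - ev_obs))
  }

  structure(
    list(per_edge = per_edge,
         detection_rate = detection_rate,
         false_edge_rate = false_edge_rate,
         sign_accuracy = sign_accuracy,
         coef_rmse = coef_rmse,
         evenness_mad = evenness_mad),
    class = "glv_recovery_report"
  )
}

#' @export
print.glv_recovery_report <- function(x, ...) {
  cat(sprintf(
    "network recovery: detection %.2f (BF>10), false-edge rate %.2f (BF>3), sign accuracy %s, coef RMSE %s\n",
    x$detection_rate, x$false_edge_rate,
    ifelse(is.na(x$sign_accuracy), "NA", sprintf("%.2f", x$sign_accuracy)),
    ifelse(is.na(x$coef_rmse), "NA", sprintf("%.3g", x$coef_rmse))))
  invisible(x)
}

#' Write a network summary as TSV
#'
#' @param summary a `glv_network_summary`.
#' @param path output file.
#' @export
write_network_summary <- function(summary, path) {
  df <- as.data.frame(summary)
  df$bayes_factor <- ifelse(is.infinite(df$bayes_factor), "Inf",
                            sprintf("%.17g", df$bayes_factor))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
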