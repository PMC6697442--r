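#' Build an inoculum-knockdown study design
#'
#' The design mirrors the five-condition batch-coculture experiment: one
#' equal-inoculum baseline condition, plus one condition per species in
#' which only that species' starting inoculum is divided by
#' `knockdown_factor` (10-fold by default). Conditions are labelled
#' `C1` (baseline) and `C2..C(S+1)` (knockdown of species 1..S, in the
#' species ordering given).
#'
#' @param species character vector of species labels.
#' @param baseline_inoculum positive abundance vector (CFU/ml), length S
#'   (or a single value recycled).
#' @param knockdown_factor fold-reduction of the knocked species'
#'   inoculum, >= 1.
#' @param sampling_times strictly increasing sampling grid (hours);
#'   default 8 points over the 27-h batch horizon.
#' @param replicates number of replicate cultures per condition.
#' @return a `glv_design`: list with `species`, `conditions` (named list
#'   of inoculum vectors), `sampling_times`, `replicates`.
#' @export
make_knockdown_design <- function(species,
                                  baseline_inoculum = 1e6,
                                  knockdown_factor = 10,
                                  sampling_times = c(0, 2, 4, 7, 11, 16, 21, 27),
                                  replicates = 3L) {
  species <- as.character(species)
  S <- length(species)
  if (S == 0L) stop("species set is empty", call. = FALSE)
  if (length(baseline_inoculum) == 1L) {
    baseline_inoculum <- rep(baseline_inoculum, S)
  }
  baseline_inoculum <- as.numeric(baseline_inoculum)
  if (length(baseline_inoculum) != S || any(baseline_inoculum <= 0)) {
    stop("baseline_inoculum must be positive, one value per species",
         call. = FALSE)
  }
  if (knockdown_factor < 1) stop("knockdown_factor must be >= 1", call. = FALSE)
  sampling_times <- as.numeric(sampling_times)
  if (length(sampling_times) < 2L || any(diff(sampling_times) <= 0)) {
    stop("sampling_times must be strictly increasing", call. = FALSE)
  }
  names(baseline_inoculum) <- species
  conditions <- vector("list", S + 1L)
  names(conditions) <- paste0("C", seq_len(S + 1L))
  conditions[[1L]] <- baseline_inoculum
  for (i in seq_len(S)) {
    inoc <- baseline_inoculum
    inoc[i] <- inoc[i] / knockdown_factor
    conditions[[i + 1L]] <- inoc
  }
  structure(
    list(species = species, conditions = conditions,
         sampling_times = sampling_times,
         replicates = as.integer(replicates)),
    class = "glv_design"
  )
}

#' @export
print.glv_design <- function(x, ...) {
  cat(sprintf("knockdown design: %d species, %d conditions, %d replicates, %d time points (%g-%g h)\n",
              length(x$species), length(x$conditions), x$replicates,
              length(x$sampling_times), min(x$sampling_times),
              max(x$sampling_times)))
  invisible(x)
}

#' Measurement noise model for qPCR-like quantification
#'
#' Multiplicative lognormal measurement error with a given coefficient of
#' variation, plus a lower detection floor: values below the floor are
#' reported at the floor and flagged as censored (retained, not dropped,
#' so inference can exclude them).
#'
#' @param measurement_cv coefficient of variation of the lognormal
#'   multiplicative error (0 disables it).
#' @param detection_floor detection floor in CFU/ml (0 disables it).
#' @return a `glv_noise_model` list.
#' @export
noise_model <- function(measurement_cv = 0.05, detection_floor = 1e3) {
  if (measurement_cv < 0) stop("measurement_cv must be >= 0", call. = FALSE)
  if (detection_floor < 0) stop("detection_floor must be >= 0", call. = FALSE)
  structure(list(measurement_cv = measurement_cv,
                 detection_floor = detection_floor),
            class = "glv_noise_model")
}

#' Apply measurement noise and detection-floor censoring to a trajectory
#'
#' Each abundance is multiplied by an i.i.d. lognormal factor with mean 1
#' and the configured CV (`sdlog^2 = log(1 + cv^2)`, `meanlog =
#' -sdlog^2/2`); results below the detection floor are set to the floor
#' and flagged in the trajectory's `censored` matrix.
#'
#' @param traj a `glv_trajectory`.
#' @param noise a [noise_model()].
#' @param seed optional integer seed for reproducibility.
#' @return a `glv_trajectory` with noisy abundances and censoring flags.
#' @export
apply_measurement_noise <- function(traj, noise, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- traj$abundances
  if (noise$measurement_cv > 0) {
    sdlog <- sqrt(log(1 + noise$measurement_cv^2))
    fac <- matrix(stats::rlnorm(length(x), -sdlog^2 / 2, sdlog),
                  nrow(x), ncol(x))
    x <- x * fac
  }
  cens <- x < noise$detection_floor
  x[cens] <- noise$detection_floor
  new_trajectory(traj$times, x, traj$condition_label, traj$replicate_id,
                 censored = cens | traj$censored)
}

preset_species <- c("Ec", "ST", "BT", "BF")

#' Ground-truth network preset: wild-type-like consortium
#'
#' Four-species parameter set emulating a consortium dominated by
#' antagonism: all off-diagonal interactions are `<= 0`, with 7 of the 12
#' candidate edges present (strongly negative) and 5 absent. Carrying
#' capacities sit near 1e9 CFU/ml. The `seed` draws a mild (+/-10%)
#' multiplicative jitter on rates and coefficient magnitudes; the same
#' seed always returns identical parameters.
#'
#' @param seed integer jitter seed; `NULL` returns the unjittered base
#'   values.
#' @return a [glv_params()] object.
#' @export
preset_wt_network <- function(seed = NULL) {
  r <- c(Ec = 0.30, ST = 0.35, BT = 0.25, BF = 0.28)
  K <- 1e9
  # edge strengths as fractions of each target's self-limitation at K
  frac <- matrix(0, 4, 4, dimnames = list(preset_species, preset_species))
  frac["Ec", "ST"] <- 0.40
  frac["Ec", "BT"] <- 0.30
  frac["ST", "Ec"] <- 0.30
  frac["BT", "ST"] <- 0.50
  frac["BT", "Ec"] <- 0.30
  frac["BF", "ST"] <- 0.50
  frac["BF", "Ec"] <- 0.25
  jit <- preset_jitter(seed, r)
  r <- r * jit$r
  a <- -(frac * jit$a) * (r / K)     # rows scale by r_i / K (vector recycling)
  diag(a) <- -r / K
  glv_params(preset_species, r, a,
             process_noise_var = rep((1e-5 * K)^2, 4))
}

#' Ground-truth network preset: engineered cross-feeding consortium
#'
#' Emulates the engineered-consortium phenotype: growth rates exactly 1/3
#' of the wild-type preset's, single-species carrying capacities 1.5
#' orders of magnitude lower (~3.2e7 CFU/ml), two positive off-diagonal
#' interactions (from BF to Ec and from BF to ST, the cross-feeding
#' edges) and two remaining negative edges (from ST to the Bacteroides
#' species); the other 8 candidate edges are absent.
#'
#' @inheritParams preset_wt_network
#' @return a [glv_params()] object.
#' @export
preset_engineered_network <- function(seed = NULL) {
  wt <- preset_wt_network(seed)
  r <- wt$growth_rates / 3
  K <- 1e9 / 10^1.5
  frac <- matrix(0, 4, 4, dimnames = list(preset_species, preset_species))
  frac["Ec", "BF"] <- +0.50
  frac["ST", "BF"] <- +0.60
  frac["BT", "ST"] <- -0.40
  frac["BF", "ST"] <- -0.40
  a <- frac * (r / K)
  diag(a) <- -r / K
  glv_params(preset_species, r, a,
             process_noise_var = rep((1e-5 * K)^2, 4))
}

preset_jitter <- function(seed, r) {
  if (is.null(seed)) {
    return(list(r = rep(1, length(r)),
                a = matrix(1, length(r), length(r))))
  }
  set.seed(seed)
  list(r = stats::runif(length(r), 0.9, 1.1),
       a = matrix(stats::runif(length(r)^2, 0.9, 1.1), length(r)))
}

#' Generate a synthetic knockdown dataset
#'
#' Simulates the discrete-time stochastic gLV model for every condition
#' and replicate of a knockdown design, passes each trajectory through
#' the measurement model, and returns the tidy dataset together with a
#' ground-truth record sufficient to regenerate it bitwise.
#'
#' @param params ground-truth [glv_params()].
#' @param design a [make_knockdown_design()] design.
#' @param noise a [noise_model()].
#' @param seed integer master seed.
#' @param stochastic simulate with process noise? Default `TRUE`.
#' @param substeps Euler substeps per sampling interval (default 1: the
#'   discrete-time model is defined on the sampling grid itself).
#' @return list with `dataset` (a `glv_trajectory_set`) and `truth`
#'   (a `glv_ground_truth` record).
#' @export
generate_dataset <- function(params, design, noise = noise_model(),
                             seed = 1L, stochastic = TRUE, substeps = 1L) {
  stopifnot(identical(params$species, design$species))
  set.seed(seed)
  trajs <- list()
  for (cond in names(design$conditions)) {
    for (rep_i in seq_len(design$replicates)) {
      tr <- glv_simulate(params, design$conditions[[cond]],
                         design$sampling_times, stochastic = stochastic,
                         substeps = substeps,
                         condition_label = cond, replicate_id = rep_i)
      trajs[[length(trajs) + 1L]] <- apply_measurement_noise(tr, noise)
    }
  }
  truth <- structure(
    list(params = params, design = design, noise = noise, seed = seed,
         stochastic = stochastic, substeps = as.integer(substeps)),
    class = "glv_ground_truth"
  )
  list(dataset = trajectory_set(trajs), truth = truth)
}

#' Regenerate the dataset recorded in a ground-truth record
#'
#' @param truth a `glv_ground_truth` record.
#' @return the identical `glv_trajectory_set` the record was created with.
#' @export
regenerate_dataset <- function(truth) {
  generate_dataset(truth$params, truth$design, truth$noise, truth$seed,
                   truth$stochastic, truth$substeps)$dataset
}

#' Write / read a ground-truth record as YAML
#'
#' @param truth a `glv_ground_truth` record.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  p <- truth$params
  doc <- list(
    seed = truth$seed,
    stochastic = truth$stochastic,
    substeps = truth$substeps,
    species = as.list(p$species),
    growth_rates = as.list(unname(p$growth_rates)),
    interaction_matrix = apply(p$interaction_matrix, 1, as.list,
                               simplify = FALSE),
    indicator_matrix = apply(p$indicator_matrix, 1, as.list,
                             simplify = FALSE),
    process_noise_var = as.list(unname(p$process_noise_var)),
    design = list(
      conditions = lapply(truth$design$conditions,
                          function(v) as.list(unname(v))),
      sampling_times = as.list(truth$design$sampling_times),
      replicates = truth$design$replicates
    ),
    noise = list(measurement_cv = truth$noise$measurement_cv,
                 detection_floor = truth$noise$detection_floor)
  )
  if (!is.null(p$higher_order)) {
    doc$higher_order <- lapply(p$higher_order, as.list)
  }
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  doc <- yaml::read_yaml(path)
  S <- length(doc$species)
  species <- unlist(doc$species)
  params <- glv_params(
    species = species,
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
  conds <- lapply(doc$design$conditions, function(v) {
    v <- unlist(v); names(v) <- species; v
  })
  design <- structure(
    list(species = species, conditions = conds,
         sampling_times = unlist(doc$design$sampling_times),
         replicates = as.integer(doc$design$replicates)),
    class = "glv_design"
  )
  structure(
    list(params = params, design = design,
         noise = noise_model(doc$noise$measurement_cv,
                             doc$noise$detection_floor),
         seed = doc$seed, stochastic = doc$stochastic,
         substeps = as.integer(doc$substeps)),
    class = "glv_ground_truth"
  )
}
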