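#' Pielou evenness of a community composition
#'
#' Normalized Shannon entropy, `-sum(p_i * log(p_i)) / log(S)`, of the
#' proportional composition: 1 means all species equally abundant, 0
#' means one species completely dominates. Absolute abundances are
#' normalized internally; zero proportions contribute 0 (the limit
#' convention `0 * log(0) = 0`).
#'
#' @param x nonnegative abundances or proportions, not all zero.
#' @param S number of species; defaults to `length(x)`, must be >= 2.
#' @return evenness in \[0, 1\].
#' @export
pielou_evenness <- function(x, S = length(x)) {
  p <- composition(x)
  if (S < 2) stop("S must be >= 2", call. = FALSE)
  pos <- p > 0
  -sum(p[pos] * log(p[pos])) / log(S) + 0  # + 0 normalizes IEEE -0
}

#' Proportional composition of an abundance vector
#'
#' @param x nonnegative abundances, not all zero.
#' @return proportions summing to 1.
#' @export
composition <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("abundances must be finite and nonnegative", call. = FALSE)
  }
  tot <- sum(x)
  if (tot == 0) stop("all abundances are zero", call. = FALSE)
  x / tot
}

#' Log-fold knockdown ratios against the baseline condition
#'
#' For each species and time point, `logR_i(t) = log_b(x_i^kd(t) /
#' x_i^base(t))`: positive when the species grows more under the
#' knockdown of another member (net antagonism from the knocked member),
#' negative when it grows less (net positive effect). Replicates are
#' aggregated by the median abundance before the ratio is formed.
#'
#' @param knockdown,baseline tidy trajectory tables (or
#'   `glv_trajectory` objects) for the two conditions, sharing species
#'   and time grids.
#' @param log_base base of the logarithm (default 10).
#' @return data frame with columns `time_h`, `species`, `logR`.
#' @export
log_fold_ratio <- function(knockdown, baseline, log_base = 10) {
  kd <- logr_median_table(knockdown)
  bs <- logr_median_table(baseline)
  if (!identical(dim(kd), dim(bs)) ||
      !identical(rownames(kd), rownames(bs)) ||
      !identical(colnames(kd), colnames(bs))) {
    stop("knockdown and baseline must share species and time grids",
         call. = FALSE)
  }
  if (any(kd <= 0) || any(bs <= 0)) {
    stop("abundances must be strictly positive to form log ratios",
         call. = FALSE)
  }
  logr <- log(kd / bs) / log(log_base)
  data.frame(
    time_h = rep(as.numeric(rownames(logr)), times = ncol(logr)),
    species = rep(colnames(logr), each = nrow(logr)),
    logR = as.vector(logr),
    stringsAsFactors = FALSE
  )
}

# time x species matrix of median-over-replicate abundances
logr_median_table <- function(obj) {
  if (inherits(obj, "glv_trajectory")) {
    m <- obj$abundances
    rownames(m) <- as.character(obj$times)
    return(m)
  }
  df <- as.data.frame(obj)
  missing <- setdiff(c("time_h", "species", "abundance_cfu_per_ml"),
                     names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  agg <- stats::aggregate(abundance_cfu_per_ml ~ time_h + species,
                          data = df, FUN = stats::median)
  times <- sort(unique(agg$time_h))
  species <- unique(df$species)
  m <- matrix(NA_real_, length(times), length(species),
              dimnames = list(as.character(times), species))
  m[cbind(match(agg$time_h, times), match(agg$species, species))] <-
    agg$abundance_cfu_per_ml
  m
}

#' Fit a four-parameter logistic (4PL) dose-response curve and EC50
#'
#' Least-squares fit of `response = bottom + (top - bottom) / (1 +
#' (ec50 / conc)^hill_slope)` (variable-slope sigmoidal model), by
#' Levenberg-Marquardt. The EC50 is the concentration giving the
#' half-way response between bottom and top, reported in the input
#' concentration units; `bottom` is constrained nonnegative.
#'
#' @param concentrations positive metabolite concentrations (e.g. uM).
#' @param responses growth readout at each concentration.
#' @return list with `bottom`, `top`, `ec50`, `hill_slope`, residual sum
#'   of squares `rss`, and `fitted(conc)` the fitted curve function.
#' @export
fit_sigmoid_ec50 <- function(concentrations, responses) {
  conc <- as.numeric(concentrations)
  resp <- as.numeric(responses)
  if (length(conc) != length(resp)) stop("length mismatch", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(unique(conc)) < 4L) {
    stop("need >= 4 distinct concentrations", call. = FALSE)
  }
  if (diff(range(resp)) <= 1e-12 * max(abs(resp), 1)) {
    stop("flat response data: EC50 is unidentifiable", call. = FALSE)
  }
  lc <- log(conc)
  half <- (min(resp) + max(resp)) / 2
  start <- list(bottom = max(min(resp), 0), top = max(resp),
                lec50 = stats::approx(resp[order(resp)],
                                      lc[order(resp)], xout = half,
                                      ties = mean, rule = 2)$y,
                hill = 1)
  curve_resid <- function(par) {
    pred <- par["bottom"] + (par["top"] - par["bottom"]) /
      (1 + exp(par["hill"] * (par["lec50"] - lc)))
    resp - pred
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(start)[c("bottom", "top", "lec50", "hill")],
      fn = curve_resid,
      lower = c(bottom = 0, top = -Inf, lec50 = min(lc) - 20, hill = -50),
      upper = c(bottom = Inf, top = Inf, lec50 = max(lc) + 20, hill = 50),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) stop("EC50 fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (fit$info %in% c(0, 5, 9)) {
    stop("EC50 fit failed to converge: ", fit$message, call. = FALSE)
  }
  cf <- fit$par
  out <- list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
              ec50 = exp(unname(cf["lec50"])),
              hill_slope = unname(cf["hill"]),
              rss = sum(fit$fvec^2))
  out$fitted <- function(conc) {
    out$bottom + (out$top - out$bottom) /
      (1 + (out$ec50 / conc)^out$hill_slope)
  }
  out
}
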