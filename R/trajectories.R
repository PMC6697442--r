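#' Trajectory sets as tidy tables
#'
#' A trajectory set is the pipeline's measurement currency: one abundance
#' per (condition, replicate, time, species), in CFU/ml, stored as a tidy
#' data frame with columns `condition`, `replicate`, `time_h`, `species`,
#' `abundance_cfu_per_ml` and (optionally) a logical `censored` flag for
#' values clamped at the detection floor.
#'
#' @param trajectories a list of `glv_trajectory` objects.
#' @return a tidy data frame of class `glv_trajectory_set`.
#' @export
trajectory_set <- function(trajectories) {
  df <- do.call(rbind, lapply(trajectories, as.data.frame))
  rownames(df) <- NULL
  validate_trajectory_table(df)
}

required_traj_cols <- c("condition", "replicate", "time_h", "species",
                        "abundance_cfu_per_ml")

validate_trajectory_table <- function(df) {
  missing <- setdiff(required_traj_cols, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$abundance_cfu_per_ml)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$abundance_cfu_per_ml))))
    stop("non-numeric abundance at row ", bad[1], call. = FALSE)
  }
  bad <- which(!is.finite(df$abundance_cfu_per_ml) |
                 df$abundance_cfu_per_ml < 0)
  if (length(bad)) {
    stop("negative or non-finite abundance at row ", bad[1], call. = FALSE)
  }
  key <- paste(df$condition, df$replicate, df$time_h, df$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (condition, replicate, time, species) at row ", dup[1],
         call. = FALSE)
  }
  if (is.null(df$censored)) df$censored <- FALSE
  class(df) <- c("glv_trajectory_set", "data.frame")
  df
}

#' Write / read a trajectory set as TSV
#'
#' Plain UTF-8 tab-separated text; a write -> read round trip restores
#' values, ordering and labels exactly. Unknown extra columns are
#' preserved. Malformed files (missing column, negative or non-numeric
#' abundance, duplicated key) are rejected with the offending row.
#'
#' @param traj_set a `glv_trajectory_set` (or conforming data frame).
#' @param path file path for the TSV.
#' @return `read_trajectories` returns a `glv_trajectory_set`;
#'   `write_trajectories` returns `path` invisibly.
#' @export
write_trajectories <- function(traj_set, path) {
  df <- as.data.frame(traj_set)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = NA, check.names = FALSE)
  for (col in c("time_h", "abundance_cfu_per_ml")) {
    if (!is.null(df[[col]]) && !is.numeric(df[[col]])) {
      suppressWarnings(num <- as.numeric(df[[col]]))
      bad <- which(is.na(num) & !is.na(df[[col]]))
      if (length(bad)) {
        stop("non-numeric ", col, " at row ", bad[1], call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  if (!is.null(df$censored)) df$censored <- as.logical(df$censored)
  validate_trajectory_table(df)
}

#' Split a tidy trajectory set into per-(condition, replicate) matrices
#'
#' @param traj_set a `glv_trajectory_set`.
#' @param species optional species ordering; defaults to first appearance.
#' @return list of `glv_trajectory` objects.
#' @export
split_trajectories <- function(traj_set, species = NULL) {
  df <- validate_trajectory_table(as.data.frame(traj_set))
  if (is.null(species)) species <- unique(df$species)
  if (!all(df$species %in% species)) {
    stop("species in table not covered by the requested ordering",
         call. = FALSE)
  }
  if (is.null(df$censored)) df$censored <- FALSE
  pieces <- split(df, list(df$condition, df$replicate), drop = TRUE,
                  sep = "\r")
  out <- lapply(pieces, function(d) {
    times <- sort(unique(d$time_h))
    S <- length(species)
    x <- matrix(NA_real_, length(times), S, dimnames = list(NULL, species))
    cens <- matrix(FALSE, length(times), S)
    ti <- match(d$time_h, times)
    si <- match(d$species, species)
    x[cbind(ti, si)] <- d$abundance_cfu_per_ml
    cens[cbind(ti, si)] <- d$censored
    if (anyNA(x)) {
      stop(sprintf("incomplete species x time grid for condition %s replicate %s",
                   d$condition[1], d$replicate[1]), call. = FALSE)
    }
    new_trajectory(times, x, d$condition[1], d$replicate[1], cens)
  })
  # order by condition then replicate for stable downstream iteration
  ord <- order(vapply(out, function(t) t$condition_label, character(1)),
               vapply(out, function(t) as.character(t$replicate_id),
                      character(1)))
  unname(out[ord])
}
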