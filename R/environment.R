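# Habitat principal component and ecotype contrasts.

#' Habitat principal component from environmental survey points
#'
#' Summarizes the three binary habitat indicators (substrate bedrock = 1,
#' barnacles present = 1, fucoid seaweed present = 1) as the first principal
#' component of the centered, unit-scaled indicator matrix. The sign is fixed
#' so that wave-exposed conditions (bedrock, barnacles, no fucoids) score
#' high.
#'
#' @param points data frame with columns `path_pos_m`, `substrate`,
#'   `barnacles`, `fucus` (indicators coded 0/1).
#' @return Object of class `habitat_pc`: list with `scores` (per point),
#'   `loadings` (length 3), `sdev`, `var_explained` (share of PC1),
#'   `path_pos` and the scaling used.
#' @export
habitat_pc <- function(points) {
  vars <- c("substrate", "barnacles", "fucus")
  stopifnot(all(vars %in% names(points)))
  m <- as.matrix(points[, vars])
  if (nrow(m) < 3) stop("need at least 3 survey points")
  if (!all(m %in% c(0, 1))) stop("indicators must be coded 0/1")
  sds <- apply(m, 2, sd)
  if (all(sds == 0)) stop("all habitat indicators are constant")
  # unit-scale only the varying columns; constant columns carry no signal
  scl <- ifelse(sds > 0, sds, 1)
  z <- sweep(sweep(m, 2, colMeans(m)), 2, scl, "/")
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  # wave direction: +substrate, +barnacles, -fucus
  if (sum(load * c(1, 1, -1)) < 0) {
    load <- -load
    scores <- -scores
  }
  structure(list(scores = unname(scores), loadings = load,
                 sdev = pc$sdev,
                 var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
                 path_pos = points$path_pos_m,
                 center = colMeans(m), scale = scl),
            class = "habitat_pc")
}

#' @export
print.habitat_pc <- function(x, ...) {
  cat(sprintf("habitat_pc: %d points, PC1 explains %.1f%% of indicator variance\n",
              length(x$scores), 100 * x$var_explained))
  cat("loadings:", paste(sprintf("%s=%.3f", names(x$loadings), x$loadings),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Assign habitat PC scores to samples by nearest survey point
#'
#' Each sample receives the PC1 score of the survey point nearest along the
#' path; ties go to the lower position. Samples beyond the surveyed range get
#' the nearest endpoint's score with a warning.
#'
#' @param samples data frame with a `path_pos_m` column.
#' @param pc a [habitat_pc()] object.
#' @return numeric vector of per-sample habitat scores.
#' @export
assign_env <- function(samples, pc) {
  stopifnot("path_pos_m" %in% names(samples))
  ord <- order(pc$path_pos)
  pp <- pc$path_pos[ord]
  sc <- pc$scores[ord]
  out_of_range <- samples$path_pos_m < min(pp) | samples$path_pos_m > max(pp)
  if (any(out_of_range))
    warning(sum(out_of_range),
            " sample(s) outside the surveyed range; nearest endpoint used")
  vapply(samples$path_pos_m, function(x) {
    d <- abs(pp - x)
    sc[which.min(d)]  # ties: first = lower position (pp sorted ascending)
  }, numeric(1))
}

#' Relative ecotype difference with bootstrap confidence interval
#'
#' Computes (mean Crab - mean Wave) / mean Crab for one trait, using only
#' samples labelled `Crab` or `Wave` (transition-zone samples are excluded),
#' with a percentile bootstrap CI from resampling within each ecotype.
#'
#' @param trait numeric trait values.
#' @param habitat_label character vector of habitat labels per sample.
#' @param n_boot number of bootstrap iterations (default 10000).
#' @param seed optional RNG seed for reproducible intervals.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `ci` (length 2), `n_crab`, `n_wave`,
#'   `n_boot`.
#' @export
ecotype_relative_difference <- function(trait, habitat_label,
                                        n_boot = 10000, seed = NULL,
                                        conf = 0.95) {
  crab <- trait[habitat_label == "Crab" & !is.na(trait)]
  wave <- trait[habitat_label == "Wave" & !is.na(trait)]
  if (length(crab) < 2 || length(wave) < 2)
    stop("need at least 2 samples per ecotype")
  m_crab <- mean(crab)
  if (m_crab == 0) stop("Crab mean is zero; relative difference undefined")
  est <- (m_crab - mean(wave)) / m_crab
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    mc <- mean(sample(crab, replace = TRUE))
    mw <- mean(sample(wave, replace = TRUE))
    if (mc == 0) NA_real_ else (mc - mw) / mc
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  list(estimate = est, ci = ci, n_crab = length(crab),
       n_wave = length(wave), n_boot = n_boot)
}
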