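# Transect descriptors: hybrid index and the relatedness dip around the
# habitat transition.

#' Hybrid index from diagnostic loci
#'
#' Mean Wave-oriented allele dosage across a set of diagnostic loci, divided
#' by 2, giving a 0 (pure Crab) to 1 (pure Wave) score. Loci with missing
#' genotypes are skipped per sample; samples missing all loci get `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param loci SNP ids of the diagnostic loci.
#' @param wave_allele for each locus, `"alt"` if the alternate allele is the
#'   Wave-associated one, `"ref"` otherwise (recycled if length 1).
#' @return numeric vector in `[0, 1]` per sample.
#' @export
hybrid_index <- function(g, loci, wave_allele = "alt") {
  idx <- match(loci, g$snps$id)
  if (anyNA(idx)) stop("unknown diagnostic loci: ",
                       paste(loci[is.na(idx)], collapse = ", "))
  wave_allele <- rep_len(wave_allele, length(idx))
  d <- g$dosage[, idx, drop = FALSE]
  flip <- wave_allele == "ref"
  d[, flip] <- 2 - d[, flip]
  rowMeans(d, na.rm = TRUE) / 2
}

#' Relatedness contrast across the habitat transition
#'
#' Compares per-sample median relatedness (from
#' [median_relatedness_profile()]) between samples inside the transition
#' zone and samples in the flanking Crab/Wave habitats, and localizes the
#' minimum of a running-median smoothed profile along the path.
#'
#' @param path_pos per-sample path positions (metres).
#' @param relatedness per-sample median relatedness values (one window).
#' @param zone per-sample labels: `"transition"` versus anything else
#'   (flank); alternatively supply `boundaries = c(lo, hi)` in metres and
#'   leave `zone = NULL`.
#' @param boundaries optional numeric length-2 transition interval.
#' @param smooth_k running-median window (samples) for dip localization;
#'   default 11.
#' @return list with `mean_transition`, `mean_flank`, `difference`
#'   (flank - transition), `dip_position` (path position of the smoothed
#'   minimum; `NA` when the profile is flat), `flat`, `n_transition`,
#'   `n_flank`, `smooth_k`.
#' @export
transition_dip <- function(path_pos, relatedness, zone = NULL,
                           boundaries = NULL, smooth_k = 11) {
  stopifnot(length(path_pos) == length(relatedness))
  if (is.null(zone)) {
    if (is.null(boundaries) || length(boundaries) != 2)
      stop("supply either `zone` labels or `boundaries = c(lo, hi)`")
    zone <- ifelse(path_pos >= min(boundaries) &
                     path_pos <= max(boundaries), "transition", "flank")
  }
  ok <- !is.na(relatedness)
  in_tz <- zone == "transition" & ok
  in_fl <- zone != "transition" & ok
  if (sum(in_tz) < 5 || sum(in_fl) < 5)
    warning("fewer than 5 samples in a zone; contrast is noisy")
  m_tz <- mean(relatedness[in_tz])
  m_fl <- mean(relatedness[in_fl])
  ord <- order(path_pos)
  r <- relatedness[ord][ok[ord]]
  pp <- path_pos[ord][ok[ord]]
  k <- min(smooth_k, if (length(r) %% 2 == 0) length(r) - 1 else length(r))
  if (k %% 2 == 0) k <- k - 1
  sm <- if (k >= 3) runmed(r, k) else r
  flat <- diff(range(sm)) < 1e-12
  dip <- if (flat) NA_real_ else pp[which.min(sm)]
  list(mean_transition = m_tz, mean_flank = m_fl,
       difference = m_fl - m_tz, dip_position = dip, flat = flat,
       n_transition = sum(in_tz), n_flank = sum(in_fl), smooth_k = k)
}
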