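# Genomic relationship matrices (Yang et al. estimator) and spatial
# relatedness summaries.

#' Remove SNPs inside inversion regions (with a cM buffer)
#'
#' Drops SNPs lying on a region's linkage group with map position in
#' `[cm_start - buffer, cm_end + buffer]` (closed interval). The default 5 cM
#' buffer guards against residual linkage with the inversion.
#'
#' @param g a [genotype_matrix()] with map annotation.
#' @param regions an [inversion_regions()] table (may have zero rows).
#' @param buffer_cm buffer in centimorgans (default 5).
#' @param drop_unmapped also drop SNPs without a map position (they cannot be
#'   checked against the buffer); default `FALSE`.
#' @return The filtered `genotype_matrix`.
#' @export
select_background_snps <- function(g, regions, buffer_cm = 5,
                                   drop_unmapped = FALSE) {
  keep <- rep(TRUE, nrow(g$snps))
  if (!is.null(regions) && nrow(regions) > 0) {
    for (r in seq_len(nrow(regions))) {
      inside <- !is.na(g$snps$lg) & !is.na(g$snps$cm) &
        g$snps$lg == regions$lg[r] &
        g$snps$cm >= regions$cm_start[r] - buffer_cm &
        g$snps$cm <= regions$cm_end[r] + buffer_cm
      keep <- keep & !inside
    }
  }
  if (drop_unmapped)
    keep <- keep & !is.na(g$snps$lg) & !is.na(g$snps$cm)
  if (!any(keep))
    stop("no SNPs remain outside the inversion regions")
  g[, which(keep)]
}

#' Genomic relationship matrix (Yang et al. estimator)
#'
#' Off-diagonal entries are
#' \deqn{A_{ij} = \frac{1}{m}\sum_k \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}
#'   {2p_k(1-p_k)}}
#' and diagonal entries
#' \deqn{A_{ii} = 1 + \frac{1}{m}\sum_k \frac{x_{ik}^2-(1+2p_k)x_{ik}+2p_k^2}
#'   {2p_k(1-p_k)},}
#' with allele frequencies \eqn{p_k} estimated from the input samples and
#' missing dosages mean-imputed to \eqn{2p_k} per SNP. Monomorphic SNPs are
#' dropped with a warning.
#'
#' @param g a [genotype_matrix()] (apply [select_background_snps()] first for
#'   an inversion-free matrix).
#' @return Object of class `grm`: list with `matrix` (n x n, symmetric),
#'   `sample_ids`, `n_markers`, `allele_freq`.
#' @export
compute_grm <- function(g) {
  x <- g$dosage
  p <- colMeans(x, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) dropped from the GRM")
    x <- x[, poly, drop = FALSE]
    p <- p[poly]
  }
  m <- ncol(x)
  if (m == 0) stop("no polymorphic SNPs left for the GRM")
  for (j in seq_len(m)) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- 2 * p[j]
  }
  denom <- 2 * p * (1 - p)
  w <- sweep(x, 2, 2 * p)                 # x - 2p
  ws <- sweep(w, 2, sqrt(denom), "/")
  a <- tcrossprod(ws) / m
  # Yang-style diagonal replaces the plain cross-product diagonal
  dterm <- x^2 - sweep(x, 2, 1 + 2 * p, "*")
  dterm <- sweep(dterm, 2, 2 * p^2, "+")
  dterm <- sweep(dterm, 2, denom, "/")
  diag(a) <- 1 + rowMeans(dterm)
  a <- (a + t(a)) / 2
  dimnames(a) <- list(g$samples, g$samples)
  structure(list(matrix = a, sample_ids = g$samples, n_markers = m,
                 allele_freq = p),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  od <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("grm: %d samples, %d markers\n", length(x$sample_ids),
              x$n_markers))
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(x$matrix)), mean(od)))
  invisible(x)
}

#' Per-linkage-group genomic relationship matrices
#'
#' One GRM per linkage group, using all mapped SNPs on that group (optionally
#' excluding inversion regions). Because the estimator is a per-SNP average,
#' the marker-count-weighted sum of the per-LG matrices reconstructs the
#' all-SNP GRM exactly.
#'
#' @param g a [genotype_matrix()] with map annotation.
#' @param lgs linkage groups to use (default: all observed).
#' @param exclude_regions optional [inversion_regions()] removed (with
#'   `buffer_cm`) before splitting.
#' @param buffer_cm buffer used with `exclude_regions`.
#' @return named list of [compute_grm()] objects; LGs without SNPs are
#'   omitted with a warning.
#' @export
per_lg_grms <- function(g, lgs = NULL, exclude_regions = NULL,
                        buffer_cm = 5) {
  if (!is.null(exclude_regions))
    g <- select_background_snps(g, exclude_regions, buffer_cm)
  if (is.null(lgs)) lgs <- sort(unique(g$snps$lg[!is.na(g$snps$lg)]))
  out <- list()
  for (l in lgs) {
    sel <- which(!is.na(g$snps$lg) & g$snps$lg == l)
    if (length(sel) == 0) {
      warning("linkage group ", l, " has no SNPs; omitted")
      next
    }
    out[[paste0("LG", l)]] <- compute_grm(g[, sel])
  }
  out
}

#' Median relatedness of each sample to its spatial neighbours
#'
#' For each focal sample, the median of its off-diagonal GRM entries to all
#' samples within `window_m` metres along the path. Samples with no
#' neighbour inside the window get `NA`.
#'
#' @param a a [compute_grm()] object (or bare symmetric matrix).
#' @param positions numeric path positions (metres), aligned with the GRM
#'   sample order.
#' @param window_m window half-widths in metres; default the standard set
#'   c(1, 2, 3, 5, 10).
#' @return data frame: `path_pos` plus one `median_rel_<w>m` column per
#'   window.
#' @export
median_relatedness_profile <- function(a, positions,
                                       window_m = c(1, 2, 3, 5, 10)) {
  m <- if (inherits(a, "grm")) a$matrix else as.matrix(a)
  n <- nrow(m)
  if (length(positions) != n)
    stop("positions must align with the GRM samples")
  out <- data.frame(path_pos = positions)
  for (w in window_m) {
    med <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      nb <- which(abs(positions - positions[i]) <= w)
      nb <- nb[nb != i]
      if (length(nb)) med[i] <- median(m[i, nb])
    }
    out[[sprintf("median_rel_%gm", w)]] <- med
  }
  out
}
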