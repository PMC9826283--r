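# Inversion karyotype calling: PCA of region SNPs + 3-means clustering.

#' Principal-component scores for SNPs inside an inversion region
#'
#' Restricts the genotype matrix to SNPs mapped inside the region (linkage
#' group match, cM interval endpoints inclusive), mean-imputes missing
#' dosages, centers columns (no scaling) and returns scores on the leading
#' principal components.
#'
#' @param g a [genotype_matrix()] with `lg`/`cm` annotated.
#' @param region one row of an [inversion_regions()] table (or a list with
#'   `name`, `lg`, `cm_start`, `cm_end`).
#' @param n_pcs number of components to return (default 2).
#' @return list with `scores` (n x n_pcs matrix), `snp_ids`, `region`,
#'   `var_explained`.
#' @export
region_pca <- function(g, region, n_pcs = 2) {
  sel <- !is.na(g$snps$lg) & !is.na(g$snps$cm) &
    g$snps$lg == region$lg &
    g$snps$cm >= region$cm_start & g$snps$cm <= region$cm_end
  if (sum(sel) < 5)
    stop("region ", region$name, ": fewer than 5 SNPs inside the interval")
  x <- g$dosage[, sel, drop = FALSE]
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mu[j]
  }
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = min(n_pcs, min(dim(xc))), nv = 0)
  k <- min(n_pcs, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- g$samples
  tot <- sum(sv$d^2)
  list(scores = scores, snp_ids = g$snps$id[sel], region = region,
       var_explained = if (tot > 0) sv$d[seq_len(k)]^2 / tot else
         rep(0, k))
}

# EM for the two-arrangement admixture model: karyotype class k in {0,1,2}
# counts copies of arrangement 1; dosage at SNP j is Binom(k, q1j) +
# Binom(2-k, q0j). Hard initial labels come from the k-means clusters;
# responsibilities, arrangement allele frequencies and class priors are then
# iterated to convergence and samples assigned by maximum posterior.
refine_karyotypes_em <- function(x, lab0, max_iter = 100, tol = 1e-8) {
  n <- nrow(x)
  x_na <- is.na(x)
  if (any(x_na)) {
    mu <- colMeans(x, na.rm = TRUE)
    for (j in seq_len(ncol(x)))
      x[x_na[, j], j] <- round(mu[j])
  }
  w <- matrix(0, n, 3)
  w[cbind(seq_len(n), lab0 + 1L)] <- 1
  clamp <- function(q) pmin(pmax(q, 1e-3), 1 - 1e-3)
  lc <- rowSums(x == 1) * log(2)   # binomial coefficient for dosage 1
  q0 <- clamp(colSums(w[, 1] * x) / pmax(2 * sum(w[, 1]), 1e-9))
  q1 <- clamp(colSums(w[, 3] * x) / pmax(2 * sum(w[, 3]), 1e-9))
  for (it in seq_len(max_iter)) {
    pa1 <- q1 * (1 - q0) / (q1 * (1 - q0) + q0 * (1 - q1))
    ea <- sweep(x == 1, 2, pa1, "*") + (x == 2)  # E[alt copies on arr 1 | het]
    w1 <- w[, 2]
    q1 <- clamp((colSums(w[, 3] * x) + colSums(w1 * ea)) /
                  (2 * sum(w[, 3]) + sum(w1)))
    q0 <- clamp((colSums(w[, 1] * x) + colSums(w1 * (x - ea))) /
                  (2 * sum(w[, 1]) + sum(w1)))
    pri <- (colSums(w) + 0.5) / (n + 1.5)
    l0 <- drop(x %*% log(q0) + (2 - x) %*% log(1 - q0)) + lc
    l2 <- drop(x %*% log(q1) + (2 - x) %*% log(1 - q1)) + lc
    l1 <- drop((x == 0) %*% log((1 - q0) * (1 - q1)) +
                 (x == 1) %*% log(q1 * (1 - q0) + q0 * (1 - q1)) +
                 (x == 2) %*% log(q0 * q1))
    ll <- cbind(l0 + log(pri[1]), l1 + log(pri[2]), l2 + log(pri[3]))
    wnew <- exp(ll - apply(ll, 1, max))
    wnew <- wnew / rowSums(wnew)
    done <- max(abs(wnew - w)) < tol
    w <- wnew
    if (done) break
  }
  max.col(w) - 1L
}

#' Call inversion karyotypes from PC1 scores
#'
#' Clusters PC1 scores into three groups by k-means (multiple restarts under
#' a fixed seed) and labels them 0/1/2 by center order, the middle cluster
#' being the arrangement heterozygote. When the region genotypes are
#' supplied and `refine = TRUE` (the default), the k-means labels seed an EM
#' fit of the two-arrangement binomial mixture (arrangement-specific allele
#' frequencies per SNP, free class priors) and samples are re-assigned by
#' maximum posterior probability; this uses the full multilocus genotype
#' information rather than its one-dimensional projection. Orientation: if
#' reference samples are supplied (typically those from the Wave end), the
#' dosage counts the arrangement commoner in the reference, i.e. labels are
#' flipped 0<->2 when the reference mean dosage falls below 1. A diagnostic
#' checks that the heterozygote cluster has the highest mean observed
#' heterozygosity across the region SNPs and warns otherwise.
#'
#' @param scores output of [region_pca()], or a numeric vector of PC1 scores.
#' @param region_geno optional dosage matrix of the region SNPs (samples x
#'   SNPs) for the EM refinement and the heterozygosity diagnostic; taken
#'   from `g` when calling via [call_inversions()].
#' @param seed RNG seed for the k-means restarts.
#' @param reference logical or integer index of reference (Wave-end) samples
#'   used to orient the dosage; `NULL` keeps the center order.
#' @param refine refine the k-means labels with the multilocus EM step
#'   (requires `region_geno`).
#' @return list of class `karyotype_call`: `dosage` (0/1/2 per sample),
#'   `centers` (sorted k-means cluster centers on PC1), `sizes` (final class
#'   sizes), `separation` (smallest gap between adjacent centers divided by
#'   pooled within-cluster SD), `het_by_class` (mean observed heterozygosity
#'   per dosage class), `flipped`, `het_ok`, `refined`.
#' @export
call_karyotypes <- function(scores, region_geno = NULL, seed = 1,
                            reference = NULL, refine = TRUE) {
  pc1 <- if (is.list(scores)) scores$scores[, 1] else as.numeric(scores)
  if (length(unique(pc1)) < 3)
    stop("fewer than 3 distinct PC1 scores; cannot form 3 clusters")
  set.seed(seed)
  km <- kmeans(pc1, centers = 3, nstart = 25)
  ord <- order(km$centers[, 1])
  lab <- match(km$cluster, ord) - 1L  # 0/1/2 along PC1
  refined <- FALSE
  if (refine && !is.null(region_geno) && min(km$size) > 0) {
    lab <- refine_karyotypes_em(as.matrix(region_geno), lab)
    refined <- TRUE
  }
  centers <- sort(km$centers[, 1])
  sizes <- tabulate(lab + 1L, 3)
  wss <- km$withinss[ord]
  pooled_sd <- sqrt(sum(wss) / max(1, length(pc1) - 3))
  separation <- if (pooled_sd > 0)
    min(diff(centers)) / pooled_sd else Inf
  flipped <- FALSE
  if (!is.null(reference)) {
    ref_mean <- mean(lab[reference])
    if (is.finite(ref_mean) && ref_mean < 1) {
      lab <- 2L - lab
      flipped <- TRUE
    }
  }
  het_by_class <- rep(NA_real_, 3)
  het_ok <- NA
  if (!is.null(region_geno)) {
    het <- rowMeans(region_geno == 1, na.rm = TRUE)
    for (k in 0:2) het_by_class[k + 1] <- mean(het[lab == k], na.rm = TRUE)
    het_ok <- !anyNA(het_by_class) &&
      which.max(het_by_class) == 2L
    if (isFALSE(het_ok))
      warning("heterozygote cluster does not show maximal heterozygosity; ",
              "check cluster structure for this region")
  }
  names(het_by_class) <- c("hom0", "het", "hom2")
  structure(list(dosage = lab, centers = centers, sizes = sizes,
                 separation = separation, het_by_class = het_by_class,
                 flipped = flipped, het_ok = het_ok, refined = refined),
            class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  cat(sprintf("karyotype_call: n = %d (%s), separation = %.2f\n",
              length(x$dosage),
              paste(x$sizes, collapse = "/"), x$separation))
  cat(sprintf("  centers: %s; het by class: %s%s\n",
              paste(sprintf("%.2f", x$centers), collapse = ", "),
              paste(sprintf("%.3f", x$het_by_class), collapse = "/"),
              if (isFALSE(x$het_ok)) " [het check FAILED]" else ""))
  invisible(x)
}

#' Call karyotypes for every inversion region
#'
#' Convenience wrapper: [region_pca()] + [call_karyotypes()] per region.
#'
#' @param g a [genotype_matrix()] with map annotation.
#' @param regions an [inversion_regions()] table.
#' @param seed RNG seed passed to each k-means call.
#' @param reference optional index of Wave-end reference samples for dosage
#'   orientation.
#' @return list with `karyotypes` (samples x regions integer matrix) and
#'   `qc` (per-region data frame: centers, sizes, separation, het_ok).
#' @export
call_inversions <- function(g, regions, seed = 1, reference = NULL) {
  k <- matrix(NA_integer_, length(g$samples), nrow(regions),
              dimnames = list(g$samples, regions$name))
  qc <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    pca <- region_pca(g, regions[r, ])
    geno <- g$dosage[, pca$snp_ids, drop = FALSE]
    call <- call_karyotypes(pca, region_geno = geno, seed = seed,
                            reference = reference)
    k[, r] <- call$dosage
    qc[[r]] <- data.frame(name = regions$name[r],
                          n_snps = length(pca$snp_ids),
                          c0 = call$centers[1], c1 = call$centers[2],
                          c2 = call$centers[3],
                          n0 = call$sizes[1], n1 = call$sizes[2],
                          n2 = call$sizes[3],
                          separation = call$separation,
                          het_ok = call$het_ok,
                          stringsAsFactors = FALSE)
  }
  list(karyotypes = k, qc = do.call(rbind, qc))
}

#' Collapse a complex inversion region to one focal arrangement
#'
#' Complex regions segregate three arrangements; only copies of the declared
#' focal arrangement are counted, so carriers of the rare third arrangement
#' contribute the focal copy count only.
#'
#' @param arrangements character matrix (samples x 2) of per-chromosome
#'   arrangement labels.
#' @param focal the focal arrangement label.
#' @return integer vector of focal-arrangement copy counts (0/1/2).
#' @export
collapse_complex <- function(arrangements, focal) {
  arrangements <- as.matrix(arrangements)
  if (ncol(arrangements) != 2)
    stop("`arrangements` must have two columns (one per chromosome copy)")
  as.integer(rowSums(arrangements == focal))
}
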