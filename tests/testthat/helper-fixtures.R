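# Shared fixture builders and independent oracles.

# genotype_matrix from a bare dosage matrix, with passing-quality metadata
make_geno <- function(dosage, lg = NA_integer_, cm = NA_real_,
                      qual = 50) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  genotype_matrix(
    dosage,
    samples = sprintf("s%03d", seq_len(nrow(dosage))),
    snps = data.frame(id = sprintf("snp%04d", seq_len(m)),
                      qual = rep_len(qual, m),
                      ref = "A", alt = "T", biallelic = TRUE,
                      lg = rep_len(lg, m), cm = rep_len(cm, m),
                      stringsAsFactors = FALSE))
}

# block-diagonal family relationship matrix: full sibs (0.5) within families
family_grm <- function(n_families, sibs_per_family, r = 0.5) {
  fam <- rep(seq_len(n_families), each = sibs_per_family)
  a <- outer(fam, fam, function(i, j) ifelse(i == j, r, 0))
  diag(a) <- 1
  a
}

# draw y = X beta + u + e with V(u) = s2a * A, V(e) = s2e * I
draw_mvn_response <- function(X, beta, A, s2a, s2e) {
  n <- nrow(A)
  V <- s2a * A + s2e * diag(n)
  drop(X %*% beta) + drop(crossprod(chol(V), rnorm(n)))
}

# Independent REML log-likelihood oracle: direct dense evaluation of
# -0.5 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ] using determinant()
# and solve(), sharing no code with the package's solvers.
reml_loglik_oracle <- function(s2a, s2e, y, X, A) {
  n <- length(y)
  p <- ncol(X)
  V <- s2a * A + s2e * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  B <- solve(XtViX)
  P <- Vi - Vi %*% X %*% B %*% t(X) %*% Vi
  ld_V <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ld_X <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  -0.5 * ((n - p) * log(2 * pi) + ld_V + ld_X +
            drop(t(y) %*% P %*% y))
}

# Naive double-loop evaluation of the Yang relationship formulas
# (the brute-force GRM oracle; no vectorized shortcuts).
grm_oracle <- function(dosage) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  p <- colMeans(dosage, na.rm = TRUE) / 2
  for (k in seq_len(m)) dosage[is.na(dosage[, k]), k] <- 2 * p[k]
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        s <- 0
        for (k in seq_len(m))
          s <- s + (dosage[i, k]^2 - (1 + 2 * p[k]) * dosage[i, k] +
                      2 * p[k]^2) / (2 * p[k] * (1 - p[k]))
        a[i, j] <- 1 + s / m
      } else {
        s <- 0
        for (k in seq_len(m))
          s <- s + (dosage[i, k] - 2 * p[k]) * (dosage[j, k] - 2 * p[k]) /
            (2 * p[k] * (1 - p[k]))
        a[i, j] <- s / m
      }
    }
  }
  a
}

# single-inversion simulation used by the karyotype tests
sim_one_region <- function(seed, n = 300, n_snps = 100L, divergence = 0.3,
                           p_wave = 0.5, p_crab = 0.5) {
  cfg <- sim_config(
    n = n, n_neutral_snps = 50, n_generations = 0, seed = seed,
    inversions = data.frame(name = "invA", lg = 3L, cm_start = 5,
                            cm_end = 30, center_m = 150, width_m = 20,
                            p_wave = p_wave, p_crab = p_crab,
                            divergence = divergence, n_snps = n_snps,
                            share = 0.05, stringsAsFactors = FALSE))
  simulate_contact_zone(cfg)
}

# karyotype call accuracy against simulation truth (orientation-free)
karyotype_accuracy <- function(sim, seed = 1, refine = TRUE) {
  pca <- region_pca(sim$genotypes, sim$regions[1, ])
  geno <- sim$genotypes$dosage[, pca$snp_ids, drop = FALSE]
  call <- call_karyotypes(pca, region_geno = geno, seed = seed,
                          refine = refine)
  truth <- sim$truth$karyotypes[, 1]
  max(mean(call$dosage == truth), mean(2L - call$dosage == truth))
}
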