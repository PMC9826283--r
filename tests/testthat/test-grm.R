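# Genomic relationship matrices and spatial relatedness summaries.

test_that("two-sample hand example matches the relationship formulas", {
  g <- make_geno(matrix(c(0, 2), 2, 1))
  a <- compute_grm(g)
  expect_equal(a$matrix, matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
  expect_equal(a$n_markers, 1L)
})

test_that("vectorized GRM equals the naive double-loop oracle", {
  set.seed(8)
  dos <- matrix(rbinom(50 * 200, 2, runif(200, 0.1, 0.9)[rep(1:200, each = 50)]),
                50, 200)
  dos[sample(length(dos), 100)] <- NA  # missing dosages mean-imputed
  g <- make_geno(dos)
  a <- compute_grm(g)
  expect_lt(max(abs(a$matrix - grm_oracle(dos))), 1e-10)
  expect_lt(max(abs(a$matrix - t(a$matrix))), 1e-12)
})

test_that("GRM of simulated unrelated individuals centers correctly", {
  cfg <- sim_config(n = 500, n_neutral_snps = 5000, n_generations = 0,
                    seed = 5)
  sim <- simulate_contact_zone(cfg)
  bg <- sim$genotypes[, which(startsWith(sim$genotypes$snps$id, "bg"))]
  a <- compute_grm(bg)
  od <- a$matrix[upper.tri(a$matrix)]
  expect_lt(abs(mean(od)), 0.01)
  expect_lt(abs(mean(diag(a$matrix)) - 1), 0.02)
})

test_that("full sibs show relationship near 0.5 and SNP-order invariance", {
  # 60 founder couples each producing 2 offspring by meiosis over a
  # 10-linkage-group map
  set.seed(10)
  m <- 5000
  lg <- sort(rep_len(1:10, m))
  cm <- unlist(lapply(split(seq_len(m), lg), function(i) sort(runif(length(i), 0, 50))),
               use.names = FALSE)
  lg_idx <- split(seq_len(m), lg)
  lg_cm <- split(cm, lg)
  f <- runif(m, 0.2, 0.8)
  n_f <- 120
  H1 <- matrix(rbinom(n_f * m, 1, rep(f, each = n_f)), n_f, m)
  H2 <- matrix(rbinom(n_f * m, 1, rep(f, each = n_f)), n_f, m)
  kids <- matrix(0, 120, m)
  for (i in seq_len(120)) {
    pair <- ((i - 1) %/% 2) * 2 + 1  # couple index: parents pair, pair+1
    kids[i, ] <- invclinal:::make_gamete(H1[pair, ], H2[pair, ],
                                         lg_idx, lg_cm, 50) +
      invclinal:::make_gamete(H1[pair + 1, ], H2[pair + 1, ],
                              lg_idx, lg_cm, 50)
  }
  gk <- make_geno(kids)
  a <- compute_grm(gk)
  sib_pairs <- cbind(seq(1, 119, by = 2), seq(2, 120, by = 2))
  sib_rel <- a$matrix[sib_pairs]
  expect_lt(abs(mean(sib_rel) - 0.5), 0.05)

  # SNP permutation leaves the GRM unchanged
  perm <- sample(m)
  a2 <- compute_grm(gk[, perm])
  expect_lt(max(abs(a2$matrix - a$matrix)), 1e-12)
})

test_that("background selection removes buffered inversion intervals", {
  g <- make_geno(matrix(rbinom(20 * 4, 2, 0.5), 20, 4),
                 lg = c(6L, 6L, 7L, 6L), cm = c(7, 26, 15, 15))
  regions <- inversion_regions("r1", 6L, 10, 20)
  out <- select_background_snps(g, regions, buffer_cm = 5)
  expect_equal(out$snps$cm, c(26, 15))   # LG6@7 removed, LG6@26 + LG7 kept
  expect_equal(out$snps$lg, c(6L, 7L))

  out0 <- select_background_snps(g, regions, buffer_cm = 0)
  expect_equal(nrow(out0$snps), 3)       # only the in-region SNP removed

  # empty region list -> identity; idempotence
  expect_identical(select_background_snps(g, regions[0, ])$dosage, g$dosage)
  expect_identical(select_background_snps(out, regions, buffer_cm = 5)$dosage,
                   out$dosage)
  all_regions <- inversion_regions(c("a", "b"), c(6L, 7L), c(0, 0),
                                   c(100, 100))
  expect_error(select_background_snps(g, all_regions, buffer_cm = 5),
               "no SNPs remain")
})

test_that("per-LG GRMs partition markers and reconstruct the all-SNP GRM", {
  cfg <- sim_config(n = 60, n_neutral_snps = 300, n_generations = 0,
                    n_lgs = 6, seed = 12)
  sim <- simulate_contact_zone(cfg)
  g <- sim$genotypes[, which(startsWith(sim$genotypes$snps$id, "bg"))]
  a_all <- compute_grm(g)
  by_lg <- per_lg_grms(g)
  expect_equal(length(by_lg), 6)
  counts <- sapply(by_lg, `[[`, "n_markers")
  expect_equal(sum(counts), a_all$n_markers)
  w <- Reduce(`+`, lapply(by_lg, function(a) a$matrix * a$n_markers)) /
    a_all$n_markers
  expect_lt(max(abs(w - a_all$matrix)), 1e-10)

  # single-LG genome: per-LG GRM equals the all-SNP GRM
  g1 <- g[, which(g$snps$lg == 1)]
  expect_equal(per_lg_grms(g1)[["LG1"]]$matrix, compute_grm(g1)$matrix)
  expect_warning(per_lg_grms(g, lgs = c(1, 99)), "no SNPs")
})

test_that("median relatedness profile: neighbours, isolation and families", {
  a <- matrix(c(1, 0.5, 0.1,
                0.5, 1, 0.3,
                0.1, 0.3, 1), 3, 3)
  prof <- median_relatedness_profile(a, c(0, 1, 2), window_m = 1.5)
  expect_equal(prof$median_rel_1.5m[1], 0.5)     # one neighbour
  expect_equal(prof$median_rel_1.5m[2], 0.4)     # median of 0.5, 0.3
  prof2 <- median_relatedness_profile(a, c(0, 1, 50), window_m = 1.5)
  expect_true(is.na(prof2$median_rel_1.5m[3]))   # isolated sample

  # co-located families raise local medians above the transect-wide mean
  set.seed(13)
  fam <- rep(1:20, each = 5)
  a_f <- family_grm(20, 5) + matrix(rnorm(100^2, 0, 0.01), 100, 100)
  a_f <- (a_f + t(a_f)) / 2
  pos <- fam * 10 + runif(100, 0, 1)   # families tightly co-located
  prof3 <- median_relatedness_profile(a_f, pos, window_m = 2)
  overall_mean <- mean(a_f[upper.tri(a_f)])
  expect_gt(mean(prof3$median_rel_2m, na.rm = TRUE), overall_mean)
})
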