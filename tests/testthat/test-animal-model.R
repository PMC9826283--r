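# Design construction, collinearity diagnostics and REML estimation.

make_samples <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("s%03d", 1:n), site = "T",
             path_pos_m = runif(n, 0, 100), shore_height_m = rnorm(n, 1.5, 0.5),
             sex = sample(c("F", "M"), n, replace = TRUE),
             habitat_label = "Crab", dist_center_m = runif(n, 0, 50),
             trait = rnorm(n), stringsAsFactors = FALSE)
}

test_that("build_design assembles intercept, mains, inversions, interactions", {
  n <- 60
  smp <- make_samples(n)
  kar <- matrix(rbinom(n * 16, 2, 0.5), n,
                dimnames = list(NULL, paste0("inv", 1:16)))
  des <- build_design(smp, "trait", karyotypes = kar,
                      env_scores = rnorm(n))
  expect_equal(ncol(des$X), 21)  # intercept + 4 mains + 16 inversions
  expect_equal(des$assign[1], "(Intercept)")
  # response and covariates are z-scored
  expect_equal(mean(des$y), 0, tolerance = 1e-12)
  expect_equal(sd(des$y), 1, tolerance = 1e-12)
  expect_equal(unname(colMeans(des$X)[-1]), rep(0, 20), tolerance = 1e-12)

  # interaction column is the product of the standardized mains
  des2 <- build_design(smp, "trait", env_scores = rnorm(n),
                       interactions = list(c("habitat", "shore_height_m")))
  i_col <- des2$X[, "habitat:shore_height_m"]
  expect_equal(i_col, des2$X[, "habitat"] * des2$X[, "shore_height_m"])

  smp$bad <- NA_real_
  expect_error(build_design(smp, "trait", covariates = c("sex", "bad")),
               "bad")
  smp$flat <- 1
  expect_error(build_design(smp, "trait", covariates = "flat"), "flat")

  # missing responses are dropped, missing covariates zero-filled
  smp2 <- make_samples(n)
  smp2$trait[1:5] <- NA
  smp2$shore_height_m[6] <- NA
  des3 <- build_design(smp2, "trait")
  expect_equal(length(des3$y), n - 5)
  expect_equal(unname(des3$X[1, "shore_height_m"]), 0)  # sample 6 is now row 1
})

test_that("VIF matches the closed form and flags exact collinearity", {
  set.seed(3)
  n <- 200
  z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
  # two columns with exact sample correlation 0.9, third orthogonalized
  e <- residuals(lm(z2 ~ z1))
  x2 <- 0.9 * scale(z1)[, 1] + sqrt(1 - 0.81) * scale(e)[, 1]
  x3 <- residuals(lm(z3 ~ z1 + x2))
  X <- cbind(a = scale(z1)[, 1], b = x2, c = scale(x3)[, 1])
  v <- vif(X)
  expect_equal(unname(v[c("a", "b")]), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-8)
  expect_equal(unname(v["c"]), 1, tolerance = 1e-8)

  # columns orthogonal to each other and to the intercept -> all VIF 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n))))[, 2:5]
  expect_equal(unname(vif(q)), rep(1, 4), tolerance = 1e-8)

  # duplicated column -> infinite
  expect_true(all(is.infinite(vif(cbind(x = z1, y = z1)))))
})

test_that("eigen REML matches the independent dense likelihood", {
  set.seed(21)
  n <- 60
  A <- family_grm(20, 3)
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- draw_mvn_response(X, c(0.3, 0.2, -0.1), A, 0.5, 0.5)
  fit <- animal_model(y, X, grm = A)
  s2 <- fit$sigma2
  ll_direct <- reml_loglik_oracle(s2[1], s2[2], y, X, A)
  expect_equal(fit$logLik, ll_direct, tolerance = 1e-8)
  # the optimum dominates nearby parameter values
  for (f in c(0.8, 1.25)) {
    expect_gte(fit$logLik + 1e-8,
               reml_loglik_oracle(s2[1] * f, s2[2], y, X, A))
    expect_gte(fit$logLik + 1e-8,
               reml_loglik_oracle(s2[1], s2[2] * f, y, X, A))
  }
})

test_that("beta at sigma2_A = 0 equals OLS and fits are order-invariant", {
  set.seed(22)
  n <- 80
  A <- family_grm(20, 4)
  X <- cbind(1, rnorm(n))
  # response with no genetic structure: fit should hit the boundary often;
  # force the boundary case by passing grm = NULL
  y <- rnorm(n)
  fit0 <- animal_model(y, X, grm = NULL)
  expect_equal(unname(fit0$beta), unname(coef(lm(y ~ X[, 2]))),
               tolerance = 1e-10)

  y2 <- draw_mvn_response(X, c(0, 0.5), A, 0.4, 0.6)
  fit <- animal_model(y2, X, grm = A)
  perm <- sample(n)
  fit_p <- animal_model(y2[perm], X[perm, ], grm = A[perm, perm])
  expect_equal(fit_p$sigma2, fit$sigma2, tolerance = 1e-6)
  expect_equal(fit_p$beta, fit$beta, tolerance = 1e-6)
  expect_equal(fit_p$logLik, fit$logLik, tolerance = 1e-6)

  expect_warning(animal_model(y2, X, grm = diag(n)), "identifiable")
})

test_that("zero-heritability truth lands on the boundary about half the time", {
  set.seed(23)
  n <- 120
  A <- family_grm(30, 4)
  X <- cbind(1, rnorm(n))
  hits <- sapply(1:60, function(i) {
    y <- rnorm(n)  # sigma2_A = 0 truth
    animal_model(y, X, grm = A)$boundary
  })
  expect_gte(mean(hits), 0.35)  # boundary theory: about one half
})

test_that("heritability is recovered from family-structured data", {
  set.seed(24)
  n <- 500
  A <- family_grm(100, 5)
  X <- cbind(1, rnorm(n))
  h2 <- sapply(1:20, function(i) {
    y <- draw_mvn_response(X, c(0, 0.3), A, 0.5, 0.5)
    animal_model(y, X, grm = A)$h2
  })
  expect_lt(abs(mean(h2) - 0.5), 0.05)
})

test_that("AI-REML agrees with the eigen solver and recovers two components", {
  set.seed(25)
  n <- 150
  A <- family_grm(50, 3)
  X <- cbind(1, rnorm(n))
  y <- draw_mvn_response(X, c(0.1, 0.2), A, 0.5, 0.5)
  f_eigen <- animal_model(y, X, grm = A)
  f_ai <- invclinal:::reml_ai(y, X, list(A = A))
  expect_equal(unname(f_ai$sigma2), unname(f_eigen$sigma2),
               tolerance = 1e-6)
  expect_equal(f_ai$logLik, f_eigen$logLik, tolerance = 1e-6)

  # two-component recovery (block families on disjoint structures)
  n2 <- 250
  A1 <- family_grm(50, 5)
  fam2 <- sample(rep(1:25, each = 10))
  A2 <- outer(fam2, fam2, function(i, j) ifelse(i == j, 0.5, 0))
  diag(A2) <- 1
  X2 <- cbind(1, rnorm(n2))
  est <- sapply(1:8, function(i) {
    V <- 0.3 * A1 + 0.2 * A2 + 0.5 * diag(n2)
    y2 <- drop(crossprod(chol(V), rnorm(n2)))
    animal_model(y2, X2, grm = list(g1 = A1, g2 = A2))$sigma2
  })
  expect_lt(max(abs(rowMeans(est) - c(0.3, 0.2, 0.5))), 0.1)
})

test_that("conditional Wald: single-df identity and recode invariance", {
  set.seed(26)
  n <- 120
  A <- family_grm(30, 4)
  inv_dosage <- rbinom(n, 2, 0.4)
  smp <- make_samples(n, seed = 26)
  kar <- cbind(invX = inv_dosage)
  des <- build_design(smp, "trait", karyotypes = kar)
  fit <- animal_model(des, grm = A)
  w <- wald_tests(fit)
  # 1-df F equals the squared t of the coefficient
  t2 <- (fit$beta["invX"] / sqrt(fit$vcov_beta["invX", "invX"]))^2
  expect_equal(w$F[w$term == "invX"], unname(t2), tolerance = 1e-10)

  # recoding the inversion 0 <-> 2 flips the sign but not the p-value
  kar2 <- cbind(invX = 2 - inv_dosage)
  des2 <- build_design(smp, "trait", karyotypes = kar2)
  fit2 <- animal_model(des2, grm = A)
  w2 <- wald_tests(fit2)
  expect_equal(w2$p[w2$term == "invX"], w$p[w$term == "invX"],
               tolerance = 1e-8)
  expect_equal(unname(fit2$beta["invX"]), -unname(fit$beta["invX"]),
               tolerance = 1e-8)
})

test_that("LRT for V_A: identical models give statistic 0 and p 1", {
  set.seed(27)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  f0 <- animal_model(y, X, grm = NULL)
  out <- lrt_va(f0, f0)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  A <- family_grm(20, 4)
  y2 <- draw_mvn_response(X, c(0, 0), A, 0.6, 0.4)
  full <- animal_model(y2, X, grm = A)
  red <- animal_model(y2, X, grm = NULL)
  out2 <- lrt_va(full, red)
  expect_gte(out2$statistic, 0)
  expect_lte(out2$p, 1)
  # mixture reference halves the p-value away from the boundary
  out3 <- lrt_va(full, red, mixture = TRUE)
  if (out2$statistic > 0) expect_equal(out3$p, out2$p / 2)
})

test_that("BH adjustment matches the hand example and is monotone", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.03), 0.03)
  set.seed(28)
  p <- runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_equal(adj, p.adjust(p, method = "BH"))
  # grouped adjustment operates within groups
  grp <- rep(c("a", "b"), each = 25)
  adj_g <- fdr_adjust(p, grp)
  expect_equal(adj_g[grp == "a"], p.adjust(p[grp == "a"], "BH"))
})

test_that("model methods: fitted, residuals, predict, simulate, blup", {
  set.seed(29)
  n <- 90
  A <- family_grm(30, 3)
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- draw_mvn_response(X, c(0.2, 0.4), A, 0.5, 0.5)
  fit <- animal_model(y, X, grm = A)
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(length(predict(fit, type = "conditional")), n)
  s1 <- simulate(fit, nsim = 3, seed = 1)
  s2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(n, 3L))
  # BLUPs shrink toward zero relative to phenotypic deviations
  expect_lt(var(blup(fit)), var(residuals(fit)) + var(blup(fit)))
  expect_output(print(summary(fit)), "Wald")
})
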