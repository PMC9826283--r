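# Variance partitioning of fixed effects, V_A and residual.

test_that("fixed-effect variance: zero beta, closed form, variance algebra", {
  set.seed(31)
  n <- 150
  X <- cbind(`(Intercept)` = 1,
             a = standardize(rnorm(n)), b = standardize(rnorm(n)),
             c = standardize(rnorm(n)))
  beta <- setNames(c(0.5, 0.4, 0, -0.3), colnames(X))
  expect_equal(fixed_effect_variance(X, beta, "b"), 0)
  # single standardized column with coefficient b -> b^2 (times var 1)
  expect_equal(fixed_effect_variance(X, beta, "a"), 0.4^2 * var(X[, "a"]))

  # group variances + 2 x pairwise covariances reconstruct Var(X beta)
  eta <- sapply(c("a", "b", "c"), function(v)
    drop(X[, v, drop = FALSE] %*% beta[v]))
  v_groups <- sum(apply(eta, 2, var))
  covs <- 2 * (cov(eta[, 1], eta[, 2]) + cov(eta[, 1], eta[, 3]) +
                 cov(eta[, 2], eta[, 3]))
  v_total <- var(drop(X[, -1] %*% beta[-1]))
  expect_equal(v_groups + covs, v_total, tolerance = 1e-10)
})

test_that("combined inversion variance handles correlation and cancellation", {
  set.seed(32)
  n <- 200
  x1 <- standardize(rbinom(n, 2, 0.5))
  X <- cbind(`(Intercept)` = 1, i1 = x1, i2 = x1)  # perfectly correlated
  beta <- c(0, 0.3, -0.3)                          # opposite effects
  expect_equal(inversions_combined(X, beta, c("i1", "i2")), 0,
               tolerance = 1e-12)
  # one inversion: combined equals its solo variance
  expect_equal(inversions_combined(X, beta, "i1"),
               fixed_effect_variance(X, beta, "i1"))
  # independent inversions: combined ~ sum of solo variances
  x2 <- standardize(rbinom(n, 2, 0.5))
  X2 <- cbind(`(Intercept)` = 1, i1 = x1, i2 = x2)
  b2 <- c(0, 0.3, 0.2)
  solo <- fixed_effect_variance(X2, b2, "i1") +
    fixed_effect_variance(X2, b2, "i2")
  comb <- inversions_combined(X2, b2, c("i1", "i2"))
  expect_lt(abs(comb - solo), 0.02)
})

test_that("partition bookkeeping sums to one and is order-invariant", {
  set.seed(33)
  n <- 200
  A <- family_grm(50, 4)
  smp <- data.frame(shore_height_m = rnorm(n),
                    sex = sample(c("F", "M"), n, TRUE),
                    trait = NA_real_)
  kar <- cbind(invA = rbinom(n, 2, 0.4), invB = rbinom(n, 2, 0.6))
  hab <- rnorm(n)
  lin <- 0.3 * standardize(hab) + 0.25 * standardize(kar[, 1]) -
    0.2 * standardize(kar[, 2])
  smp$trait <- lin + draw_mvn_response(matrix(0, n, 1), 0, A, 0.3, 0.4)
  des <- build_design(smp, "trait", karyotypes = kar, env_scores = hab,
                      covariates = c("habitat", "shore_height_m", "sex"))
  fit <- animal_model(des, grm = A)
  part <- partition_variance(fit, inversion_terms = c("invA", "invB"))
  core <- part$table[part$table$component != "inversions_combined", ]
  expect_equal(sum(core$proportion), 1, tolerance = 1e-6)
  expect_equal(sum(part$inversion_shares), 1, tolerance = 1e-10)

  # reordering fixed terms leaves component variances unchanged
  des2 <- build_design(smp, "trait", karyotypes = kar, env_scores = hab,
                       covariates = c("sex", "shore_height_m", "habitat"))
  fit2 <- animal_model(des2, grm = A)
  part2 <- partition_variance(fit2, inversion_terms = c("invA", "invB"))
  m1 <- setNames(part$table$variance, part$table$component)
  m2 <- setNames(part2$table$variance, part2$table$component)
  expect_equal(m2[names(m1)], m1, tolerance = 1e-8)
})

test_that("permuted responses collapse the genetic and fixed shares", {
  set.seed(34)
  n <- 300
  A <- family_grm(60, 5)
  kar <- cbind(invA = rbinom(n, 2, 0.5))
  smp <- data.frame(sex = sample(c("F", "M"), n, TRUE), trait = NA_real_)
  smp$trait <- 0.4 * standardize(kar[, 1]) +
    draw_mvn_response(matrix(0, n, 1), 0, A, 0.4, 0.3)
  shares <- replicate(5, {
    smp_p <- smp
    smp_p$trait <- sample(smp$trait)
    des <- build_design(smp_p, "trait", karyotypes = kar,
                        covariates = "sex")
    fit <- animal_model(des, grm = A)
    part <- partition_variance(fit)
    tab <- setNames(part$table$proportion, part$table$component)
    c(tab["invA"], tab["V_A"])
  })
  expect_lt(mean(shares[1, ]), 0.05)
  expect_lt(mean(shares[2, ]), 0.05)
})
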