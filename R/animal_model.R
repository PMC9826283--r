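# Animal-model REML: y = X beta + u + e with V(u) = sum_l sigma2_l A_l.
#
# Single-GRM fits use the eigendecomposition of A: rotating y and X by the
# eigenvectors diagonalizes V, the residual variance is profiled out, and the
# REML likelihood is maximized over the ratio lambda = sigma2_A / sigma2_e in
# one dimension. Multi-GRM fits use average-information REML with EM
# fallback steps.

#' Build the fixed-effect design matrix and standardized response
#'
#' Assembles the design for the contact-zone animal model: intercept,
#' z-scored covariates (habitat score, shore height, distance from the crab
#' habitat center), sex coded 0/1 then z-scored, one z-scored dosage column
#' per inversion, and optional interaction columns formed as elementwise
#' products of the standardized main effects. Missing covariate values
#' become 0 (the mean on the standardized scale); samples with a missing
#' response are dropped. The response itself is z-scored so variance
#' components read directly as proportions of phenotypic variance.
#'
#' @param samples data frame (see [read_sample_table()]); must contain the
#'   `response` column and any requested covariate columns.
#' @param response name of the trait column.
#' @param karyotypes optional samples x inversions dosage matrix (rows
#'   aligned with `samples`).
#' @param env_scores optional per-sample habitat PC scores (aligned with
#'   `samples`); used as the `habitat` column.
#' @param covariates character vector of main-effect columns; defaults to
#'   the standard set present in the data among `habitat`, `shore_height_m`,
#'   `dist_center_m`, `sex`.
#' @param interactions list of character pairs of term names, e.g.
#'   `list(c("habitat", "shore_height_m"))`.
#' @return list of class `model_design`: `y` (standardized response), `X`
#'   (n x p with intercept), `assign` (term label per column), `samples`
#'   (row index kept), `response`.
#' @export
build_design <- function(samples, response, karyotypes = NULL,
                         env_scores = NULL,
                         covariates = NULL,
                         interactions = NULL) {
  stopifnot(response %in% names(samples))
  dat <- samples
  if (!is.null(env_scores)) dat$habitat <- env_scores
  if (is.null(covariates))
    covariates <- intersect(c("habitat", "shore_height_m", "dist_center_m",
                              "sex"), names(dat))
  keep <- !is.na(dat[[response]])
  if (sum(keep) < 3) stop("fewer than 3 samples with an observed response")
  dat <- dat[keep, , drop = FALSE]
  if (!is.null(karyotypes))
    karyotypes <- karyotypes[keep, , drop = FALSE]
  y <- standardize(dat[[response]], name = response)

  cols <- list()
  assign <- character(0)
  add_col <- function(v, name) {
    if (all(is.na(v)))
      stop("covariate '", name, "' has no observed values")
    z <- standardize(v, name = name)
    cols[[name]] <<- z
    assign <<- c(assign, name)
  }
  for (v in covariates) {
    if (!v %in% names(dat)) stop("covariate '", v, "' not found")
    x <- dat[[v]]
    if (v == "sex") {
      lev <- sort(unique(x[!is.na(x)]))
      if (length(lev) != 2) stop("sex must have exactly two levels")
      x <- as.numeric(x == lev[2])
    }
    add_col(x, v)
  }
  if (!is.null(karyotypes)) {
    if (is.null(colnames(karyotypes)))
      colnames(karyotypes) <- paste0("inv", seq_len(ncol(karyotypes)))
    for (v in colnames(karyotypes)) add_col(karyotypes[, v], v)
  }
  if (!is.null(interactions)) {
    for (pair in interactions) {
      if (!all(pair %in% names(cols)))
        stop("interaction terms must reference existing main effects: ",
             paste(pair, collapse = ":"))
      nm <- paste(pair, collapse = ":")
      cols[[nm]] <- cols[[pair[1]]] * cols[[pair[2]]]
      assign <- c(assign, nm)
    }
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  structure(list(y = y, X = X,
                 assign = c("(Intercept)", assign),
                 samples = which(keep), response = response),
            class = "model_design")
}

#' Variance inflation factors for a design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing column j on all other columns
#' (plus an intercept). Exactly collinear columns report `Inf`. The
#' intercept column, if present, is excluded from the report.
#'
#' @param X numeric design matrix (may include an intercept column of ones).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  const <- apply(X, 2, function(v) var(v) == 0)
  Xv <- X[, !const, drop = FALSE]
  p <- ncol(Xv)
  if (p == 0) stop("no non-constant columns")
  if (nrow(Xv) <= p) stop("need more rows than columns")
  out <- numeric(p)
  for (j in seq_len(p)) {
    yj <- Xv[, j]
    Zj <- cbind(1, Xv[, -j, drop = FALSE])
    fit <- lm.fit(Zj, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  names(out) <- colnames(Xv)
  out
}

# ---- REML internals -------------------------------------------------------

# Profile REML log-likelihood pieces for a fixed variance ratio lambda,
# working in the rotated basis where V = sigma2_e * diag(1 + lambda * d).
reml_profile_eval <- function(lambda, yt, Xt, d, n, p) {
  w <- 1 + lambda * d
  XtW <- Xt / w
  XtWX <- crossprod(Xt, XtW)
  XtWy <- crossprod(XtW, yt)
  R <- chol(XtWX)
  beta <- backsolve(R, forwardsolve(t(R), XtWy))
  r <- yt - Xt %*% beta
  rss <- sum(r^2 / w)
  s2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi) + 1 + log(s2e)) +
                  sum(log(w)) + 2 * sum(log(diag(R))))
  list(ll = ll, beta = drop(beta), s2e = s2e, XtWX = XtWX)
}

reml_eigen <- function(y, X, A, ratio_log_bounds = c(-12, 12),
                       tol = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  eg <- eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  if (diff(range(d)) < 1e-10)
    warning("GRM eigenvalues are (near-)constant; sigma2_A and sigma2_e ",
            "are not separately identifiable")
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  f <- function(t) reml_profile_eval(exp(t), yt, Xt, d, n, p)$ll
  opt <- optimize(f, interval = ratio_log_bounds, maximum = TRUE, tol = tol)
  ll0 <- reml_profile_eval(0, yt, Xt, d, n, p)  # boundary sigma2_A = 0
  boundary <- FALSE
  if (ll0$ll >= opt$objective || opt$maximum <= ratio_log_bounds[1] + 1e-6) {
    lambda <- 0
    best <- ll0
    boundary <- TRUE
  } else {
    lambda <- exp(opt$maximum)
    best <- reml_profile_eval(lambda, yt, Xt, d, n, p)
  }
  s2e <- best$s2e
  s2a <- lambda * s2e
  floor_val <- 1e-8 * var(y)
  if (boundary) s2a <- floor_val
  vb <- s2e * chol2inv(chol(best$XtWX))
  list(sigma2 = c(A = s2a, residual = s2e), beta = best$beta,
       vcov_beta = vb, logLik = best$ll, converged = TRUE,
       boundary = boundary, iterations = NA_integer_)
}

# Dense-matrix REML log-likelihood at a given variance parameter vector.
reml_loglik_dense <- function(theta, y, X, As) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(theta[length(theta)], n)
  for (l in seq_along(As)) V <- V + theta[l] * As[[l]]
  R <- chol(V)
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  Rx <- chol(XtViX)
  C <- chol2inv(Rx)
  Py <- Vi %*% y - ViX %*% (C %*% crossprod(ViX, y))
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(R))) +
            2 * sum(log(diag(Rx))) + sum(y * Py))
}

reml_ai <- function(y, X, As, max_iter = 100, tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  L <- length(As)
  vy <- var(y)
  floor_val <- 1e-8 * vy
  ols <- lm.fit(X, y)
  s2_tot <- sum(ols$residuals^2) / (n - p)
  theta <- rep(s2_tot / (L + 1), L + 1)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  ll <- NA_real_
  Py <- NULL; P <- NULL
  for (iter in seq_len(max_iter)) {
    V <- diag(theta[L + 1], n)
    for (l in seq_len(L)) V <- V + theta[l] * As[[l]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) {
      warning("singular V; adding a small ridge")
      V <- V + diag(1e-8 * mean(diag(V)), n)
      R <- chol(V)
    }
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    Rx <- chol(XtViX)
    C <- chol2inv(Rx)
    P <- Vi - ViX %*% tcrossprod(C, ViX)
    Py <- P %*% y
    ll <- -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(R))) +
                    2 * sum(log(diag(Rx))) + sum(y * Py))
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # score and average-information matrix over (sigma2_1..L, sigma2_e)
    q <- vector("list", L + 1)
    trPA <- numeric(L + 1)
    for (l in seq_len(L)) {
      q[[l]] <- As[[l]] %*% Py
      trPA[l] <- sum(P * As[[l]])
    }
    q[[L + 1]] <- Py
    trPA[L + 1] <- sum(diag(P))
    score <- numeric(L + 1)
    for (l in seq_len(L + 1))
      score[l] <- -0.5 * (trPA[l] - sum(Py * q[[l]]))
    AI <- matrix(0, L + 1, L + 1)
    for (a in seq_len(L + 1)) {
      Pq <- P %*% q[[a]]
      for (b in a:(L + 1)) {
        AI[a, b] <- AI[b, a] <- 0.5 * sum(q[[b]] * Pq)
      }
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    prop <- if (!is.null(step)) theta + step else NULL
    if (is.null(prop) || any(!is.finite(prop)) || any(prop < floor_val)) {
      # EM update keeps the parameters in the feasible region
      em <- theta + theta^2 * (2 * score) / n
      prop <- pmax(em, floor_val)
    }
    theta <- prop
  }
  if (!converged)
    warning("AI-REML did not converge within ", max_iter, " iterations")
  # final GLS quantities at the last theta
  V <- diag(theta[L + 1], n)
  for (l in seq_len(L)) V <- V + theta[l] * As[[l]]
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  C <- chol2inv(chol(XtViX))
  beta <- drop(C %*% crossprod(ViX, y))
  nms <- names(As)
  if (is.null(nms)) nms <- paste0("A", seq_len(L))
  list(sigma2 = setNames(c(theta[seq_len(L)], theta[L + 1]),
                         c(nms, "residual")),
       beta = beta, vcov_beta = C,
       logLik = reml_loglik_dense(theta, y, X, As),
       converged = converged, boundary = any(theta <= floor_val * 1.001),
       iterations = iter)
}

# REML for the fixed-effects-only model (iid residual); logLik on the same
# scale as the mixed fits so likelihood-ratio tests are valid.
reml_null <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - p)
  XtX <- crossprod(X)
  ll <- -0.5 * ((n - p) * (log(2 * pi) + 1 + log(s2)) +
                  determinant(XtX, logarithm = TRUE)$modulus)
  list(sigma2 = c(residual = s2), beta = coef(fit),
       vcov_beta = s2 * chol2inv(chol(XtX)), logLik = as.numeric(ll),
       converged = TRUE, boundary = FALSE, iterations = 0L)
}

# ---- user-facing fit ------------------------------------------------------

#' Fit the animal model by REML
#'
#' Fits \eqn{y = X\beta + u + e} with \eqn{V(u) = \sum_l \sigma^2_l A_l}
#' given one or more genomic relationship matrices. A single GRM is fitted
#' by an exact eigendecomposition profile REML (1-D optimization of the
#' variance ratio); multiple GRMs (e.g. one per linkage group) by
#' average-information REML with EM fallback; `grm = NULL` fits the
#' fixed-effects-only model (used as the reduced model in [lrt_va()]).
#'
#' @param y numeric response (typically the z-scored trait from
#'   [build_design()]), or a `model_design` object (then `X`/`assign` are
#'   taken from it).
#' @param X fixed-effect design matrix including the intercept.
#' @param grm a [compute_grm()] object, a named list of them (or bare
#'   matrices), or `NULL`.
#' @param assign optional term label per design column (for [wald_tests()]).
#' @param ... passed to the underlying solver (`max_iter`, `tol`).
#' @return Object of class `animal_model`; see [summary.animal_model()].
#'   Components include `beta`, `vcov_beta`, `sigma2` (named: one entry per
#'   GRM plus `residual`), `h2` (ratio of the summed genetic components to
#'   total variance), `logLik`, `converged`, `boundary`, `n`, `rank`,
#'   `df_residual`.
#' @export
animal_model <- function(y, X = NULL, grm = NULL, assign = NULL, ...) {
  if (inherits(y, "model_design")) {
    design <- y
    y <- design$y
    if (is.null(X)) X <- design$X
    if (is.null(assign)) assign <- design$assign
  }
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X rows must match length(y)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank-deficient (rank ", qrX$rank, " < ",
         ncol(X), " columns)")
  grms <- NULL
  if (!is.null(grm)) {
    grms <- if (inherits(grm, "grm") || (is.matrix(grm))) list(A = grm)
            else grm
    grms <- lapply(grms, function(a) {
      m <- if (inherits(a, "grm")) a$matrix else as.matrix(a)
      if (nrow(m) != n) stop("GRM dimension does not match length(y)")
      (m + t(m)) / 2
    })
  }
  method <- if (is.null(grms)) "null"
            else if (length(grms) == 1) "eigen" else "ai"
  res <- switch(method,
                null = reml_null(y, X),
                eigen = reml_eigen(y, X, grms[[1]], ...),
                ai = reml_ai(y, X, grms, ...))
  if (method == "eigen")
    names(res$sigma2)[1] <- if (!is.null(names(grms))) names(grms)[1] else "A"
  beta <- setNames(res$beta, colnames(X))
  vb <- res$vcov_beta
  dimnames(vb) <- list(colnames(X), colnames(X))
  s2 <- res$sigma2
  gen <- sum(s2[names(s2) != "residual"])
  fit <- structure(list(
    beta = beta, vcov_beta = vb, sigma2 = s2,
    h2 = if (method == "null") 0 else gen / sum(s2),
    logLik = res$logLik, converged = res$converged,
    boundary = res$boundary, iterations = res$iterations,
    n = n, rank = qrX$rank, df_residual = n - qrX$rank,
    y = y, X = X, assign = assign, grms = grms, method = method,
    call = match.call()),
    class = "animal_model")
  fit
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Animal model (REML,", x$method, "solver)\n")
  cat(sprintf("  n = %d, fixed-effect rank = %d, logLik = %.4f%s\n",
              x$n, x$rank, x$logLik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  cat("  variance components:\n")
  for (nm in names(x$sigma2))
    cat(sprintf("    %-10s %.4f\n", nm, x$sigma2[nm]))
  if (x$method != "null")
    cat(sprintf("  h2 = %.3f%s\n", x$h2,
                if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Summarize an animal-model fit
#'
#' @param object an [animal_model()] fit.
#' @param ... unused.
#' @return list of class `summary.animal_model` with the variance
#'   components, heritability and the conditional Wald table.
#' @export
summary.animal_model <- function(object, ...) {
  w <- tryCatch(wald_tests(object), error = function(e) NULL)
  structure(list(fit = object, wald = w), class = "summary.animal_model")
}

#' @export
print.summary.animal_model <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$wald)) {
    cat("  conditional Wald tests:\n")
    print(x$wald, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) object$beta

#' @export
vcov.animal_model <- function(object, ...) object$vcov_beta

#' @export
logLik.animal_model <- function(object, ...) {
  structure(object$logLik, df = length(object$sigma2),
            nobs = object$n, class = "logLik")
}

#' @export
fitted.animal_model <- function(object, ...) drop(object$X %*% object$beta)

#' @export
residuals.animal_model <- function(object, ...) object$y - fitted(object)

#' Predict from an animal-model fit
#'
#' `type = "marginal"` returns `X beta` for new design rows; `type =
#' "conditional"` adds the BLUP of the genetic effect for the training
#' samples (newdata must be omitted).
#'
#' @param object an [animal_model()] fit.
#' @param newdata optional design matrix with the same columns as the fit.
#' @param type `"marginal"` or `"conditional"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.animal_model <- function(object, newdata = NULL,
                                 type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  if (type == "marginal") {
    X <- if (is.null(newdata)) object$X else as.matrix(newdata)
    return(drop(X %*% object$beta))
  }
  if (!is.null(newdata))
    stop("conditional predictions are only defined for the training samples")
  drop(object$X %*% object$beta) + blup(object)
}

#' Best linear unbiased predictions of the genetic effects
#'
#' @param object an [animal_model()] fit with at least one GRM.
#' @return numeric vector (sum of the BLUPs over all genetic components).
#' @export
blup <- function(object) {
  stopifnot(inherits(object, "animal_model"))
  if (object$method == "null") return(rep(0, object$n))
  s2 <- object$sigma2
  n <- object$n
  V <- diag(s2["residual"], n)
  comps <- names(s2)[names(s2) != "residual"]
  for (i in seq_along(comps)) V <- V + s2[comps[i]] * object$grms[[i]]
  r <- object$y - fitted(object)
  Vir <- solve(V, r)
  u <- rep(0, n)
  for (i in seq_along(comps))
    u <- u + drop(s2[comps[i]] * object$grms[[i]] %*% Vir)
  u
}

#' Simulate responses from a fitted animal model
#'
#' Draws `nsim` response vectors from `N(X beta, V)` at the REML estimates.
#'
#' @param object an [animal_model()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return matrix `n x nsim`.
#' @export
simulate.animal_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  s2 <- object$sigma2
  V <- diag(s2["residual"], n)
  comps <- names(s2)[names(s2) != "residual"]
  for (i in seq_along(comps)) V <- V + s2[comps[i]] * object$grms[[i]]
  R <- chol(V + diag(1e-10 * mean(diag(V)), n))
  mu <- fitted(object)
  mu + crossprod(R, matrix(rnorm(n * nsim), n, nsim))
}

#' @export
plot.animal_model <- function(x, ...) {
  plot(fitted(x), residuals(x), xlab = "fitted", ylab = "residual",
       main = "Animal model residuals", ...)
  abline(h = 0, lty = 2)
  invisible(x)
}
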