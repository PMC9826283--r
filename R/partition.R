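# Variance partitioning: fixed-effect contributions, V_A and residual as
# proportions of total phenotypic variance.

#' Variance of a term group's partial linear predictor
#'
#' The variance across individuals of `X_g beta_g` for the columns of one
#' term group (the de Villemereuil-style fixed-effect variance).
#'
#' @param X design matrix.
#' @param beta fixed-effect estimates aligned with `X` columns.
#' @param idx column indices (or names) of the group.
#' @return sample variance of the partial predictor.
#' @export
fixed_effect_variance <- function(X, beta, idx) {
  if (is.character(idx)) idx <- match(idx, colnames(X))
  var(drop(X[, idx, drop = FALSE] %*% beta[idx]))
}

#' Combined variance explained by all inversions
#'
#' Variance of the summed inversion partial predictor; includes the
#' between-inversion covariances, so it is not the sum of the per-inversion
#' variances when dosages are correlated (e.g. along a shared cline).
#'
#' @param X design matrix.
#' @param beta fixed-effect estimates.
#' @param inversion_idx indices (or names) of the inversion columns.
#' @return sample variance of the combined predictor.
#' @export
inversions_combined <- function(X, beta, inversion_idx) {
  fixed_effect_variance(X, beta, inversion_idx)
}

#' Partition phenotypic variance into model components
#'
#' Decomposes the sample variance of the analyzed response into the variance
#' of each fixed-effect term's partial predictor, a single line collecting
#' twice the pairwise covariances between term predictors
#' (`fixed_covariance`), the additive genetic component(s) `V_A`, the
#' residual, and an `unattributed` remainder (the gap between the observed
#' total and the model-implied pieces), so the proportions sum to exactly 1.
#' Negative covariance between predictors (terms diminishing each other's
#' effect) appears with its sign in `fixed_covariance`.
#'
#' @param fit an [animal_model()] fit (with `assign` labels).
#' @param inversion_terms term labels to combine as "inversions"; their
#'   per-term rows are also reported, plus an `inversions_combined` row and
#'   per-inversion shares of the combined variance.
#' @return list of class `variance_partition`: `table` (component,
#'   variance, proportion), `inversion_shares` (per-inversion share of the
#'   combined inversion variance), `total` (Var(y)).
#' @export
partition_variance <- function(fit, inversion_terms = NULL) {
  stopifnot(inherits(fit, "animal_model"))
  if (!fit$converged)
    warning("partitioning a non-converged fit")
  y <- fit$y
  total <- var(y)
  if (total == 0) stop("total phenotypic variance is zero")
  assign <- fit$assign
  if (is.null(assign)) assign <- colnames(fit$X)
  terms <- setdiff(unique(assign), "(Intercept)")
  eta <- sapply(terms, function(tm) {
    idx <- which(assign == tm)
    drop(fit$X[, idx, drop = FALSE] %*% fit$beta[idx])
  })
  eta <- matrix(eta, nrow = fit$n,
                dimnames = list(NULL, terms))
  v_term <- apply(eta, 2, var)
  eta_tot <- rowSums(eta)
  v_fixed_total <- var(eta_tot)
  cov_line <- v_fixed_total - sum(v_term)   # = 2 * sum of pairwise covs
  s2 <- fit$sigma2
  va <- sum(s2[names(s2) != "residual"])
  resid <- unname(s2["residual"])
  unattributed <- total - (v_fixed_total + va + resid)
  comp <- c(v_term,
            fixed_covariance = cov_line,
            V_A = va, residual = resid, unattributed = unattributed)
  tab <- data.frame(component = names(comp), variance = unname(comp),
                    proportion = unname(comp) / total,
                    stringsAsFactors = FALSE)
  inv_shares <- NULL
  if (!is.null(inversion_terms) && length(inversion_terms)) {
    miss <- setdiff(inversion_terms, terms)
    if (length(miss)) stop("unknown inversion terms: ",
                           paste(miss, collapse = ", "))
    idx <- which(assign %in% inversion_terms)
    v_comb <- fixed_effect_variance(fit$X, fit$beta, idx)
    tab <- rbind(tab,
                 data.frame(component = "inversions_combined",
                            variance = v_comb,
                            proportion = v_comb / total,
                            stringsAsFactors = FALSE))
    solo <- v_term[inversion_terms]
    inv_shares <- if (sum(solo) > 0) solo / sum(solo) else solo * NA
  }
  structure(list(table = tab, inversion_shares = inv_shares,
                 total = total),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("variance partition (total = %.4f)\n", x$total))
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$inversion_shares)) {
    cat("per-inversion share of combined inversion variance:\n")
    print(round(x$inversion_shares, 4))
  }
  invisible(x)
}
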