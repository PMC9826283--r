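# Fixed-effect tests, the V_A likelihood-ratio test and FDR correction.

#' Conditional Wald tests for fixed-effect terms
#'
#' Tests each term given all other terms in the model: for a term's
#' coefficient block \eqn{\beta_g} with covariance block \eqn{C_g},
#' \eqn{F = \beta_g' C_g^{-1} \beta_g / q} with `q` the block size, compared
#' to an F distribution with denominator degrees of freedom
#' `n - rank(X)`.
#'
#' @param fit an [animal_model()] fit carrying an `assign` vector (one term
#'   label per design column; built automatically by [build_design()]).
#' @param terms terms to test (default: all non-intercept terms).
#' @return data frame with columns `term`, `F`, `num_df`, `den_df`, `p`.
#' @export
wald_tests <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "animal_model"))
  if (!fit$converged)
    warning("fit did not converge; Wald tests may be unreliable")
  assign <- fit$assign
  if (is.null(assign))
    assign <- colnames(fit$X)
  if (is.null(terms))
    terms <- setdiff(unique(assign), "(Intercept)")
  den_df <- fit$df_residual
  out <- lapply(terms, function(tm) {
    idx <- which(assign == tm)
    if (!length(idx)) stop("term '", tm, "' not found in the design")
    b <- fit$beta[idx]
    Cb <- fit$vcov_beta[idx, idx, drop = FALSE]
    Ci <- tryCatch(solve(Cb), error = function(e)
      stop("covariance block for term '", tm, "' is singular"))
    q <- length(idx)
    Fstat <- drop(t(b) %*% Ci %*% b) / q
    data.frame(term = tm, F = Fstat, num_df = q, den_df = den_df,
               p = pf(Fstat, q, den_df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Likelihood-ratio test for additive genetic variance
#'
#' Compares the full animal model to the fixed-effects-only model with the
#' same design on the same samples: statistic `2 (logL_full - logL_reduced)`
#' against a chi-square with 1 df. The 1-df reference is conservative when
#' the true variance sits on the boundary; `mixture = TRUE` uses the
#' 0.5*chi2(0) + 0.5*chi2(1) mixture instead.
#'
#' @param fit_full [animal_model()] fit with a GRM.
#' @param fit_null [animal_model()] fit with `grm = NULL` and the same `X`.
#' @param mixture use the boundary mixture reference distribution.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_va <- function(fit_full, fit_null, mixture = FALSE) {
  stopifnot(inherits(fit_full, "animal_model"),
            inherits(fit_null, "animal_model"))
  if (fit_full$n != fit_null$n || fit_full$rank != fit_null$rank)
    stop("models must share the same samples and fixed effects")
  stat <- 2 * (fit_full$logLik - fit_null$logLik)
  if (stat < -1e-6)
    stop("full-model likelihood below the reduced model's; ",
         "REML optimization failed")
  stat <- max(stat, 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (stat == 0) 1 else p / 2
  list(statistic = stat, df = 1, p = p)
}

#' Benjamini-Hochberg FDR adjustment within term groups
#'
#' Each fixed effect is tested on multiple traits; p-values are adjusted by
#' the BH step-up procedure within each term's group of traits.
#'
#' @param p numeric vector of p-values.
#' @param group optional grouping factor (e.g. the term); `NULL` adjusts the
#'   whole vector together.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p, group = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (is.null(group)) return(p.adjust(p, method = "BH"))
  out <- p
  for (g in unique(group)) {
    idx <- which(group == g)
    out[idx] <- p.adjust(p[idx], method = "BH")
  }
  out
}
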