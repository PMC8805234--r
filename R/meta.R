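#' Inverse-variance-weighted meta-analysis
#'
#' Pools per-sample estimate records with inverse-variance weights under a
#' common-effect (fixed-effects) model, reporting Cochran's Q, its degrees
#' of freedom and p-value, and \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}.
#' A DerSimonian-Laird random-effects fit is available as a sensitivity
#' option.
#'
#' @param records Tibble of estimate records (needs `beta` and `se`;
#'   `stratum` labels are carried along if present).
#' @param method `"fixed"` (default) or `"random"` (DerSimonian-Laird).
#' @return An object of class `ntmr_meta`; see [tidy.ntmr_meta()],
#'   [glance.ntmr_meta()] and [autoplot.ntmr_meta()].
#' @examples
#' recs <- tibble::tibble(stratum = c("a", "b"), beta = c(0.1, 0.3),
#'                        se = c(0.1, 0.1))
#' glance(meta_fixed(recs))
#' @export
meta_fixed <- function(records, method = c("fixed", "random")) {
  method <- match.arg(method)
  if (nrow(records) < 1) abort("need at least one record")
  if (any(!is.finite(records$se)) || any(records$se <= 0)) {
    abort("all standard errors must be positive and finite")
  }
  b <- records$beta
  w <- 1 / records$se^2
  pooled_fe <- sum(w * b) / sum(w)
  q <- sum(w * (b - pooled_fe)^2)
  df <- length(b) - 1L
  p_q <- if (df > 0) pchisq(q, df, lower.tail = FALSE) else NA_real_
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  if (method == "random" && df > 0) {
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (records$se^2 + tau2)
  }
  pooled <- sum(w * b) / sum(w)
  structure(
    list(
      pooled_beta = pooled, pooled_se = sqrt(1 / sum(w)),
      q = q, df = df, p_q = p_q, i2 = i2,
      method = method, members = records
    ),
    class = "ntmr_meta"
  )
}

#' @export
print.ntmr_meta <- function(x, ...) {
  cat(sprintf("<ntmr_meta> %s-effects pooling of %d estimate(s)\n",
              x$method, nrow(x$members)))
  cat(sprintf("  beta = %.4f (SE %.4f); Q = %.3f on %d df (p = %s); I2 = %.1f%%\n",
              x$pooled_beta, x$pooled_se, x$q, x$df,
              format.pval(x$p_q, digits = 3), x$i2))
  invisible(x)
}

#' Tidy the member estimates of a meta-analysis
#' @param x An `ntmr_meta` object.
#' @param ... Unused.
#' @return The member estimate tibble with a `weight` column (normalised
#'   pooling weights).
#' @exportS3Method generics::tidy
tidy.ntmr_meta <- function(x, ...) {
  out <- x$members
  w <- 1 / out$se^2
  out$weight <- w / sum(w)
  out
}

#' One-row summary of a meta-analysis
#' @param x An `ntmr_meta` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ntmr_meta <- function(x, ...) {
  z <- x$pooled_beta / x$pooled_se
  tibble::tibble(
    beta = x$pooled_beta, se = x$pooled_se,
    ci_low = x$pooled_beta - qnorm(0.975) * x$pooled_se,
    ci_high = x$pooled_beta + qnorm(0.975) * x$pooled_se,
    p = 2 * pnorm(-abs(z)),
    q = x$q, df = x$df, p_q = x$p_q, i2 = x$i2, method = x$method
  )
}

#' Pooled ratio estimator across samples
#'
#' Pools the instrument-outcome and instrument-exposure coefficients
#' separately by fixed-effects meta-analysis, then applies the Wald ratio
#' and Taylor-series SE to the pooled coefficients (the pooled-MR estimator;
#' with a single sample this reduces to [ratio_estimate()]).
#'
#' @param inputs Tibble with one row per sample: `beta_zy`, `se_zy`,
#'   `beta_zx`, `se_zx` (optional `n`, `stratum`).
#' @param order Taylor SE order, see [ratio_estimate()].
#' @param outcome Optional outcome label.
#' @return One-row estimate tibble (`method = "ratio_meta"`), with the two
#'   pooling objects attached as attribute `meta`.
#' @export
ratio_meta <- function(inputs, order = c("first", "second"),
                       outcome = NA_character_) {
  order <- match.arg(order)
  stopifnot(all(c("beta_zy", "se_zy", "beta_zx", "se_zx") %in% names(inputs)))
  num <- meta_fixed(tibble::tibble(beta = inputs$beta_zy, se = inputs$se_zy))
  den <- meta_fixed(tibble::tibble(beta = inputs$beta_zx, se = inputs$se_zx))
  if (den$pooled_beta == 0) abort("pooled denominator is zero")
  n_tot <- if ("n" %in% names(inputs)) sum(inputs$n) else NA
  out <- ratio_estimate(num$pooled_beta, num$pooled_se,
                        den$pooled_beta, den$pooled_se,
                        n = n_tot, order = order, outcome = outcome)
  out$method <- "ratio_meta"
  attr(out, "meta") <- list(numerator = num, denominator = den)
  out
}

#' Between-SNP heterogeneity of Wald ratios (Cochran's Q)
#'
#' Tests whether per-SNP MR estimates share a common value:
#' \eqn{Q = \sum_j w_j (b_j - b_{IVW})^2}, \eqn{w_j = 1/se_j^2}, referred to
#' a chi-square with k-1 df. Large Q indicates heterogeneous per-SNP causal
#' estimates, a signature of horizontal pleiotropy.
#'
#' @param wald_tbl Per-SNP table from [per_snp_wald()] (needs `beta`, `se`).
#' @return Tibble with `q`, `df`, `p`, `i2`, `b_ivw`.
#' @export
cochran_q_snps <- function(wald_tbl) {
  tbl <- wald_tbl[is.finite(wald_tbl$beta) & is.finite(wald_tbl$se), ]
  if (nrow(tbl) < 2) abort("need at least 2 usable SNPs for Cochran's Q")
  w <- 1 / tbl$se^2
  b_ivw <- sum(w * tbl$beta) / sum(w)
  q <- sum(w * (tbl$beta - b_ivw)^2)
  df <- nrow(tbl) - 1L
  tibble::tibble(
    q = q, df = df, p = pchisq(q, df, lower.tail = FALSE),
    i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0,
    b_ivw = b_ivw
  )
}
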