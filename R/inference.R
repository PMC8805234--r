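# General linear IV solve: regressors A, instruments Zf (both with exogenous
# columns included identically). Homoskedastic asymptotic vcov.
iv_fit <- function(y, A, Zf) {
  Ahat <- Zf %*% solve(crossprod(Zf), crossprod(Zf, A))
  b <- solve(crossprod(Ahat, A), crossprod(Ahat, y))
  resid <- y - A %*% b
  sigma2 <- sum(resid^2) / (length(y) - ncol(A))
  V <- sigma2 * solve(crossprod(Ahat))
  list(coef = as.numeric(b), V = V, resid = as.numeric(resid))
}

#' Bootstrap-covariance z-test for an MV-versus-MR difference
#'
#' Tests whether the fully adjusted multivariable estimate (model three)
#' differs from the MR (TSLS) estimate for the same outcome. Because both
#' are computed on overlapping samples from the same cohort, their sampling
#' covariance is estimated by a paired nonparametric bootstrap over
#' families: in each replicate the families are resampled with replacement
#' and both point estimates are recomputed; the test statistic is
#' \deqn{z = (\beta_{MV} - \beta_{MR}) /
#'   \sqrt{se_{MV}^2 + se_{MR}^2 - 2\,\widehat{cov}_{boot}}}
#' with a two-sided normal p-value. Evidence of a difference indicates
#' residual confounding of the MV estimate or violated MR assumptions.
#'
#' @param pheno Phenotype tibble (one row per family).
#' @param outcome Outcome column.
#' @param instrument Instrument column name or numeric vector aligned to
#'   `pheno` rows.
#' @param exposure Exposure column.
#' @param mr_covariates Covariates for the TSLS model (e.g. genetic PCs).
#' @param model_covariates Covariate sets for the MV models (see
#'   [mv_regress()]); model three is used.
#' @param n_boot Bootstrap replicates (>= 500).
#' @param seed RNG seed for the bootstrap, recorded in the output.
#' @return An `ntmr_difftest` object (list with `beta_mv`, `se_mv`,
#'   `beta_mr`, `se_mr`, `cov_boot`, `z`, `p`, `n_boot`, `seed`).
#' @export
mv_mr_difference_test <- function(pheno, outcome, instrument,
                                  exposure = "exposure",
                                  mr_covariates = character(),
                                  model_covariates = NULL,
                                  n_boot = 1000, seed = 1) {
  if (n_boot < 500) abort("n_boot must be at least 500")
  mv_args <- list(pheno = pheno, outcome = outcome, model = "three",
                  exposure = exposure)
  if (!is.null(model_covariates)) mv_args$model_covariates <- model_covariates
  mv <- do.call(mv_regress, mv_args)
  mr <- tsls(pheno, outcome, instrument, exposure = exposure,
             covariates = mr_covariates)

  z_col <- if (is.character(instrument) && length(instrument) == 1) {
    pheno[[instrument]]
  } else {
    as.numeric(instrument)
  }
  mc <- if (is.null(model_covariates)) formals(mv_regress)$model_covariates else model_covariates
  mc <- if (is.call(mc)) eval(mc) else mc
  mv_cols <- unique(c(outcome, exposure, unlist(mc)))
  mv_cols <- intersect(mv_cols, names(pheno))
  cc_mv <- complete.cases(pheno[, mv_cols])
  mr_cols <- c(outcome, exposure, mr_covariates)
  cc_mr <- complete.cases(pheno[, mr_cols]) & !is.na(z_col)

  n <- nrow(pheno)
  y <- pheno[[outcome]]
  Xmv <- model_matrix_from(pheno, unique(c(exposure, mc$three)))
  W <- if (length(mr_covariates)) as.matrix(pheno[, mr_covariates]) else NULL
  Zf_full <- cbind(z = z_col, 1, W)
  x_full <- pheno[[exposure]]

  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 2)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    imv <- idx[cc_mv[idx]]
    b_mv <- stats::lm.fit(Xmv[imv, , drop = FALSE], y[imv])$coefficients[2]
    imr <- idx[cc_mr[idx]]
    Zb <- Zf_full[imr, , drop = FALSE]
    xhat <- Zb %*% qr.solve(Zb, x_full[imr])
    Ab <- cbind(xhat, Zb[, -1, drop = FALSE])
    b_mr <- stats::lm.fit(Ab, y[imr])$coefficients[1]
    reps[r, ] <- c(b_mv, b_mr)
  }
  cov_boot <- stats::cov(reps[, 1], reps[, 2])
  v_diff <- mv$se^2 + mr$se^2 - 2 * cov_boot
  if (v_diff <= 0) {
    abort(sprintf(
      "non-positive difference variance (bootstrap covariance = %.3g)",
      cov_boot
    ))
  }
  z <- (mv$beta - mr$beta) / sqrt(v_diff)
  structure(
    list(beta_mv = mv$beta, se_mv = mv$se, beta_mr = mr$beta, se_mr = mr$se,
         cov_boot = cov_boot, z = z, p = 2 * pnorm(-abs(z)),
         n_boot = n_boot, seed = seed,
         n_mv = mv$n, n_mr = mr$n),
    class = "ntmr_difftest"
  )
}

#' @export
print.ntmr_difftest <- function(x, ...) {
  cat("<ntmr_difftest> MV (model three) vs MR\n")
  cat(sprintf("  beta_mv = %.4f (SE %.4f, n = %d); beta_mr = %.4f (SE %.4f, n = %d)\n",
              x$beta_mv, x$se_mv, x$n_mv, x$beta_mr, x$se_mr, x$n_mr))
  cat(sprintf("  bootstrap cov = %.3g (%d reps, seed %d); z = %.3f, p = %s\n",
              x$cov_boot, x$n_boot, x$seed, x$z, format.pval(x$p, digits = 3)))
  invisible(x)
}

#' @rdname mv_mr_difference_test
#' @param x An `ntmr_difftest` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ntmr_difftest <- function(x, ...) {
  tibble::tibble(
    beta_mv = x$beta_mv, se_mv = x$se_mv, beta_mr = x$beta_mr,
    se_mr = x$se_mr, cov_boot = x$cov_boot, z = x$z, p = x$p,
    n_boot = x$n_boot, seed = x$seed
  )
}

#' MR-Egger regression
#'
#' Inverse-variance-weighted regression (weights \eqn{1/se_{ZY}^2}) of the
#' per-SNP outcome coefficients on the exposure coefficients *with* a free
#' intercept, after orienting every SNP so its exposure coefficient is
#' positive. A non-zero intercept signals directional horizontal pleiotropy;
#' the slope is a pleiotropy-adjusted causal estimate.
#'
#' @param wald_tbl Per-SNP table with `beta_zx`, `se_zx`, `beta_zy`,
#'   `se_zy` (>= 3 SNPs).
#' @return Tibble with `intercept`, `intercept_se`, `intercept_p`, `slope`,
#'   `slope_se`, `slope_p`, `n_snps`.
#' @export
mr_egger <- function(wald_tbl) {
  tbl <- wald_tbl[stats::complete.cases(
    wald_tbl[, c("beta_zx", "se_zx", "beta_zy", "se_zy")]), ]
  if (nrow(tbl) < 3) abort("MR-Egger needs at least 3 SNPs")
  s <- ifelse(tbl$beta_zx < 0, -1, 1)
  bx <- tbl$beta_zx * s
  by <- tbl$beta_zy * s
  if (sd(bx) == 0) abort("no identification: all exposure coefficients equal")
  fit <- lm(by ~ bx, weights = 1 / tbl$se_zy^2)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    intercept = sm[1, 1], intercept_se = sm[1, 2], intercept_p = sm[1, 4],
    slope = sm[2, 1], slope_se = sm[2, 2], slope_p = sm[2, 4],
    n_snps = nrow(tbl)
  )
}

#' Screen an instrument against potential confounders and risk factors
#'
#' A valid instrument should be unrelated to confounders of the
#' exposure-outcome association. Computes the Pearson correlation of the
#' score with each candidate risk-factor column, with two-sided p-values and
#' significance stars at 0.05 / 0.001 / 1e-5.
#'
#' @param data Tibble containing the score and risk-factor columns.
#' @param score_col Name of the score column.
#' @param factor_cols Character vector of risk-factor columns (default: all
#'   other numeric columns).
#' @return Tibble `factor`, `r`, `p`, `stars`, `n`, `note` (constant columns
#'   are skipped with a note).
#' @export
instrument_validity_screen <- function(data, score_col,
                                       factor_cols = NULL) {
  if (is.null(factor_cols)) {
    factor_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                           score_col)
  }
  if (!length(factor_cols)) abort("no risk-factor columns to screen")
  purrr::map_dfr(factor_cols, function(cl) {
    ok <- complete.cases(data[, c(score_col, cl)])
    x <- data[[score_col]][ok]; yv <- data[[cl]][ok]
    if (sd(yv) == 0 || sd(x) == 0) {
      return(tibble::tibble(factor = cl, r = NA_real_, p = NA_real_,
                            stars = "", n = sum(ok), note = "constant column"))
    }
    ct <- cor.test(x, yv)
    p <- ct$p.value
    tibble::tibble(
      factor = cl, r = unname(ct$estimate), p = p,
      stars = if (p < 1e-5) "***" else if (p < 1e-3) "**" else if (p < 0.05) "*" else "",
      n = sum(ok), note = ""
    )
  })
}

#' MR stratified by SNP effect size
#'
#' Partitions the instrument's SNPs into quantile bins of absolute weight,
#' builds a sub-score per bin, runs TSLS per sub-score, and fits an
#' inverse-variance-weighted linear trend of the MR estimate on the inverse
#' bin median absolute weight (the scale on which a fixed pleiotropic
#' outcome effect biases a bin's estimate linearly). If horizontal
#' pleiotropy is concentrated among weakly associated SNPs, small-weight
#' bins give larger MR estimates and the trend slope is positive.
#'
#' @param pheno Phenotype tibble.
#' @param dosages Dosage matrix aligned to `pheno` rows (e.g. non-transmitted
#'   dosages).
#' @param weights Harmonised weight table.
#' @param outcome,exposure Column names.
#' @param n_bins Number of bins (default 5, quintiles).
#' @param covariates TSLS covariates.
#' @return List with `per_bin` (estimate tibble with `bin`,
#'   `median_abs_weight`, `n_snps`) and `trend` (`slope`, `se`, `p`).
#' @export
effect_size_stratified_mr <- function(pheno, dosages, weights, outcome,
                                      exposure = "exposure", n_bins = 5,
                                      covariates = character()) {
  if (n_bins < 2) abort("n_bins must be at least 2")
  if (nrow(weights) < n_bins) abort("fewer SNPs than bins")
  bin <- dplyr::ntile(abs(weights$weight), n_bins)
  per_bin <- purrr::map_dfr(seq_len(n_bins), function(b) {
    wb <- weights[bin == b, , drop = FALSE]
    if (nrow(wb) == 0) abort(sprintf("empty bin %d", b))
    sc <- score(dosages, wb)
    est <- tsls(pheno, outcome, std(sc$score), exposure = exposure,
                covariates = covariates)
    est$bin <- b
    est$median_abs_weight <- median(abs(wb$weight))
    est$n_snps <- nrow(wb)
    est
  })
  # IVW meta-regression of bin estimates (known SEs) on the *inverse* bin
  # median |weight|: a fixed per-SNP pleiotropic outcome effect biases a
  # bin's Wald ratio in proportion to the inverse of its instrument
  # strength, so the bias is linear on this scale (and a linear-in-median
  # regression is misspecified). Positive slope = larger estimates in
  # smaller-effect bins. Normal-theory inference, as in fixed-effects
  # meta-regression.
  tw <- 1 / per_bin$se^2
  X <- cbind(1, 1 / per_bin$median_abs_weight)
  XtWX_inv <- solve(crossprod(X * sqrt(tw)))
  bhat <- XtWX_inv %*% crossprod(X * tw, per_bin$beta)
  slope <- bhat[2]
  slope_se <- sqrt(XtWX_inv[2, 2])
  list(
    per_bin = per_bin,
    trend = tibble::tibble(slope = slope, se = slope_se,
                           p = 2 * pnorm(-abs(slope / slope_se)))
  )
}

#' Sex-interaction sensitivity test
#'
#' Tests whether the exposure effect differs by offspring sex, via the
#' product term in either the multivariable model (default) or the
#' second stage of a TSLS fit (the instrument and its sex product instrument
#' the exposure and its sex product).
#'
#' @param pheno Phenotype tibble.
#' @param outcome,exposure Column names.
#' @param sex Sex column (two levels required).
#' @param instrument Optional instrument column/vector; if given, the MR
#'   version is fitted.
#' @param covariates Additional covariate columns.
#' @return Tibble `method`, `beta` (interaction), `se`, `p`, `n`.
#' @export
sex_interaction <- function(pheno, outcome, exposure = "exposure",
                            sex = "child_sex", instrument = NULL,
                            covariates = character()) {
  z <- if (is.null(instrument)) NULL
       else if (is.character(instrument) && length(instrument) == 1) pheno[[instrument]]
       else as.numeric(instrument)
  dat <- tibble::tibble(.y = pheno[[outcome]], .x = pheno[[exposure]],
                        .s = pheno[[sex]])
  if (!is.null(z)) dat$.z <- z
  for (cl in covariates) dat[[cl]] <- pheno[[cl]]
  dat <- dat[complete.cases(dat), ]
  if (length(unique(dat$.s)) < 2) abort("sex column has a single level")
  s <- as.numeric(factor(dat$.s)) - 1
  W <- if (length(covariates)) as.matrix(dat[, covariates]) else NULL
  if (is.null(z)) {
    mf <- data.frame(.y = dat$.y, .x = dat$.x, s = s)
    if (!is.null(W)) mf <- cbind(mf, as.data.frame(W))
    fml <- stats::as.formula(paste(
      ".y ~ .x * s", if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
    ))
    fit <- lm(fml, data = mf)
    sm <- summary(fit)$coefficients
    row <- grep("^\\.x:s$", rownames(sm))
    tibble::tibble(method = "mv_interaction", beta = sm[row, 1],
                   se = sm[row, 2], p = sm[row, 4], n = nrow(dat))
  } else {
    A <- cbind(x = dat$.x, xs = dat$.x * s, `(Intercept)` = 1, s = s, W)
    Zf <- cbind(z = dat$.z, zs = dat$.z * s, `(Intercept)` = 1, s = s, W)
    fit <- iv_fit(dat$.y, A, Zf)
    se <- sqrt(fit$V[2, 2])
    tibble::tibble(method = "mr_interaction", beta = fit$coef[2], se = se,
                   p = 2 * pnorm(-abs(fit$coef[2] / se)), n = nrow(dat))
  }
}

#' Parental polygenic-score correlations
#'
#' Under random mating the maternal score (transmitted or not) is
#' uncorrelated with the paternal score; assortative mating induces a
#' positive correlation in both, which would bias family-based designs.
#' Reports Pearson correlations of the maternal non-transmitted and full
#' scores with the paternal score, with 95% CIs.
#'
#' @param nt_score Maternal non-transmitted-allele score.
#' @param full_score Maternal full (transmitted + non-transmitted) score.
#' @param paternal_score Paternal score (required).
#' @return Tibble `pair`, `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
parental_prs_correlation <- function(nt_score, full_score, paternal_score) {
  if (is.null(paternal_score) || !length(paternal_score)) {
    abort("paternal scores are required")
  }
  one <- function(x, label) {
    ok <- complete.cases(cbind(x, paternal_score))
    ct <- cor.test(x[ok], paternal_score[ok])
    tibble::tibble(pair = label, r = unname(ct$estimate),
                   ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                   p = ct$p.value, n = sum(ok))
  }
  dplyr::bind_rows(
    one(nt_score, "nontransmitted_vs_paternal"),
    one(full_score, "full_vs_paternal")
  )
}
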