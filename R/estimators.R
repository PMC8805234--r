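# Fast OLS via QR, returning coefficients and classical SEs. X must already
# contain an intercept column if one is wanted.
fast_ols <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  r <- fit$residuals
  df <- length(y) - fit$rank
  sigma2 <- sum(r^2) / df
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  se <- sqrt(diag(XtX_inv) * sigma2)
  piv <- fit$qr$pivot
  se[piv] <- se
  list(coef = fit$coefficients, se = se, sigma2 = sigma2,
       residuals = r, rank = fit$rank, df = df)
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    abort(paste0("collinear covariates: ", paste(bad, collapse = ", ")))
  }
  invisible(X)
}

model_matrix_from <- function(data, cols) {
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, cols, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Confounder-adjusted multivariable regression (models one to three)
#'
#' Ordinary least squares of a standardised outcome on the standardised
#' exposure plus a nested covariate set: model one adjusts for maternal age,
#' offspring age and offspring sex; model two additionally for the measured
#' confounders; model three additionally for the paternal exposure analogue
#' (the fully adjusted model). All three models are fitted on the identical
#' complete-case sample: rows with missing data in *any* column used by any
#' of the three models are excluded, so estimates are comparable across
#' models.
#'
#' @param pheno Phenotype tibble (see [generate_phenotypes()] for the
#'   default column layout).
#' @param outcome Outcome column name.
#' @param model `"one"`, `"two"` or `"three"`.
#' @param exposure Exposure column name.
#' @param model_covariates Named list of covariate vectors for the three
#'   models; defaults match the simulated phenotype table.
#' @param extra_covariates Additional columns appended to every model (e.g.
#'   genetic PCs, gestational age).
#' @param robust Use heteroskedasticity-robust (HC1) standard errors.
#' @return One-row estimate tibble (`method`, `beta`, `se`, `n`, CI, `p`).
#' @export
mv_regress <- function(pheno, outcome, model = c("one", "two", "three"),
                       exposure = "exposure",
                       model_covariates = list(
                         one = c("mother_age", "child_age", "child_sex"),
                         two = c("mother_age", "child_age", "child_sex",
                                 "conf1", "conf2"),
                         three = c("mother_age", "child_age", "child_sex",
                                   "conf1", "conf2", "father_exposure")
                       ),
                       extra_covariates = character(),
                       robust = FALSE) {
  model <- match.arg(model)
  all_cols <- unique(c(outcome, exposure, unlist(model_covariates),
                       extra_covariates))
  missing_cols <- setdiff(all_cols, names(pheno))
  if (length(missing_cols)) {
    abort(paste0("columns not in phenotype table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  cc <- pheno[complete.cases(pheno[, all_cols]), all_cols, drop = FALSE]
  if (nrow(cc) == 0) abort("empty complete-case sample")
  covs <- unique(c(model_covariates[[model]], extra_covariates))
  X <- model_matrix_from(cc, c(exposure, covs))
  check_full_rank(X)
  fml <- stats::as.formula(paste(
    sprintf("`%s` ~ `%s`", outcome, exposure),
    if (length(covs)) paste("+", paste0("`", covs, "`", collapse = " + ")) else ""
  ))
  fit <- lm(fml, data = cc)
  beta <- unname(coef(fit)[2])
  se <- if (robust) {
    sqrt(diag(sandwich::vcovHC(fit, type = "HC1"))[2])
  } else {
    sqrt(diag(stats::vcov(fit))[2])
  }
  if (!is.finite(se)) se <- 0
  estimate_record(paste0("mv", match(model, c("one", "two", "three"))),
                  outcome = outcome, beta = beta, se = unname(se), n = nrow(cc))
}

#' First-stage instrument strength diagnostics
#'
#' Partial R-squared of the instrument(s) for the exposure after
#' residualising both on the covariates, and the corresponding F-statistic
#' \eqn{F = R^2 (n - k_c - k - 1) / ((1 - R^2) k)} for k instruments and
#' k_c covariates. A perfectly predictive instrument returns `f = Inf`.
#'
#' @param exposure Numeric vector.
#' @param instrument Numeric vector or matrix (one column per instrument).
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @return List with `r2` and `f`.
#' @export
first_stage_diagnostics <- function(exposure, instrument, covariates = NULL) {
  Z <- as.matrix(instrument)
  n <- length(exposure)
  k <- ncol(Z)
  kc <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    W <- cbind(1, as.matrix(covariates))
    kc <- ncol(W) - 1L
    exposure <- stats::lm.fit(W, exposure)$residuals
    Z <- stats::lm.fit(W, Z)$residuals
    Z <- as.matrix(Z)
  }
  if (n <= kc + k + 1) abort("too few observations for first-stage diagnostics")
  fit <- stats::lm.fit(cbind(1, Z), exposure)
  tss <- sum((exposure - mean(exposure))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  r2 <- min(max(r2, 0), 1)
  f <- if (r2 >= 1) Inf else r2 * (n - kc - k - 1) / ((1 - r2) * k)
  list(r2 = r2, f = f)
}

#' One-sample two-stage least squares
#'
#' Instruments the exposure with a polygenic score (or any instrument set),
#' including the covariates identically in both stages, and reports the IV
#' point estimate with its asymptotic standard error plus first-stage
#' partial R-squared and F. With a single instrument and no covariates this
#' reproduces the Wald ratio exactly.
#'
#' @param pheno Phenotype tibble.
#' @param outcome,exposure Column names.
#' @param instrument Column name in `pheno` or a numeric vector aligned to
#'   its rows.
#' @param covariates Covariate column names (e.g. 20 genetic PCs).
#' @param robust Heteroskedasticity-robust SEs.
#' @param f_floor First-stage F below this triggers a weak-instrument
#'   warning (never an error).
#' @return One-row estimate tibble with `first_stage_r2`, `first_stage_f`.
#' @export
tsls <- function(pheno, outcome, instrument, exposure = "exposure",
                 covariates = character(), robust = FALSE, f_floor = 10) {
  z <- if (is.character(instrument) && length(instrument) == 1) {
    pheno[[instrument]]
  } else {
    as.numeric(instrument)
  }
  if (length(z) != nrow(pheno)) abort("instrument length does not match data")
  dat <- tibble::tibble(
    .y = pheno[[outcome]], .x = pheno[[exposure]], .z = z
  )
  for (cl in covariates) dat[[cl]] <- pheno[[cl]]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n == 0) abort("empty complete-case sample")
  if (sd(dat$.z) == 0) abort("instrument is constant")

  W <- if (length(covariates)) as.matrix(dat[, covariates, drop = FALSE]) else NULL
  A <- cbind(x = dat$.x, `(Intercept)` = 1, W)       # regressors
  Zf <- cbind(z = dat$.z, `(Intercept)` = 1, W)      # instruments
  check_full_rank(Zf)
  # fitted regressors under projection on the instrument space
  Ahat <- Zf %*% solve(crossprod(Zf), crossprod(Zf, A))
  b <- solve(crossprod(Ahat, A), crossprod(Ahat, dat$.y))
  resid <- dat$.y - A %*% b
  bread <- solve(crossprod(Ahat))
  if (robust) {
    meat <- crossprod(Ahat * as.numeric(resid))
    V <- bread %*% meat %*% bread
  } else {
    sigma2 <- sum(resid^2) / (n - ncol(A))
    V <- sigma2 * bread
  }
  fs <- first_stage_diagnostics(dat$.x, dat$.z, W)
  if (is.finite(fs$f) && fs$f < f_floor) {
    warn(sprintf("weak instrument: first-stage F = %.2f < %g", fs$f, f_floor))
  }
  estimate_record("tsls", outcome = outcome, beta = b[1],
                  se = sqrt(V[1, 1]), n = n,
                  first_stage_r2 = fs$r2, first_stage_f = fs$f)
}

#' Wald/ratio estimator with Taylor-series standard error
#'
#' The causal effect is the instrument-outcome coefficient divided by the
#' instrument-exposure coefficient, \eqn{\beta = \beta_{ZY}/\beta_{ZX}}.
#' The first-order Taylor (delta-method) SE is
#' \deqn{\sqrt{se_{ZY}^2/\beta_{ZX}^2 +
#'   \beta_{ZY}^2 se_{ZX}^2/\beta_{ZX}^4};}
#' the second-order form adds the cross term
#' \eqn{se_{ZY}^2 se_{ZX}^2/\beta_{ZX}^4} inside the root.
#'
#' @param beta_zy,se_zy Instrument-outcome coefficient and SE.
#' @param beta_zx,se_zx Instrument-exposure coefficient and SE.
#' @param n Sample size (annotation only).
#' @param order `"first"` (default) or `"second"`.
#' @param outcome Optional outcome label.
#' @return One-row estimate tibble with `method = "ratio"`.
#' @export
ratio_estimate <- function(beta_zy, se_zy, beta_zx, se_zx, n = NA,
                           order = c("first", "second"),
                           outcome = NA_character_) {
  order <- match.arg(order)
  if (any(c(se_zy, se_zx) <= 0)) abort("standard errors must be positive")
  if (beta_zx == 0) abort("undefined ratio: beta_zx is zero")
  beta <- beta_zy / beta_zx
  v <- se_zy^2 / beta_zx^2 + beta_zy^2 * se_zx^2 / beta_zx^4
  if (order == "second") v <- v + se_zy^2 * se_zx^2 / beta_zx^4
  estimate_record("ratio", outcome = outcome, beta = beta, se = sqrt(v),
                  n = ifelse(is.na(n), NA_integer_, n))
}

#' Per-SNP Wald ratios
#'
#' For each SNP, regresses outcome and exposure on the dosage (plus
#' covariates) in the same sample and forms the Wald ratio with a
#' first-order Taylor SE. Feeds the between-SNP heterogeneity (Cochran's Q)
#' and MR-Egger diagnostics. Monomorphic SNPs are dropped with a warning.
#'
#' @param pheno Phenotype tibble.
#' @param outcome,exposure Column names.
#' @param dosages Dosage matrix aligned to `pheno` rows (SNP ids as column
#'   names).
#' @param weights Optional harmonised weight table; if given, a `weight`
#'   column is joined onto the output (used by effect-size stratification).
#' @param covariates Covariate column names included in both regressions.
#' @return Tibble with one row per SNP: `id`, `beta_zx`, `se_zx`, `beta_zy`,
#'   `se_zy`, `beta`, `se`, `n` (+ `weight`).
#' @export
per_snp_wald <- function(pheno, outcome, dosages, weights = NULL,
                         exposure = "exposure", covariates = character()) {
  stopifnot(is.matrix(dosages), nrow(dosages) == nrow(pheno))
  keep_cols <- c(outcome, exposure, covariates)
  base_ok <- complete.cases(pheno[, keep_cols])
  mono <- apply(dosages[base_ok, , drop = FALSE], 2,
                function(g) sd(g, na.rm = TRUE) %in% c(0, NA) || all(is.na(g)))
  if (any(mono)) {
    warn(sprintf("dropping %d monomorphic SNP(s)", sum(mono)))
    dosages <- dosages[, !mono, drop = FALSE]
  }
  ids <- colnames(dosages) %||% paste0("snp", seq_len(ncol(dosages)))
  rows <- purrr::map(seq_len(ncol(dosages)), function(j) {
    ok <- base_ok & !is.na(dosages[, j])
    g <- dosages[ok, j]
    X <- model_matrix_from(pheno[ok, , drop = FALSE], covariates)
    X <- cbind(g = g, X)
    fx <- fast_ols(pheno[[exposure]][ok], X)
    fy <- fast_ols(pheno[[outcome]][ok], X)
    tibble::tibble(
      id = ids[j],
      beta_zx = unname(fx$coef[1]), se_zx = fx$se[1],
      beta_zy = unname(fy$coef[1]), se_zy = fy$se[1],
      n = sum(ok)
    )
  })
  out <- dplyr::bind_rows(rows)
  ratio <- purrr::pmap(out[, c("beta_zy", "se_zy", "beta_zx", "se_zx")],
                       function(beta_zy, se_zy, beta_zx, se_zx) {
                         if (beta_zx == 0) return(c(NA_real_, NA_real_))
                         r <- ratio_estimate(beta_zy, se_zy, beta_zx, se_zx)
                         c(r$beta, r$se)
                       })
  out$beta <- vapply(ratio, `[`, numeric(1), 1)
  out$se <- vapply(ratio, `[`, numeric(1), 2)
  if (!is.null(weights)) {
    out <- dplyr::left_join(out, weights[, c("id", "weight")], by = "id")
  }
  out
}
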