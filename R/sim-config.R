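#' Configure a trio cohort simulation
#'
#' Builds the parameter set for [simulate_trios()]. The simulated world is a
#' cohort of mother-father-offspring trios genotyped at `n_snps` biallelic
#' SNPs. A maternal polygenic score drives a maternal exposure (think
#' pre-pregnancy BMI in SD units); offspring outcomes receive a maternal
#' causal effect plus, optionally, offspring and paternal direct genetic
#' effects, a shared familial confounder, assortative mating and block LD.
#' All phenotypes are internally standardised, so every effect parameter is
#' in SD-per-SD units.
#'
#' @param n_trios Number of families.
#' @param n_snps Number of SNPs in the causal panel.
#' @param allele_freq_range Length-2 numeric in (0, 1); effect-allele
#'   frequencies are drawn uniformly in this range (a zero-width range pins
#'   all frequencies to one value).
#' @param weight_dist Distribution of the true per-allele SNP effects on the
#'   exposure before rescaling: `"normal"` (default), `"uniform"`, or
#'   `"single"` (a point mass on one SNP, all others zero -- the single-SNP
#'   instrument panel).
#' @param alpha Proportion of exposure variance explained by the full
#'   (standardised) maternal polygenic score. Weights are rescaled so this
#'   holds by construction; `alpha = 0` gives an all-zero weight vector.
#' @param beta_m Named numeric vector of maternal causal effects on the
#'   offspring outcome(s), one entry per outcome label (SD outcome per SD
#'   exposure). Names become outcome column names `y_<label>`.
#' @param gamma_c Offspring direct genetic effect (SD outcome per SD of the
#'   offspring's own polygenic score).
#' @param gamma_p Paternal direct genetic effect (SD outcome per SD paternal
#'   polygenic score) -- genetic nurture through the father.
#' @param lambda_x,lambda_y Effect of the latent familial confounder on the
#'   exposure and on each outcome (SD per confounder SD).
#' @param rho_am Target spousal polygenic-score correlation in `[0, 1)`;
#'   achieved by rank-matching couples on noise-perturbed scores.
#' @param ld_block_size SNPs per LD block (1 = unlinked panel).
#' @param ld_within_r Pairwise haplotype correlation within an LD block.
#' @param missing_rate Completely-at-random missingness applied to phenotype
#'   and confounder columns.
#' @param beta_m_sex_diff Difference in the maternal effect between offspring
#'   sexes (male minus female), for sex-interaction sensitivity analyses.
#' @param pleiotropy Optional per-SNP direct effects of the *maternal
#'   genotype* on each outcome (horizontal pleiotropy that bypasses the
#'   exposure). Either `NULL`, a length-`n_snps` vector, or a function
#'   `function(weights)` returning such a vector (so injections can target,
#'   e.g., small-weight SNPs).
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical cohorts. `NULL` uses the current RNG state.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_trios = 200, n_snps = 20, seed = 1)
#' cohort <- simulate_trios(cfg)
#' @export
sim_config <- function(n_trios = 5000,
                       n_snps = 100,
                       allele_freq_range = c(0.05, 0.95),
                       weight_dist = c("normal", "uniform", "single"),
                       alpha = 0.05,
                       beta_m = c(bw = 0.1),
                       gamma_c = 0.2,
                       gamma_p = 0,
                       lambda_x = 0.5,
                       lambda_y = 0.5,
                       rho_am = 0,
                       ld_block_size = 1,
                       ld_within_r = 0,
                       missing_rate = 0,
                       beta_m_sex_diff = 0,
                       pleiotropy = NULL,
                       seed = NULL) {
  weight_dist <- match.arg(weight_dist)
  if (!is_count(n_trios) || n_trios < 1) abort("`n_trios` must be a positive integer")
  if (!is_count(n_snps) || n_snps < 1) abort("`n_snps` must be a positive integer")
  if (length(allele_freq_range) != 2 || any(!is.finite(allele_freq_range)) ||
      any(allele_freq_range <= 0) || any(allele_freq_range >= 1) ||
      diff(allele_freq_range) < 0) {
    abort("`allele_freq_range` must be an ordered pair within (0, 1)")
  }
  check_prob(alpha, "alpha")
  check_prob(rho_am, "rho_am", hi = 1 - 1e-9)
  check_prob(missing_rate, "missing_rate")
  check_prob(ld_within_r, "ld_within_r")
  if (!is_count(ld_block_size) || ld_block_size < 1) abort("`ld_block_size` must be >= 1")
  if (is.null(names(beta_m)) || any(!nzchar(names(beta_m)))) {
    names(beta_m) <- paste0("t", seq_along(beta_m))
  }
  if (alpha + lambda_x^2 > 1) {
    abort("negative exposure residual variance: alpha + lambda_x^2 exceeds 1")
  }
  if (!is.null(pleiotropy) && !is.function(pleiotropy) &&
      length(pleiotropy) != n_snps) {
    abort("`pleiotropy` must be NULL, a function of the weights, or length n_snps")
  }
  structure(
    list(
      n_trios = as.integer(n_trios), n_snps = as.integer(n_snps),
      allele_freq_range = allele_freq_range, weight_dist = weight_dist,
      alpha = alpha, beta_m = beta_m, gamma_c = gamma_c, gamma_p = gamma_p,
      lambda_x = lambda_x, lambda_y = lambda_y, rho_am = rho_am,
      ld_block_size = as.integer(ld_block_size), ld_within_r = ld_within_r,
      missing_rate = missing_rate, beta_m_sex_diff = beta_m_sex_diff,
      pleiotropy = pleiotropy,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_trios, " trios x ", x$n_snps, " SNPs\n", sep = "")
  cat("  alpha=", x$alpha, " beta_m=[", paste(names(x$beta_m), x$beta_m,
      sep = "=", collapse = ", "), "] gamma_c=", x$gamma_c,
      " gamma_p=", x$gamma_p, "\n", sep = "")
  cat("  lambda_x=", x$lambda_x, " lambda_y=", x$lambda_y,
      " rho_am=", x$rho_am, " ld=", x$ld_block_size, "x", x$ld_within_r,
      " missing=", x$missing_rate, "\n", sep = "")
  invisible(x)
}
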