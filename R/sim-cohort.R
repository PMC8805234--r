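#' Draw the SNP panel and true effect weights
#'
#' Samples per-SNP effect-allele frequencies uniformly within
#' `allele_freq_range` and true per-allele effects on the exposure from
#' `weight_dist`, then rescales the weights so that the maternal polygenic
#' score explains exactly `alpha` of the exposure variance under
#' Hardy-Weinberg dosage variance \eqn{2p(1-p)}. With `ld_block_size > 1`
#' SNPs are grouped into blocks that share a frequency and sit on the same
#' chromosome (blocks are unlinked across chromosomes).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `id`, `chrom`, `pos`, `ea`, `oa`, `freq`,
#'   `block`, `weight`.
#' @export
draw_snp_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_snps
  block <- ((seq_len(m) - 1L) %/% config$ld_block_size) + 1L
  fr <- config$allele_freq_range
  freq <- if (config$ld_block_size > 1L) {
    runif(max(block), fr[1], fr[2])[block]
  } else {
    runif(m, fr[1], fr[2])
  }
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, m, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1), character(1))
  w <- switch(config$weight_dist,
    normal  = rnorm(m),
    uniform = runif(m, -1, 1),
    single  = { v <- numeric(m); v[sample.int(m, 1)] <- 1; v }
  )
  v_raw <- sum(w^2 * 2 * freq * (1 - freq))
  w <- if (config$alpha == 0 || v_raw == 0) numeric(m) else w * sqrt(config$alpha / v_raw)
  pos_in_block <- stats::ave(seq_len(m), block, FUN = seq_along)
  tibble::tibble(
    id = sprintf("rs%05d", seq_len(m)),
    chrom = as.character(block),
    pos = 10000L + 1000L * as.integer(pos_in_block),
    ea = unname(ea), oa = unname(oa),
    freq = freq, block = block, weight = w
  )
}

# Draw n phased haplotype pairs for one parent set. Within an LD block each
# allele copies a per-haplotype block "driver" allele with probability
# sqrt(ld_within_r), giving pairwise haplotype correlation ld_within_r while
# preserving marginal frequencies.
draw_haplotypes <- function(n, snp_meta, config) {
  m <- nrow(snp_meta)
  one <- function() {
    if (config$ld_block_size == 1L || config$ld_within_r == 0) {
      matrix(rbinom(n * m, 1L, rep(snp_meta$freq, each = n)), n, m)
    } else {
      h <- matrix(0L, n, m)
      cpy <- sqrt(config$ld_within_r)
      for (b in unique(snp_meta$block)) {
        cols <- which(snp_meta$block == b)
        p <- snp_meta$freq[cols[1]]
        driver <- rbinom(n, 1L, p)
        for (j in cols) {
          take <- rbinom(n, 1L, cpy)
          h[, j] <- take * driver + (1L - take) * rbinom(n, 1L, p)
        }
      }
      h
    }
  }
  list(h1 = one(), h2 = one())
}

#' Simulate parental haplotypes, with optional assortative mating
#'
#' Mothers and fathers are drawn independently as phased haplotype pairs.
#' When `rho_am > 0`, couples are formed by rank-matching: each parent's
#' standardised polygenic score is perturbed with Gaussian noise of variance
#' \eqn{(1-\rho)/\rho} (the closed-form attenuation that makes the matched
#' spousal score correlation equal \eqn{\rho}), both sexes are sorted on the
#' noisy score, and ranks are paired. The achieved correlation is recorded;
#' falling short of the target by more than 0.05 is an error.
#'
#' @param config A [sim_config()].
#' @param snp_meta Panel from [draw_snp_panel()].
#' @return List with matrices `mat_h1`, `mat_h2`, `pat_h1`, `pat_h2`
#'   (`n_trios` x `n_snps`) and the achieved spousal correlation
#'   `achieved_rho` (`NA` under random mating).
#' @export
simulate_parents <- function(config, snp_meta) {
  stopifnot(inherits(config, "sim_config"), nrow(snp_meta) == config$n_snps)
  n <- config$n_trios
  mo <- draw_haplotypes(n, snp_meta, config)
  fa <- draw_haplotypes(n, snp_meta, config)
  achieved <- NA_real_
  if (config$rho_am > 0) {
    w <- snp_meta$weight
    prs_m <- as.numeric((mo$h1 + mo$h2) %*% w)
    prs_f <- as.numeric((fa$h1 + fa$h2) %*% w)
    if (sd(prs_m) == 0 || sd(prs_f) == 0) {
      abort("rho_am unattainable: polygenic score has zero variance")
    }
    tau <- sqrt((1 - config$rho_am) / config$rho_am)
    om <- order(std(prs_m) + tau * rnorm(n))
    of <- order(std(prs_f) + tau * rnorm(n))
    mo$h1 <- mo$h1[om, , drop = FALSE]; mo$h2 <- mo$h2[om, , drop = FALSE]
    fa$h1 <- fa$h1[of, , drop = FALSE]; fa$h2 <- fa$h2[of, , drop = FALSE]
    achieved <- cor(prs_m[om], prs_f[of])
    if (achieved < config$rho_am - 0.05) {
      abort(sprintf(
        "assortative-mating target rho_am = %.3f not reached (achieved %.3f)",
        config$rho_am, achieved
      ))
    }
  }
  list(mat_h1 = mo$h1, mat_h2 = mo$h2, pat_h1 = fa$h1, pat_h2 = fa$h2,
       achieved_rho = achieved)
}

#' Mendelian transmission from phased parents to offspring
#'
#' For each meiosis one of the two parental haplotypes is chosen uniformly
#' per LD block (whole blocks are transmitted; with unlinked SNPs this is an
#' independent uniform choice per SNP). Returns the offspring genotype along
#' with the exact maternal transmitted / non-transmitted decomposition, which
#' satisfies `mat_transmitted + mat_nontransmitted == maternal genotype`
#' identically.
#'
#' @param parents Output of [simulate_parents()].
#' @param snp_meta Panel from [draw_snp_panel()].
#' @return List with matrices `child_g`, `mat_transmitted`,
#'   `mat_nontransmitted`, `pat_transmitted`.
#' @export
transmit <- function(parents, snp_meta) {
  n <- nrow(parents$mat_h1)
  blocks <- snp_meta$block
  pick <- function(h1, h2) {
    choice <- matrix(rbinom(n * max(blocks), 1L, 0.5), n, max(blocks))[, blocks, drop = FALSE]
    choice * h1 + (1L - choice) * h2
  }
  mat_t <- pick(parents$mat_h1, parents$mat_h2)
  pat_t <- pick(parents$pat_h1, parents$pat_h2)
  list(
    child_g = mat_t + pat_t,
    mat_transmitted = mat_t,
    mat_nontransmitted = (parents$mat_h1 + parents$mat_h2) - mat_t,
    pat_transmitted = pat_t
  )
}

# Resolve the pleiotropy spec (NULL / vector / function of weights) to a
# per-SNP vector of direct maternal-genotype effects on the outcome.
resolve_pleiotropy <- function(config, weights) {
  pl <- config$pleiotropy
  if (is.null(pl)) return(numeric(length(weights)))
  if (is.function(pl)) pl <- pl(weights)
  if (length(pl) != length(weights)) abort("pleiotropy vector has wrong length")
  pl
}

#' Generate phenotypes for a simulated trio cohort
#'
#' The latent familial confounder C is standard normal per family. The
#' maternal exposure is
#' \deqn{X = \sqrt{\alpha}\,PRS_m + \lambda_x C + e_x,}
#' standardised after generation, with residual variance chosen so
#' \eqn{Var(X) = 1}; the standardised maternal score therefore explains
#' \eqn{\alpha} of the exposure variance. Each outcome is
#' \deqn{Y = \beta_m X + \gamma_c PRS_c + \gamma_p PRS_p + \lambda_y C +
#'   \delta'G_m + e_y,}
#' standardised after generation (\eqn{\delta'G_m} is the optional
#' horizontal-pleiotropy term acting through the maternal genotype). A
#' paternal exposure analogue (the "paternal BMI" confounder-model covariate)
#' is built the same way as X from the paternal score. Observed confounder
#' columns are two noisy proxies of C; missingness is applied completely at
#' random at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @param cohort List carrying `snp_meta` plus the haplotype/transmission
#'   matrices (as assembled by [simulate_trios()]).
#' @return List of two tibbles: `phenotypes` (one row per family:
#'   `family_id`, `mother_age`, `child_sex`, `child_age`, `conf1`, `conf2`,
#'   `exposure`, `father_exposure`, one `y_<label>` per outcome) and `truth`
#'   (realised standardised scores and the latent confounder).
#' @export
generate_phenotypes <- function(config, cohort) {
  n <- config$n_trios
  w <- cohort$snp_meta$weight
  g_mat <- cohort$mat_h1 + cohort$mat_h2
  prs_mat <- std(as.numeric(g_mat %*% w))
  prs_pat <- std(as.numeric((cohort$pat_h1 + cohort$pat_h2) %*% w))
  prs_child <- std(as.numeric(cohort$child_g %*% w))
  prs_nt <- std(as.numeric(cohort$mat_nontransmitted %*% w))
  prs_t <- std(as.numeric(cohort$mat_transmitted %*% w))

  conf <- rnorm(n)
  a <- sqrt(config$alpha)
  res_x <- 1 - config$alpha - config$lambda_x^2
  if (res_x < 0) abort("negative exposure residual variance")
  exposure <- std(a * prs_mat + config$lambda_x * conf + rnorm(n, sd = sqrt(res_x)))
  father_exposure <- std(a * prs_pat + config$lambda_x * conf + rnorm(n, sd = sqrt(res_x)))

  sex <- rbinom(n, 1L, 0.5)
  mother_age <- pmin(pmax(round(rnorm(n, 29, 4.5)), 18), 45)
  child_age <- rnorm(n, 10, 0.6)
  conf1 <- sqrt(0.7) * conf + sqrt(0.3) * rnorm(n)
  conf2 <- sqrt(0.5) * conf + sqrt(0.5) * rnorm(n)

  delta <- resolve_pleiotropy(config, w)
  pleio <- if (any(delta != 0)) {
    pt <- as.numeric(g_mat %*% delta)
    pt - mean(pt)
  } else 0

  outcomes <- purrr::imap(config$beta_m, function(b, label) {
    sys <- b * exposure +
      (sex - 0.5) * config$beta_m_sex_diff * exposure +
      config$gamma_c * prs_child + config$gamma_p * prs_pat +
      config$lambda_y * conf + pleio
    res_y <- 1 - var(sys)
    if (res_y <= 0) {
      abort(sprintf("negative outcome residual variance for '%s'", label))
    }
    std(sys + rnorm(n, sd = sqrt(res_y)))
  })
  names(outcomes) <- paste0("y_", names(config$beta_m))

  pheno <- tibble::tibble(
    family_id = sprintf("F%05d", seq_len(n)),
    mother_age = mother_age, child_sex = sex, child_age = child_age,
    conf1 = conf1, conf2 = conf2,
    exposure = exposure, father_exposure = father_exposure,
    !!!outcomes
  )
  if (config$missing_rate > 0) {
    miss_cols <- c("exposure", "father_exposure", "conf1", "conf2", names(outcomes))
    for (cl in miss_cols) {
      hit <- runif(n) < config$missing_rate
      pheno[[cl]][hit] <- NA_real_
    }
  }
  truth <- tibble::tibble(
    family_id = pheno$family_id, confounder = conf,
    prs_mat = prs_mat, prs_pat = prs_pat, prs_child = prs_child,
    prs_nt = prs_nt, prs_t = prs_t
  )
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a full mother-father-offspring cohort
#'
#' Runs [draw_snp_panel()], [simulate_parents()], [transmit()] and
#' [generate_phenotypes()] under the configuration's seed and assembles the
#' result into a `trio_cohort` object.
#'
#' @param config A [sim_config()].
#' @return A `trio_cohort`: list with `config`, `snp_meta`, haplotype
#'   matrices (`mat_h1`, `mat_h2`, `pat_h1`, `pat_h2`), `child_g`,
#'   `mat_transmitted`, `mat_nontransmitted`, `pat_transmitted`,
#'   `phenotypes`, `truth`, `achieved_rho`. All genotype matrices have
#'   family-id rownames and SNP-id colnames.
#' @export
simulate_trios <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  snp_meta <- draw_snp_panel(config)
  parents <- simulate_parents(config, snp_meta)
  tx <- transmit(parents, snp_meta)
  cohort <- c(list(snp_meta = snp_meta),
              parents[c("mat_h1", "mat_h2", "pat_h1", "pat_h2")], tx)
  ph <- generate_phenotypes(config, cohort)
  ids <- ph$phenotypes$family_id
  for (nm in c("mat_h1", "mat_h2", "pat_h1", "pat_h2", "child_g",
               "mat_transmitted", "mat_nontransmitted", "pat_transmitted")) {
    dimnames(cohort[[nm]]) <- list(ids, snp_meta$id)
  }
  structure(
    c(list(config = config), cohort,
      list(phenotypes = ph$phenotypes, truth = ph$truth,
           achieved_rho = parents$achieved_rho)),
    class = "trio_cohort"
  )
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("<trio_cohort> ", nrow(x$phenotypes), " families x ",
      nrow(x$snp_meta), " SNPs\n", sep = "")
  cat("  outcomes:", paste(grep("^y_", names(x$phenotypes), value = TRUE),
                           collapse = ", "), "\n")
  if (!is.na(x$achieved_rho)) {
    cat("  achieved spousal PRS correlation:", round(x$achieved_rho, 3), "\n")
  }
  invisible(x)
}
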