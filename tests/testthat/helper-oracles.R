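# Independent oracles and small fixture builders used across the suite.

# Path-tracing oracle for the crude (model-one) regression slope of the
# standardised outcome on the standardised exposure, under random mating:
# slope = cov(X, Y) with both variables at unit variance.
#   X = sqrt(alpha) PRS_m + lambda_x C + e
#   Y = beta_m X + gamma_c PRS_c + gamma_p PRS_p + lambda_y C + e'
# cov(PRS_m, PRS_c) = 1/2, cov(X, PRS_p) = 0, cov(X, C) = lambda_x.
oracle_mv1_slope <- function(alpha, beta_m, gamma_c, lambda_x, lambda_y) {
  beta_m + 0.5 * sqrt(alpha) * gamma_c + lambda_x * lambda_y
}

# Large-n limit of MR with the FULL maternal PRS as instrument (no
# offspring adjustment, random mating): cov(Z,Y)/cov(Z,X) with Z = PRS_m.
oracle_full_prs_mr <- function(alpha, beta_m, gamma_c) {
  beta_m + gamma_c / (2 * sqrt(alpha))
}

# Brute-force duo resolution by enumerating every Mendelian transmission
# consistent with the observed genotypes. Deliberately written as explicit
# enumeration over (maternal transmitted, paternal transmitted) pairs.
oracle_resolve_duo <- function(m, ch, f = NA) {
  feasible <- c()
  for (tm in 0:1) {
    for (tp in 0:1) {
      ok_m <- if (m == 0) tm == 0 else if (m == 2) tm == 1 else TRUE
      ok_f <- if (is.na(f)) TRUE else if (f == 0) tp == 0 else if (f == 2) tp == 1 else TRUE
      if (ok_m && ok_f && tm + tp == ch) feasible <- c(feasible, tm)
    }
  }
  feasible_nf <- c()
  for (tm in 0:1) {
    for (tp in 0:1) {
      ok_m <- if (m == 0) tm == 0 else if (m == 2) tm == 1 else TRUE
      if (ok_m && tm + tp == ch) feasible_nf <- c(feasible_nf, tm)
    }
  }
  feasible <- unique(feasible); feasible_nf <- unique(feasible_nf)
  if (length(feasible) == 0) {
    list(transmitted = NA_real_, status = "mendel_error")
  } else if (length(feasible_nf) == 1) {
    list(transmitted = feasible_nf, status = "forced")
  } else if (length(feasible) == 1) {
    list(transmitted = feasible, status = "father_resolved")
  } else {
    list(transmitted = 0.5, status = "ambiguous_expected")
  }
}

# Naive direct-definition clumping oracle: repeatedly scan for the
# lowest-p (then lowest-id) unprocessed candidate and accept it unless it is
# in LD above r2_max with an already-accepted SNP within the window.
# Correlations are recomputed from sums each time; no code shared with the
# package implementation.
oracle_clump <- function(stats, ref, p_max, r2_max, window_kb) {
  stats <- as.data.frame(stats)
  stats <- stats[stats$p <= p_max, , drop = FALSE]
  done <- rep(FALSE, nrow(stats))
  accepted <- character(0)
  cor2 <- function(a, b) {
    n <- length(a)
    sa <- sum(a); sb <- sum(b)
    num <- n * sum(a * b) - sa * sb
    den <- sqrt(n * sum(a^2) - sa^2) * sqrt(n * sum(b^2) - sb^2)
    if (den == 0) return(NA_real_)
    (num / den)^2
  }
  while (any(!done)) {
    cand <- which(!done)
    cand <- cand[order(stats$p[cand], stats$id[cand])][1]
    ok <- TRUE
    for (acc in accepted) {
      k <- which(stats$id == acc)
      if (stats$chrom[cand] == stats$chrom[k] &&
          abs(stats$pos[cand] - stats$pos[k]) <= window_kb * 1000) {
        r2 <- cor2(ref[, stats$id[cand]], ref[, stats$id[k]])
        if (!is.na(r2) && r2 > r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) accepted <- c(accepted, stats$id[cand])
    done[cand] <- TRUE
  }
  accepted
}

# Small single-instrument IV fixture with known structure.
make_iv_data <- function(n = 500, beta = 0.3, conf = 0.4, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  u <- rnorm(n)
  x <- 0.5 * z + conf * u + rnorm(n)
  y <- beta * x + conf * u + rnorm(n)
  w1 <- rnorm(n); w2 <- 0.3 * x + rnorm(n)
  tibble::tibble(z = z, x = x, y = y, w1 = w1, w2 = w2)
}

# Small cohort shorthand for tests.
quick_cohort <- function(n_trios = 500, n_snps = 50, seed = 1, ...) {
  simulate_trios(sim_config(n_trios = n_trios, n_snps = n_snps, seed = seed, ...))
}
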