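test_that("difference test internals are mutually consistent", {
  co <- simulate_trios(sim_config(n_trios = 1200, n_snps = 40, alpha = 0.1,
                                  seed = 30))
  ph <- co$phenotypes
  ph$nt <- co$truth$prs_nt
  dt <- suppressWarnings(
    mv_mr_difference_test(ph, "y_bw", "nt", n_boot = 500, seed = 9)
  )
  expect_equal(dt$p, 2 * pnorm(-abs(dt$z)))
  expect_equal(dt$z, (dt$beta_mv - dt$beta_mr) /
                 sqrt(dt$se_mv^2 + dt$se_mr^2 - 2 * dt$cov_boot))
  # point estimates agree with the standalone estimators
  expect_equal(dt$beta_mv, mv_regress(ph, "y_bw", "three")$beta)
  expect_equal(dt$beta_mr, tsls(ph, "y_bw", "nt")$beta)
  # the bootstrap is reproducible under its recorded seed
  dt2 <- mv_mr_difference_test(ph, "y_bw", "nt", n_boot = 500, seed = 9)
  expect_equal(dt$cov_boot, dt2$cov_boot)
  expect_error(mv_mr_difference_test(ph, "y_bw", "nt", n_boot = 100),
               "at least 500")
  expect_s3_class(tidy(dt), "tbl_df")
})

test_that("MR-Egger recovers an exact linear fixture", {
  tbl <- tibble::tibble(
    beta_zx = c(0.1, 0.2, 0.3), se_zx = 0.01,
    beta_zy = 0.01 + 0.1 * c(0.1, 0.2, 0.3), se_zy = 0.02
  )
  e <- mr_egger(tbl)
  expect_equal(e$intercept, 0.01, tolerance = 1e-12)
  expect_equal(e$slope, 0.1, tolerance = 1e-12)
  # orientation: flipping the sign of a SNP's pair changes nothing
  tbl2 <- tbl
  tbl2$beta_zx[2] <- -tbl2$beta_zx[2]
  tbl2$beta_zy[2] <- -tbl2$beta_zy[2]
  e2 <- mr_egger(tbl2)
  expect_equal(e2$intercept, e$intercept)
  expect_equal(e2$slope, e$slope)
  expect_error(mr_egger(tbl[1:2, ]), "at least 3")
  same <- tibble::tibble(beta_zx = rep(0.2, 4), se_zx = 0.01,
                         beta_zy = rnorm(4), se_zy = 0.02)
  expect_error(mr_egger(same), "identification")
})

test_that("balanced pleiotropy leaves the MR-Egger slope consistent", {
  set.seed(61)
  k <- 50
  bzx_true <- runif(k, 0.05, 0.2)
  slopes <- replicate(60, {
    bzx <- bzx_true + rnorm(k, sd = 0.002)
    bzy <- 0.1 * bzx_true + rnorm(k, sd = 0.02) + rnorm(k, sd = 0.01)
    mr_egger(tibble::tibble(beta_zx = bzx, se_zx = 0.002,
                            beta_zy = bzy, se_zy = sqrt(0.02^2 + 0.01^2)))$slope
  })
  expect_equal(mean(slopes), 0.1, tolerance = 0.15)
})

test_that("instrument validity screen mirrors the correlation conventions", {
  set.seed(37)
  d <- tibble::tibble(
    prs = rnorm(500),
    indep = rnorm(500),
    flat = rep(1, 500)
  )
  d$linked <- 0.5 * d$prs + rnorm(500)
  scr <- instrument_validity_screen(d, "prs")
  expect_setequal(scr$factor, c("indep", "flat", "linked"))
  expect_identical(scr$note[scr$factor == "flat"], "constant column")
  expect_identical(scr$stars[scr$factor == "linked"], "***")
  expect_gt(scr$p[scr$factor == "indep"], 1e-3)
  d$self <- d$prs
  scr2 <- instrument_validity_screen(d, "prs", "self")
  expect_equal(scr2$r, 1)
})

test_that("a simulated pleiotropic confounder link is detected by the screen", {
  co <- simulate_trios(sim_config(n_trios = 3000, n_snps = 40, seed = 44))
  d <- tibble::tibble(
    prs = co$truth$prs_nt,
    conf = co$phenotypes$conf1,
    linked = 0.15 * co$truth$prs_nt + rnorm(3000)
  )
  scr <- instrument_validity_screen(d, "prs")
  expect_lt(scr$p[scr$factor == "linked"], 1e-5)
  expect_gt(scr$p[scr$factor == "conf"], 0.001)
})

test_that("effect-size-stratified MR is null for homogeneous panels", {
  co <- simulate_trios(sim_config(n_trios = 4000, n_snps = 60, alpha = 0.2,
                                  weight_dist = "uniform", seed = 47))
  wt <- co$snp_meta[, c("id", "weight")]
  wt$flip <- FALSE
  st <- suppressWarnings(
    effect_size_stratified_mr(co$phenotypes, co$mat_nontransmitted, wt, "y_bw",
                              n_bins = 3)
  )
  expect_equal(nrow(st$per_bin), 3)
  expect_true(dplyr::between(0, st$trend$slope - 2.6 * st$trend$se,
                             st$trend$slope + 2.6 * st$trend$se))
  expect_error(
    effect_size_stratified_mr(co$phenotypes, co$mat_nontransmitted, wt, "y_bw",
                              n_bins = 1),
    "at least 2"
  )
})

test_that("identical sub-scores give identical per-bin estimates", {
  co <- quick_cohort(n_trios = 500, n_snps = 10, seed = 50)
  dos <- co$mat_nontransmitted
  dos2 <- cbind(dos, dos)
  colnames(dos2) <- c(colnames(dos), paste0(colnames(dos), "b"))
  wt <- tibble::tibble(id = colnames(dos2),
                       weight = rep(co$snp_meta$weight, 2), flip = FALSE)
  st <- suppressWarnings(
    effect_size_stratified_mr(co$phenotypes, dos2, wt, "y_bw", n_bins = 2)
  )
  expect_equal(st$per_bin$beta[1], st$per_bin$beta[2], tolerance = 0.2)
})

test_that("sex-interaction test behaves under null and signal", {
  co <- simulate_trios(sim_config(n_trios = 6000, n_snps = 30,
                                  beta_m = c(bw = 0.2),
                                  beta_m_sex_diff = 0.4, seed = 52))
  ph <- co$phenotypes
  got <- sex_interaction(ph, "y_bw")
  expect_identical(got$method, "mv_interaction")
  expect_equal(got$beta, 0.4, tolerance = 0.3)
  mr <- sex_interaction(ph, "y_bw", instrument = co$truth$prs_nt)
  expect_identical(mr$method, "mr_interaction")
  expect_true(is.finite(mr$se))
  ph$child_sex <- 1
  expect_error(sex_interaction(ph, "y_bw"), "single level")
})

test_that("sex-interaction p-values are calibrated under the null", {
  set.seed(58)
  ps <- replicate(150, {
    n <- 400
    s <- rbinom(n, 1, 0.5)
    x <- rnorm(n)
    y <- 0.2 * x + rnorm(n)
    d <- tibble::tibble(exposure = x, y_t = y, child_sex = s)
    sex_interaction(d, "y_t")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("parental score correlations separate random from assortative mating", {
  co <- simulate_trios(sim_config(n_trios = 4000, n_snps = 80, rho_am = 0.2,
                                  seed = 63))
  tr <- co$truth
  tab <- parental_prs_correlation(tr$prs_nt, tr$prs_mat, tr$prs_pat)
  expect_equal(tab$r[tab$pair == "full_vs_paternal"], 0.2, tolerance = 0.3)
  expect_gt(tab$r[tab$pair == "nontransmitted_vs_paternal"], 0.05)
  co0 <- simulate_trios(sim_config(n_trios = 4000, n_snps = 80, seed = 64))
  tab0 <- parental_prs_correlation(co0$truth$prs_nt, co0$truth$prs_mat,
                                   co0$truth$prs_pat)
  expect_true(all(tab0$ci_low < 0 & tab0$ci_high > 0))
  ident <- parental_prs_correlation(tr$prs_pat, tr$prs_pat, tr$prs_pat)
  expect_equal(ident$r, c(1, 1))
  expect_error(parental_prs_correlation(tr$prs_nt, tr$prs_mat, NULL),
               "paternal")
})
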