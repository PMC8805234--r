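make_meta <- function(ea, oa, freq = 0.2) {
  tibble::tibble(id = sprintf("rs%03d", seq_along(ea)), chrom = "1",
                 pos = seq_along(ea) * 1000L, ea = ea, oa = oa, freq = freq)
}

test_that("harmonisation keeps, flips and drops SNPs by the allele rules", {
  meta <- make_meta(ea = c("A", "G", "A", "A", "C"),
                    oa = c("G", "A", "T", "C", "G"),
                    freq = c(0.2, 0.2, 0.5, 0.2, 0.2))
  w <- tibble::tibble(
    id = meta$id,
    ea = c("A", "A", "A", "T", "G"),   # match / swapped / palindromic / strand / strand-swap
    oa = c("G", "G", "T", "G", "C"),
    weight = c(0.02, 0.02, 0.01, 0.03, 0.04)
  )
  h <- harmonize(w, meta)
  expect_setequal(h$id, c("rs001", "rs002", "rs004", "rs005"))
  expect_identical(attr(h, "dropped")$reason, "palindromic_ambiguous")
  expect_false(h$flip[h$id == "rs001"])
  expect_true(h$flip[h$id == "rs002"])
  expect_false(h$flip[h$id == "rs004"])  # strand flip, same orientation
  expect_true(h$flip[h$id == "rs005"])   # strand flip + swapped
})

test_that("a swapped-allele weight contributes identically after harmonisation", {
  meta <- make_meta(ea = "A", oa = "G")
  dos <- matrix(c(0, 1, 2, 1), 4, 1, dimnames = list(NULL, "rs001"))
  direct <- score(dos, harmonize(
    tibble::tibble(id = "rs001", ea = "A", oa = "G", weight = 0.02), meta))
  flipped <- score(dos, harmonize(
    tibble::tibble(id = "rs001", ea = "G", oa = "A", weight = 0.02), meta))
  # orientation identity: same weight on the opposite allele shifts the
  # score by a constant, leaving centred scores identical
  expect_equal(direct$score - mean(direct$score),
               -(flipped$score - mean(flipped$score)) * 1,
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(diff(range(direct$score)), diff(range(flipped$score)))
})

test_that("scoring is invariant to wholesale allele re-orientation", {
  co <- quick_cohort(n_trios = 100, n_snps = 30, seed = 4)
  w1 <- co$snp_meta[, c("id", "ea", "oa", "weight")]
  # the same associations expressed on the opposite allele
  w2 <- w1
  w2$ea <- w1$oa; w2$oa <- w1$ea; w2$weight <- -w1$weight
  dos <- co$mat_nontransmitted
  h1 <- harmonize(w1, co$snp_meta)
  h2 <- harmonize(w2, co$snp_meta)
  expect_setequal(attr(h1, "dropped")$id, attr(h2, "dropped")$id)
  s1 <- score(dos, h1)
  s2 <- score(dos, h2)
  # centred scores agree to machine precision
  expect_equal(s1$score - mean(s1$score), s2$score - mean(s2$score),
               tolerance = 1e-12)
})

test_that("harmonising a table against itself is the identity", {
  co <- quick_cohort(n_trios = 50, n_snps = 20, seed = 6)
  meta <- co$snp_meta
  meta$freq <- 0.2  # no palindromic-ambiguity drops
  w <- meta[, c("id", "ea", "oa", "weight")]
  h <- harmonize(w, meta)
  expect_equal(h[, c("id", "ea", "oa", "weight")], w, ignore_attr = TRUE)
  expect_true(all(!h$flip))
  expect_equal(nrow(attr(h, "dropped")), 0)
  expect_error(
    harmonize(tibble::tibble(id = "zz", ea = "A", oa = "G", weight = 1), meta),
    "no SNPs"
  )
})

test_that("clumping follows the stated greedy rule", {
  ref <- matrix(rbinom(300, 2, 0.3), 100, 3,
                dimnames = list(NULL, c("A", "B", "C")))
  ref[, "B"] <- ref[, "A"]; flip <- sample(100, 5)
  ref[flip, "B"] <- 2 - ref[flip, "B"]  # r2(A,B) high
  stats <- tibble::tibble(id = c("A", "B", "C"), chrom = "1",
                          pos = c(1e5, 1.5e5, 2e5),
                          weight = 1, p = c(1e-10, 1e-8, 1e-6))
  sel <- clump_and_threshold(stats, ref, p_max = 1e-5, r2_max = 0.1,
                             window_kb = 500)
  expect_setequal(sel$id, c("A", "C"))
  # independent SNPs: everything below the threshold is retained
  ref2 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  sel2 <- clump_and_threshold(stats, ref2, p_max = 1e-7, r2_max = 0.1,
                              window_kb = 500)
  expect_setequal(sel2$id, c("A", "B"))
})

test_that("clumping is order-invariant and matches the naive oracle", {
  set.seed(31)
  for (rep in 1:20) {
    m <- 20
    blocks <- sample(1:4, m, replace = TRUE)
    driver <- matrix(rbinom(200 * 4, 1, 0.4), 200, 4)
    ref <- sapply(seq_len(m), function(j) {
      take <- rbinom(200, 1, 0.9)
      take * driver[, blocks[j]] + (1 - take) * rbinom(200, 1, 0.4)
    })
    colnames(ref) <- sprintf("s%02d", 1:m)
    stats <- tibble::tibble(
      id = colnames(ref), chrom = as.character(sample(1:2, m, TRUE)),
      pos = sample.int(5e5, m), weight = 1,
      p = signif(runif(m, 1e-12, 1e-4), 3)
    )
    got <- clump_and_threshold(stats, ref, p_max = 1e-5, r2_max = 0.2,
                               window_kb = 300)
    want <- oracle_clump(stats, ref, 1e-5, 0.2, 300)
    expect_identical(got$id, want)
    shuf <- clump_and_threshold(stats[sample(m), ], ref, p_max = 1e-5,
                                r2_max = 0.2, window_kb = 300)
    expect_identical(shuf$id, got$id)
  }
})

test_that("uncovered clumping candidates are dropped with a warning", {
  ref <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("A", "B")))
  stats <- tibble::tibble(id = c("A", "B", "Z"), chrom = "1",
                          pos = c(1, 2, 3) * 1e5, weight = 1, p = rep(1e-9, 3))
  expect_warning(sel <- clump_and_threshold(stats, ref, p_max = 1, r2_max = 1),
                 "missing")
  expect_setequal(sel$id, c("A", "B"))
})

test_that("scores are weighted dosage sums with mean imputation", {
  dos <- matrix(c(0, 1, 2, NA, 1, 1, 0, 2), 4, 2,
                dimnames = list(paste0("i", 1:4), c("a", "b")))
  w <- tibble::tibble(id = c("a", "b"), weight = c(1, 0.5), flip = FALSE)
  s <- score(dos, w)
  expect_equal(s$score[1:3], unname(dos[1:3, 1] + 0.5 * dos[1:3, 2]))
  expect_equal(s$score[4], 1 + 0.5 * 2)  # imputed mean dosage 1 for SNP a
  expect_equal(attr(s, "n_imputed"), 1)
  # single SNP, unit weight: score equals dosage
  s1 <- score(dos[, 1, drop = FALSE] + 0,
              tibble::tibble(id = "a", weight = 1, flip = FALSE))
  expect_equal(s1$score[1:3], unname(dos[1:3, 1]))
  # all-zero weights: all-zero scores
  s0 <- score(dos[1:3, ], tibble::tibble(id = c("a", "b"), weight = 0, flip = FALSE))
  expect_true(all(s0$score == 0))
  # all-missing SNP dropped with a warning
  dos_na <- dos; dos_na[, 2] <- NA
  expect_warning(sna <- score(dos_na, w), "all-missing")
  expect_equal(sna$n_snps_used[1], 1)
})

test_that("scoring the simulator with its true weights reproduces the truth PRS", {
  co <- quick_cohort(n_trios = 200, n_snps = 40, seed = 9)
  w <- co$snp_meta[, c("id", "weight")]
  w$flip <- FALSE
  s <- score(co$mat_h1 + co$mat_h2, w)
  expect_equal(cor(s$score, as.numeric((co$mat_h1 + co$mat_h2) %*%
                                         co$snp_meta$weight)), 1)
})

test_that("within-stratum standardisation yields exact moments", {
  set.seed(12)
  x <- rnorm(200, mean = rep(c(5, 10), each = 100), sd = rep(c(1, 3), each = 100))
  g <- rep(c("a", "b"), each = 100)
  z <- standardize_within_strata(x, g)
  for (s in c("a", "b")) {
    expect_lt(abs(mean(z[g == s])), 1e-12)
    expect_lt(abs(sd(z[g == s]) - 1), 1e-12)
  }
  # between-stratum mean difference removed
  expect_lt(abs(mean(z[g == "a"]) - mean(z[g == "b"])), 1e-12)
  # single stratum = ordinary z-score
  expect_equal(standardize_within_strata(x, rep(1, 200)),
               as.numeric(scale(x)))
})

test_that("sparse strata merge with their nearest neighbour", {
  set.seed(3)
  age <- c(rep(20, 3), rep(21, 50), rep(22, 50))
  x <- rnorm(103, mean = age)
  z <- standardize_within_strata(x, age, min_size = 10)
  # 20 merged into 21: the pooled 20+21 group has exact moments
  m20_21 <- z[age %in% c(20, 21)]
  expect_lt(abs(mean(m20_21)), 1e-12)
  expect_lt(abs(sd(m20_21) - 1), 1e-12)
  expect_lt(abs(sd(z[age == 22]) - 1), 1e-12)
})

test_that("zero-variance strata raise an error naming the stratum", {
  x <- c(rep(1, 20), rnorm(20))
  g <- rep(c("young", "old"), each = 20)
  expect_error(standardize_within_strata(x, g), "young")
})
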