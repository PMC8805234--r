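COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) {
  !is.na(COMPLEMENT[ea]) & COMPLEMENT[ea] == oa
}

#' Harmonise a weight table to cohort SNP metadata
#'
#' Aligns an external per-SNP weight table (effect sizes from a base GWAS or
#' shrinkage method) to the allele coding of the target cohort. Rules, in
#' order:
#'
#' * alleles match as-is: kept;
#' * effect/other swapped: kept with `flip = TRUE` (scoring uses dosage
#'   `2 - g`, preserving the weight's sign and each SNP's contribution);
#' * strand flip (both alleles complemented): resolved by complementing,
#'   then the two rules above;
#' * palindromic SNPs (A/T or C/G) with cohort frequency in (0.4, 0.6):
#'   dropped as unresolvable; outside that band they are oriented by
#'   frequency when the weight table carries an `eaf` column, otherwise kept
#'   as nominally matched;
#' * SNPs absent from the cohort: dropped.
#'
#' @param weights Tibble with columns `id`, `ea`, `oa`, `weight` and
#'   optionally `chrom`, `pos`, `p`, `eaf`.
#' @param snp_meta Cohort SNP table with `id`, `ea`, `oa`, `freq`.
#' @return The aligned weight table (columns of `weights` plus `flip`), with
#'   a `dropped` attribute (tibble `id`, `reason`). Zero surviving SNPs is an
#'   error.
#' @export
harmonize <- function(weights, snp_meta) {
  stopifnot(all(c("id", "ea", "oa", "weight") %in% names(weights)),
            all(c("id", "ea", "oa") %in% names(snp_meta)))
  if (anyDuplicated(weights$id)) abort("duplicate snp ids in weight table")
  if (any(!is.finite(weights$weight))) abort("non-finite weights")
  tgt <- snp_meta[, c("id", "ea", "oa", if ("freq" %in% names(snp_meta)) "freq")]
  names(tgt) <- c("id", "t_ea", "t_oa", if ("freq" %in% names(snp_meta)) "freq")
  x <- dplyr::left_join(weights, tgt, by = "id")
  if (!"freq" %in% names(x)) x$freq <- NA_real_

  drop_reason <- rep(NA_character_, nrow(x))
  drop_reason[is.na(x$t_ea)] <- "not_in_cohort"

  pal <- is_palindromic(x$ea, x$oa) & is.na(drop_reason)
  amb <- pal & !is.na(x$freq) & x$freq > 0.4 & x$freq < 0.6
  drop_reason[amb] <- "palindromic_ambiguous"

  live <- is.na(drop_reason)
  same <- live & x$ea == x$t_ea & x$oa == x$t_oa
  swap <- live & x$ea == x$t_oa & x$oa == x$t_ea
  # strand flip: complements match (never fires for palindromic pairs)
  cea <- unname(COMPLEMENT[x$ea]); coa <- unname(COMPLEMENT[x$oa])
  s_same <- live & !same & !swap & cea == x$t_ea & coa == x$t_oa
  s_swap <- live & !same & !swap & cea == x$t_oa & coa == x$t_ea
  drop_reason[live & !(same | swap | s_same | s_swap)] <- "allele_mismatch"

  flip <- swap | s_swap
  # palindromic, out of band, with source EAF: orient by frequency agreement
  if ("eaf" %in% names(weights)) {
    chk <- pal & !amb & is.na(drop_reason) & !is.na(x$eaf) & !is.na(x$freq)
    flip[chk] <- abs(x$eaf[chk] - x$freq[chk]) > abs(x$eaf[chk] - (1 - x$freq[chk]))
  }

  keep <- is.na(drop_reason)
  dropped <- tibble::tibble(id = x$id[!keep], reason = drop_reason[!keep])
  if (!any(keep)) abort("no SNPs survived harmonisation")
  out <- weights[keep, , drop = FALSE]
  out$flip <- flip[keep]
  attr(out, "dropped") <- dropped
  out
}

#' Greedy LD clumping and p-value thresholding
#'
#' Selects an approximately independent set of SNPs for score construction:
#' candidates are sorted by ascending p-value (ties broken by id), and a SNP
#' is accepted iff its p-value is at most `p_max` and its squared dosage
#' correlation with every previously accepted SNP on the same chromosome
#' within `window_kb` is at most `r2_max`. The result is deterministic and
#' independent of input row order.
#'
#' @param stats Weight table with `id`, `chrom`, `pos` and `p` columns.
#' @param ref_genotypes Dosage matrix (individuals x SNPs, SNP-id column
#'   names) used to estimate LD; candidates without reference coverage are
#'   dropped with a warning.
#' @param p_max P-value threshold.
#' @param r2_max Maximum squared correlation with any accepted SNP.
#' @param window_kb LD window in kilobases.
#' @return `stats` restricted to the selected SNPs, in selection order.
#' @export
clump_and_threshold <- function(stats, ref_genotypes, p_max = 5e-8,
                                r2_max = 0.1, window_kb = 250) {
  stopifnot(all(c("id", "chrom", "pos", "p") %in% names(stats)))
  covered <- stats$id %in% colnames(ref_genotypes)
  if (any(!covered)) {
    warn(sprintf("%d candidate SNP(s) missing from the LD reference; dropped",
                 sum(!covered)))
    stats <- stats[covered, , drop = FALSE]
  }
  stats <- stats[order(stats$p, stats$id), , drop = FALSE]
  stats <- stats[stats$p <= p_max, , drop = FALSE]
  if (nrow(stats) == 0) return(stats)
  sel <- integer(0)
  for (i in seq_len(nrow(stats))) {
    ok <- TRUE
    for (j in sel) {
      if (stats$chrom[i] == stats$chrom[j] &&
          abs(stats$pos[i] - stats$pos[j]) <= window_kb * 1000) {
        r <- suppressWarnings(
          cor(ref_genotypes[, stats$id[i]], ref_genotypes[, stats$id[j]])
        )
        if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) sel <- c(sel, i)
  }
  stats[sel, , drop = FALSE]
}

#' Compute weighted polygenic scores
#'
#' The score for individual i is \eqn{\sum_j w_j d_{ij}} over the harmonised
#' weight table, where \eqn{d_{ij}} is the (possibly fractional) dosage on
#' the table's effect allele: dosages of SNPs flagged `flip` by
#' [harmonize()] enter as `2 - g`. Sporadically missing dosages are
#' mean-imputed per SNP; all-missing SNPs are dropped with a warning.
#'
#' @param dosages Numeric matrix, individuals x SNPs, SNP ids as column
#'   names, individual ids as row names. Fractional dosages (expected values
#'   from ambiguous duo sites) are allowed.
#' @param weights Harmonised weight table ([harmonize()]); SNPs absent from
#'   `dosages` are an error.
#' @return Tibble `id`, `score`, `n_snps_used`, with attributes
#'   `snps_dropped` (tibble of dropped SNPs with reasons) and `n_imputed`
#'   (count of mean-imputed entries).
#' @export
score <- function(dosages, weights) {
  stopifnot(is.matrix(dosages), all(c("id", "weight") %in% names(weights)))
  missing_cols <- setdiff(weights$id, colnames(dosages))
  if (length(missing_cols)) {
    abort(sprintf("%d weight-table SNP(s) absent from dosage matrix",
                  length(missing_cols)))
  }
  d <- dosages[, weights$id, drop = FALSE]
  flip <- if ("flip" %in% names(weights)) weights$flip else rep(FALSE, nrow(weights))
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]

  all_na <- colSums(!is.na(d)) == 0
  dropped <- tibble::tibble(id = weights$id[all_na],
                            reason = rep("all_missing", sum(all_na)))
  if (any(all_na)) {
    warn(sprintf("dropping %d all-missing SNP(s) from score", sum(all_na)))
    d <- d[, !all_na, drop = FALSE]
  }
  w <- weights$weight[!all_na]
  n_imputed <- sum(is.na(d))
  if (n_imputed > 0) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  out <- tibble::tibble(
    id = rownames(dosages) %||% as.character(seq_len(nrow(d))),
    score = as.numeric(d %*% w),
    n_snps_used = ncol(d)
  )
  attr(out, "snps_dropped") <- dropped
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Standardise values within strata
#'
#' Z-scores a variable within strata (the anthropometric convention:
#' exposure standardised within 1-year maternal-age bands, outcomes within
#' sex or sex-by-age bands). Strata smaller than `min_size` are merged with
#' the nearest stratum by label (labels are sorted; numeric labels sort
#' numerically) until every working stratum reaches the minimum.
#'
#' @param values Numeric vector (`NA` passed through).
#' @param strata Stratum labels, same length as `values`.
#' @param min_size Minimum stratum size before merging (default 10).
#' @return Numeric vector of within-stratum z-scores.
#' @export
standardize_within_strata <- function(values, strata, min_size = 10) {
  stopifnot(length(values) == length(strata))
  lab <- as.character(strata)
  lv <- unique(lab[!is.na(lab)])
  num <- suppressWarnings(as.numeric(lv))
  lv <- if (!any(is.na(num))) lv[order(num)] else sort(lv)
  # merge sparse strata into the nearest (by sorted label order) neighbour
  grp <- seq_along(lv)                       # group id per level, ordered
  level_of_obs <- match(lab, lv)
  repeat {
    ids <- unique(grp)
    cnt <- vapply(ids, function(g) sum(grp[level_of_obs] == g, na.rm = TRUE),
                  integer(1))
    small <- which(cnt < min_size)
    if (!length(small) || length(ids) == 1) break
    pos <- small[1]
    nb <- if (pos == 1) ids[2] else ids[pos - 1]
    grp[grp == ids[pos]] <- nb
  }
  gmap <- grp[level_of_obs]
  out <- rep(NA_real_, length(values))
  for (g in unique(gmap[!is.na(gmap)])) {
    ix <- which(gmap == g & !is.na(values))
    s <- sd(values[ix])
    if (!is.finite(s) || s == 0) {
      abort(sprintf("zero-variance stratum: %s",
                    paste(lv[grp == g], collapse = "+")))
    }
    out[ix] <- (values[ix] - mean(values[ix])) / s
  }
  out
}
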