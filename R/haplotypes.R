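#' Resolve maternal transmitted/non-transmitted dosages for one SNP
#'
#' Given hard-call dosages for a mother and child (optionally the father),
#' determines how many copies of the effect allele the mother transmitted,
#' by enumerating the transmissions consistent with Mendelian inheritance:
#'
#' * forced: unique without paternal information (mother homozygous, child
#'   homozygous, or child heterozygous with a homozygous mother);
#' * father_resolved: unique only once a homozygous father pins down the
#'   paternal allele;
#' * ambiguous (mother and child both heterozygous, father absent or
#'   heterozygous): by `policy`, either the expected value 0.5 under the
#'   symmetric prior (`"expected"`, default, unbiased for score building) or
#'   a dropped site (`"drop"`, returns `NA`);
#' * mendel_error: no consistent transmission (e.g. mother 0, child 2).
#'
#' The identity `transmitted + nontransmitted == mother_g` holds at every
#' non-error site. All arguments are vectorised.
#'
#' @param mother_g,child_g Dosages in \{0, 1, 2\} (`NA` allowed; gives
#'   status `"missing"`).
#' @param father_g Optional paternal dosages (`NULL` or `NA` = unavailable).
#' @param policy `"expected"` or `"drop"` for symmetric-ambiguous sites.
#' @return Tibble with columns `transmitted`, `nontransmitted`, `status`.
#' @examples
#' resolve_duo(1, 1, father_g = 0)   # child's allele must be maternal
#' resolve_duo(1, 1)                 # ambiguous: expected dosage 0.5
#' @export
resolve_duo <- function(mother_g, child_g, father_g = NULL,
                        policy = c("expected", "drop")) {
  policy <- match.arg(policy)
  n <- max(length(mother_g), length(child_g))
  m <- rep_len(as.numeric(mother_g), n)
  cg <- rep_len(as.numeric(child_g), n)
  f <- if (is.null(father_g)) rep(NA_real_, n) else rep_len(as.numeric(father_g), n)
  bad <- function(x) !is.na(x) & !(x %in% c(0, 1, 2))
  if (any(bad(m) | bad(cg) | bad(f))) abort("dosages must be in {0, 1, 2}")

  # feasibility of maternal transmitted allele t in {0, 1}
  feas <- function(t) {
    tp <- cg - t
    ok <- (t <= m) & (t >= m - 1) & (tp >= 0) & (tp <= 1)
    # father constraint: f = 0 -> tp = 0; f = 2 -> tp = 1; f = 1/NA -> free
    okf <- ok & (is.na(f) | !((f == 0 & tp == 1) | (f == 2 & tp == 0)))
    list(no_father = ok, with_father = okf)
  }
  f0 <- feas(0); f1 <- feas(1)
  n_no <- f0$no_father + f1$no_father
  n_with <- f0$with_father + f1$with_father

  transmitted <- rep(NA_real_, n)
  status <- rep(NA_character_, n)
  miss <- is.na(m) | is.na(cg)
  status[miss] <- "missing"
  err <- !miss & n_with == 0
  status[err] <- "mendel_error"

  forced <- !miss & !err & n_no == 1
  transmitted[forced] <- ifelse(f1$no_father[forced], 1, 0)
  status[forced] <- "forced"

  fres <- !miss & !err & n_no == 2 & n_with == 1
  transmitted[fres] <- ifelse(f1$with_father[fres], 1, 0)
  status[fres] <- "father_resolved"

  amb <- !miss & !err & n_with == 2
  if (policy == "expected") {
    transmitted[amb] <- 0.5
    status[amb] <- "ambiguous_expected"
  } else {
    status[amb] <- "ambiguous_dropped"
  }
  tibble::tibble(
    transmitted = transmitted,
    nontransmitted = m - transmitted,
    status = status
  )
}

#' Resolve transmitted/non-transmitted dosages across a cohort
#'
#' Applies [resolve_duo()] element-wise to aligned mother / child (optionally
#' father) genotype matrices, summarises per-SNP resolution status, and
#' excludes SNPs whose Mendelian-error rate exceeds `mendel_threshold`
#' (standard trio QC).
#'
#' @param mother_g,child_g Integer dosage matrices, individuals x SNPs, with
#'   matching dimensions (SNP-id column names recommended).
#' @param father_g Optional aligned paternal dosage matrix.
#' @param policy Ambiguity policy passed to [resolve_duo()].
#' @param mendel_threshold Per-SNP Mendelian-error rate above which a SNP is
#'   excluded (default 0.01).
#' @return List: `transmitted` and `nontransmitted` dosage matrices (QC-passed
#'   SNPs only; ambiguous-dropped and Mendel-error sites are `NA`), `qc`
#'   tibble of per-SNP status rates, and `excluded` (ids of removed SNPs).
#' @export
resolve_cohort <- function(mother_g, child_g, father_g = NULL,
                           policy = c("expected", "drop"),
                           mendel_threshold = 0.01) {
  policy <- match.arg(policy)
  if (!identical(dim(mother_g), dim(child_g))) {
    abort("mother and child genotype matrices must have identical dimensions")
  }
  if (!is.null(father_g) && !identical(dim(father_g), dim(mother_g))) {
    abort("father genotype matrix dimensions do not match")
  }
  res <- resolve_duo(as.vector(mother_g), as.vector(child_g),
                     if (is.null(father_g)) NULL else as.vector(father_g),
                     policy = policy)
  dm <- dim(mother_g)
  dn <- dimnames(mother_g)
  trans <- matrix(res$transmitted, dm[1], dm[2], dimnames = dn)
  nontr <- matrix(res$nontransmitted, dm[1], dm[2], dimnames = dn)
  stat <- matrix(res$status, dm[1], dm[2])

  snp_ids <- dn[[2]] %||% paste0("snp", seq_len(dm[2]))
  rate <- function(s) colMeans(stat == s, na.rm = FALSE)
  qc <- tibble::tibble(
    id = snp_ids,
    forced = rate("forced"),
    father_resolved = rate("father_resolved"),
    ambiguous = colMeans(matrix(stat %in% c("ambiguous_expected", "ambiguous_dropped"),
                                dm[1], dm[2])),
    mendel_error = rate("mendel_error"),
    missing = rate("missing")
  )
  qc$excluded <- qc$mendel_error > mendel_threshold
  excluded <- snp_ids[qc$excluded]
  if (length(excluded)) {
    inform(sprintf("excluding %d SNP(s) with Mendelian-error rate > %g: %s",
                   length(excluded), mendel_threshold,
                   paste(head(excluded, 5), collapse = ", ")))
    keep <- !qc$excluded
    trans <- trans[, keep, drop = FALSE]
    nontr <- nontr[, keep, drop = FALSE]
  }
  list(transmitted = trans, nontransmitted = nontr, qc = qc,
       excluded = excluded, policy = policy)
}
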