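#' Write a simulated trio cohort as VCF
#'
#' Emits a VCFv4.2 file with three samples per family (`<id>_M`, `<id>_F`,
#' `<id>_C`): parental genotypes phased (`h1|h2`), offspring unphased. The
#' ALT allele is the effect allele, so allele code 1 corresponds to the
#' dosage counted throughout the package.
#'
#' @param cohort A `trio_cohort` from [simulate_trios()].
#' @param path Output file path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(cohort, path) {
  sm <- cohort$snp_meta
  fam <- cohort$phenotypes$family_id
  gt_m <- matrix(paste0(t(cohort$mat_h1), "|", t(cohort$mat_h2)),
                 nrow(sm), length(fam))
  gt_f <- matrix(paste0(t(cohort$pat_h1), "|", t(cohort$pat_h2)),
                 nrow(sm), length(fam))
  cg <- t(cohort$child_g)
  gt_c <- matrix(c("0/0", "0/1", "1/1")[cg + 1L], nrow(sm), length(fam))
  samples <- as.vector(rbind(paste0(fam, "_M"), paste0(fam, "_F"),
                             paste0(fam, "_C")))
  gt <- matrix("", nrow(sm), 3 * length(fam))
  gt[, seq(1, ncol(gt), 3)] <- gt_m
  gt[, seq(2, ncol(gt), 3)] <- gt_f
  gt[, seq(3, ncol(gt), 3)] <- gt_c
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ntmr trio simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(sm$chrom, sm$pos, sm$id, sm$oa, sm$ea, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a trio VCF into genotype matrices
#'
#' Reads a VCF whose samples follow the `<family>_M` / `<family>_F` /
#' `<family>_C` naming convention ([write_trio_vcf()]); fathers are
#' optional. Dosages count the ALT (effect) allele. Phased parental
#' genotypes additionally yield haplotype matrices.
#'
#' @param path VCF file path.
#' @return List: `snp_meta` (`id`, `chrom`, `pos`, `ea`, `oa`, `freq` --
#'   effect-allele frequency in mothers), dosage matrices `mother_g`,
#'   `child_g` (and `father_g` when present), and maternal haplotypes
#'   `mat_h1`/`mat_h2` when the maternal genotypes are phased.
#' @export
read_trio_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  role <- sub("^.*_", "", samples)
  fam <- sub("_[MFC]$", "", samples)
  dose <- function(x) {
    a <- substr(x, 1, 1); b <- substr(x, 3, 3)
    suppressWarnings(as.integer(a) + as.integer(b))
  }
  pick <- function(r) {
    cols <- which(role == r)
    if (!length(cols)) return(NULL)
    m <- t(apply(gt[, cols, drop = FALSE], 2, dose))
    if (ncol(gt[, cols, drop = FALSE]) == 1) m <- matrix(dose(gt[, cols]), 1)
    dimnames(m) <- list(fam[cols], rownames(gt))
    m
  }
  mother_g <- pick("M"); father_g <- pick("F"); child_g <- pick("C")
  if (is.null(mother_g) || is.null(child_g)) {
    abort("VCF must contain *_M and *_C samples")
  }
  mat_h1 <- mat_h2 <- NULL
  mcols <- which(role == "M")
  if (all(grepl("\\|", gt[, mcols]))) {
    h <- function(k) {
      m <- t(apply(gt[, mcols, drop = FALSE], 2,
                   function(x) as.integer(substr(x, k, k))))
      dimnames(m) <- list(fam[mcols], rownames(gt))
      m
    }
    mat_h1 <- h(1); mat_h2 <- h(3)
  }
  snp_meta <- tibble::tibble(
    id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ea = fix$ALT, oa = fix$REF,
    freq = colMeans(mother_g, na.rm = TRUE) / 2
  )
  list(snp_meta = snp_meta, mother_g = mother_g, father_g = father_g,
       child_g = child_g, mat_h1 = mat_h1, mat_h2 = mat_h2)
}

#' Read / write a SNP weight table (TSV)
#'
#' The interchange format is a tab-separated file with header columns
#' `id`, `chr`, `pos`, `ea`, `oa`, `weight` and optionally `p` and `eaf`.
#'
#' @param path File path.
#' @return A weight tibble with `chr` renamed to `chrom`.
#' @export
read_weights_tsv <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE)
  if ("chr" %in% names(w)) names(w)[names(w) == "chr"] <- "chrom"
  if ("chrom" %in% names(w)) w$chrom <- as.character(w$chrom)
  stopifnot(all(c("id", "ea", "oa", "weight") %in% names(w)))
  w
}

#' @rdname read_weights_tsv
#' @param weights Weight tibble (`id`, `chrom`, `pos`, `ea`, `oa`, `weight`,
#'   optional `p`, `eaf`).
#' @export
write_weights_tsv <- function(weights, path) {
  out <- weights
  if ("chrom" %in% names(out)) names(out)[names(out) == "chrom"] <- "chr"
  keep <- intersect(c("id", "chr", "pos", "ea", "oa", "weight", "p", "eaf"),
                    names(out))
  readr::write_tsv(out[, keep], path)
  invisible(path)
}

#' Read / write a dosage matrix (TSV)
#'
#' Individuals x SNPs with an `id` first column and one column per SNP.
#' Fractional dosages (expected values at ambiguous sites) are preserved.
#'
#' @param path File path.
#' @return Numeric matrix with individual-id rownames.
#' @export
read_dosage_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  m
}

#' @rdname read_dosage_tsv
#' @param mat Numeric dosage matrix (rownames = individual ids).
#' @export
write_dosage_tsv <- function(mat, path) {
  d <- tibble::as_tibble(mat, .name_repair = "minimal")
  d <- dplyr::bind_cols(tibble::tibble(id = rownames(mat)), d)
  readr::write_tsv(d, path)
  invisible(path)
}
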